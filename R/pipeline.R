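#' Run the full small-RNA pipeline over a set of libraries
#'
#' Preprocesses every library (adapter trimming, quality and length
#' filters), assigns clean inserts to isomiR classes against the reference,
#' builds count tables and RPM-normalizes them.
#'
#' @param samples Named list: per sample either a FASTQ path or a read
#'   data.frame (`read_id`, `seq`, `qual`); e.g. the `samples` element of a
#'   [simulate_libraries()] result.
#' @param sample_sheet data.frame with `sample`, `condition`, `replicate`.
#' @param ref An `isomir_reference`.
#' @param preprocess A [preprocess_params()] object.
#' @param caller A [caller_params()] object.
#' @param drop_ambiguous Passed to [call_reads()].
#' @param denominator Passed to [rpm_normalize()].
#' @return List of class `isomir_pipeline`: `counts` (`isomir_counts`),
#'   `rpm` (`isomir_rpm`), `preprocess_reports`, `call_summaries`, `calls`.
#' @export
run_pipeline <- function(samples, sample_sheet, ref,
                         preprocess = preprocess_params(),
                         caller = caller_params(),
                         drop_ambiguous = TRUE,
                         denominator = "mapped_mirna_reads") {
  stopifnot(all(sample_sheet$sample %in% names(samples)))
  reports <- list()
  summaries <- list()
  calls <- list()
  clean_totals <- integer(nrow(sample_sheet))
  names(clean_totals) <- sample_sheet$sample
  for (s in sample_sheet$sample) {
    pp <- preprocess_fastq(samples[[s]], preprocess)
    reports[[s]] <- pp$report
    clean_totals[s] <- pp$report$kept_reads
    cl <- call_reads(pp$reads, ref, caller, drop_ambiguous = drop_ambiguous)
    summaries[[s]] <- cl$summary
    calls[[s]] <- cl$calls
  }
  counts <- build_counts(calls, sample_sheet, clean_reads = clean_totals)
  rpm <- rpm_normalize(counts, denominator = denominator)
  structure(list(counts = counts, rpm = rpm,
                 preprocess_reports = reports,
                 call_summaries = summaries,
                 calls = calls),
            class = "isomir_pipeline")
}

#' @export
print.isomir_pipeline <- function(x, ...) {
  cat(sprintf("isomir_pipeline: %d samples, %d miRNAs, %d isomiR features\n",
              ncol(x$counts$isomir), nrow(x$counts$mirna),
              nrow(x$counts$isomir)))
  invisible(x)
}

#' Differential analysis over a pipeline result
#'
#' Applies the abundance filters, then runs the miRNA abundance volcano
#' analysis (on miRNAs at >= `min_mirna_rpm` RPM in at least one condition)
#' and the per-isomiR proportion tests (templated labels only).
#'
#' @param pipe An `isomir_pipeline` result.
#' @param contrast Character vector `c(treated, control)`.
#' @param spec A [test_spec()].
#' @param min_mirna_rpm Mature abundance filter threshold (RPM).
#' @param min_isomir_rpm IsomiR abundance filter threshold (RPM).
#' @param templated_only,include_mismatch Passed to [isomir_proportions()].
#' @return List of class `isomir_differential`: `volcano` (data.frame),
#'   `proportion_tests` (`isomir_proportion_tests`), `kept_mirnas`,
#'   `kept_isomirs`, `proportions`.
#' @export
differential_analysis <- function(pipe, contrast, spec = test_spec(),
                                  min_mirna_rpm = 10, min_isomir_rpm = 1,
                                  templated_only = TRUE,
                                  include_mismatch = TRUE) {
  kept_m <- filter_mature(pipe$rpm, min_rpm = min_mirna_rpm)
  kept_i <- filter_isomirs(pipe$rpm, min_rpm = min_isomir_rpm)
  volcano <- mirna_volcano(pipe$rpm, contrast, spec, features = kept_m)
  props <- isomir_proportions(pipe$counts, templated_only = templated_only,
                              include_mismatch = include_mismatch)
  # restrict proportion testing to abundance-passing miRNAs and isomiRs
  keep_row <- props$features$mature_id %in% kept_m &
    paste0(props$features$mature_id, "::", props$features$label) %in%
      paste0(kept_i$mature_id, "::", kept_i$label)
  props_f <- props
  props_f$proportions <- props$proportions[keep_row, , drop = FALSE]
  props_f$features <- props$features[keep_row, , drop = FALSE]
  tests <- isomir_proportion_test(props_f, contrast, spec)
  structure(list(volcano = volcano, proportion_tests = tests,
                 kept_mirnas = kept_m, kept_isomirs = kept_i,
                 proportions = props),
            class = "isomir_differential")
}
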