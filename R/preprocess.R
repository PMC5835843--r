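#' Preprocessing parameters
#'
#' Defaults reproduce a standard small-RNA cleanup: trimming of the NEBNext
#' 3' adapter, FASTX-style quality filtering (at least `quality_percent` % of
#' bases at or above Phred `quality_cutoff`), and a minimum insert length.
#'
#' @param adapter 3' adapter sequence (DNA alphabet).
#' @param quality_percent Minimum percentage of bases that must reach
#'   `quality_cutoff` (inclusive) for a read to pass.
#' @param quality_cutoff Phred score threshold (inclusive).
#' @param min_length Minimum insert length after trimming, in nt.
#' @param min_adapter_prefix Minimum length of an adapter prefix at the
#'   read's 3' end that counts as an adapter hit.
#' @return Object of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter = "AGATCGGAAGAGCACACGTCT",
                              quality_percent = 90,
                              quality_cutoff = 30,
                              min_length = 15L,
                              min_adapter_prefix = 5L) {
  stopifnot(nzchar(adapter), quality_percent > 0, quality_percent <= 100,
            min_length >= 1L, min_adapter_prefix >= 1L)
  structure(list(adapter = toupper(adapter),
                 quality_percent = quality_percent,
                 quality_cutoff = as.integer(quality_cutoff),
                 min_length = as.integer(min_length),
                 min_adapter_prefix = as.integer(min_adapter_prefix)),
            class = "preprocess_params")
}

#' Locate the 3' adapter in a read
#'
#' An adapter occurrence is either an exact match of the full adapter
#' anywhere in the read, or an exact match of an adapter prefix of at least
#' `min_prefix` nt that extends to the read's 3' end (a read-through where
#' sequencing stopped inside the adapter). The leftmost occurrence wins.
#'
#' @param bases Character vector of read sequences.
#' @param adapter Adapter sequence.
#' @param min_prefix Minimum rescued prefix length.
#' @return Integer vector: 0-based position of the adapter start, which
#'   equals the insert length (`0` = adapter-only read); `NA` when the
#'   adapter is absent.
#' @export
find_adapter <- function(bases, adapter = "AGATCGGAAGAGCACACGTCT",
                         min_prefix = 5L) {
  pos <- regexpr(adapter, bases, fixed = TRUE)
  ins <- ifelse(pos > 0L, pos - 1L, NA_integer_)
  # prefix rescue at the 3' end, longest (= leftmost) prefix first
  todo <- is.na(ins)
  if (any(todo) && nchar(adapter) - 1L >= min_prefix) {
    nb <- nchar(bases)
    for (p in seq(nchar(adapter) - 1L, min_prefix)) {
      if (!any(todo)) break
      pref <- substr(adapter, 1L, p)
      hit <- todo & nb >= p & substring(bases, nb - p + 1L, nb) == pref
      ins[hit] <- nb[hit] - p
      todo <- todo & !hit
    }
  }
  as.integer(ins)
}

#' FASTX-style quality filter decision
#'
#' A read passes iff at least `percent` % of its bases have Phred quality
#' greater than or equal to `cutoff` (both boundaries inclusive).
#'
#' @param quals Integer vector of Phred scores for one read, or a character
#'   scalar of Sanger (+33) encoded qualities.
#' @param percent Required percentage of passing bases.
#' @param cutoff Phred threshold.
#' @return Logical scalar.
#' @export
quality_pass <- function(quals, percent = 90, cutoff = 30) {
  if (is.character(quals)) {
    stopifnot(length(quals) == 1L)
    quals <- utf8ToInt(quals) - 33L
  }
  if (!length(quals)) stop("empty quality vector", call. = FALSE)
  if (any(quals < 0L | quals > 93L)) {
    stop("Phred scores outside [0, 93]; only Sanger +33 encoding is supported",
         call. = FALSE)
  }
  sum(quals >= cutoff) / length(quals) * 100 >= percent
}

# vectorized quality filter over encoded quality strings
.quality_pass_chr <- function(qual, percent, cutoff) {
  n <- nchar(qual)
  if (cutoff <= 0L) return(rep(TRUE, length(qual)))
  # count bases at or above the cutoff by deleting the low-quality range
  lo <- 33L
  hi <- 33L + cutoff - 1L
  if (hi > 126L) hi <- 126L
  pat <- sprintf("[\\x%02x-\\x%02x]", lo, hi)
  n_hi <- nchar(gsub(pat, "", qual, perl = TRUE))
  n_hi / n * 100 >= percent
}

.read_fastq <- function(path) {
  x <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
      error = function(e) {
        stop("malformed FASTQ '", path, "': ", conditionMessage(e), call. = FALSE)
      }
    ),
    # Biostrings parks the parsed qualities in metadata columns and warns
    # when it drops them while building the quality-scaled set
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `read_id`, `seq`, `qual`.
#' @param path Output path (`.gz` suffix compresses).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Preprocess a small-RNA FASTQ library
#'
#' Applies, in order and with each read assigned exactly one fate:
#' quality filtering on the untrimmed read (`dropped_quality`), adapter
#' location (absent: `dropped_no_adapter`; at position 0: `dropped_adapter_only`),
#' trimming of bases and qualities at the adapter start, and the minimum
#' insert length rule (`dropped_short`). Everything else is kept.
#'
#' @param input Path to a FASTQ file (optionally gzipped) or a data.frame
#'   with columns `read_id`, `seq`, `qual`.
#' @param params A [preprocess_params()] object.
#' @param output Optional path; clean inserts are written there as FASTQ.
#' @return List of class `preprocess_result`: `reads` (data.frame of clean
#'   inserts: `read_id`, `seq`, `qual`) and `report` (class
#'   `preprocess_report`, counts of each fate).
#' @export
preprocess_fastq <- function(input, params = preprocess_params(),
                             output = NULL) {
  stopifnot(inherits(params, "preprocess_params"))
  reads <- if (is.character(input)) .read_fastq(input) else input
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  report <- list(input_reads = n, kept_reads = 0L, dropped_no_adapter = 0L,
                 dropped_adapter_only = 0L, dropped_short = 0L,
                 dropped_quality = 0L)
  if (n == 0L) {
    out <- reads[0L, c("read_id", "seq", "qual")]
    return(structure(list(reads = out,
                          report = structure(report, class = "preprocess_report")),
                     class = "preprocess_result"))
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("base/quality length mismatch at record ",
         which(nchar(reads$seq) != nchar(reads$qual))[1L], call. = FALSE)
  }
  seqs <- toupper(reads$seq)
  fate <- rep(NA_character_, n)

  ok_q <- .quality_pass_chr(reads$qual, params$quality_percent,
                            params$quality_cutoff)
  fate[!ok_q] <- "dropped_quality"

  ins <- find_adapter(seqs, params$adapter, params$min_adapter_prefix)
  open <- is.na(fate)
  fate[open & is.na(ins)] <- "dropped_no_adapter"
  open <- is.na(fate)
  fate[open & !is.na(ins) & ins == 0L] <- "dropped_adapter_only"
  open <- is.na(fate)
  fate[open & ins < params$min_length] <- "dropped_short"
  keep <- is.na(fate)
  fate[keep] <- "kept"

  out <- data.frame(read_id = reads$read_id[keep],
                    seq = substr(seqs[keep], 1L, ins[keep]),
                    qual = substr(reads$qual[keep], 1L, ins[keep]),
                    stringsAsFactors = FALSE)
  tab <- table(factor(fate, levels = c("kept", "dropped_no_adapter",
                                       "dropped_adapter_only", "dropped_short",
                                       "dropped_quality")))
  report$kept_reads <- unname(tab[["kept"]])
  report$dropped_no_adapter <- unname(tab[["dropped_no_adapter"]])
  report$dropped_adapter_only <- unname(tab[["dropped_adapter_only"]])
  report$dropped_short <- unname(tab[["dropped_short"]])
  report$dropped_quality <- unname(tab[["dropped_quality"]])
  report <- structure(report, class = "preprocess_report")
  if (!is.null(output)) write_fastq(out, output)
  structure(list(reads = out, report = report), class = "preprocess_result")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess report:\n")
  for (f in names(x)) cat(sprintf("  %-22s %d\n", f, x[[f]]))
  invisible(x)
}

#' Serialize a preprocessing report
#'
#' @param report A `preprocess_report`.
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @return Invisibly, `path`.
#' @export
write_preprocess_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  } else {
    utils::write.table(data.frame(metric = names(report),
                                  value = unlist(report)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
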