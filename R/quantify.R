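# deterministic row ordering for isomiR labels: canonical first, then pure
# 3' offsets ascending, then 5' compounds, then non-templated tails; a
# mismatch-suffixed label sorts directly after its base label
.label_rank <- function(label) {
  base <- sub("\\|m\\d+$", "", label)
  has_mm <- base != label
  rank <- rep(4000, length(label))
  rank[base == "0"] <- 0
  p3 <- grepl("^[+-]\\d+$", base)
  rank[p3] <- 1000 + as.integer(base[p3])
  p5 <- startsWith(base, "5p:")
  rank[p5] <- 2000 + as.integer(sub("^5p:", "", base[p5]))
  nt <- startsWith(base, "nt:")
  rank[nt] <- 3000 + nchar(base[nt])
  rank + 0.5 * has_mm
}

#' Build per-sample isomiR and miRNA count tables
#'
#' Aggregates call tables into a count matrix at isomiR resolution
#' (rows are `(mature_id, label)` pairs) and its sum at miRNA resolution.
#' Absent (feature, sample) pairs are zero-filled; rows are ordered by
#' mature id, then canonical label first, then 3' offsets ascending.
#'
#' @param calls Named list of call tables (data.frames from
#'   [call_reads()]`$calls`, or `isomir_calls` objects), one per sample.
#' @param sample_sheet data.frame with columns `sample`, `condition`,
#'   `replicate`; every sample must have a call table.
#' @param clean_reads Optional named integer vector of preprocessed read
#'   totals per sample (used as an alternative RPM denominator).
#' @return Object of class `isomir_counts`: list with `isomir` (matrix),
#'   `mirna` (matrix), `features` (data.frame `mature_id`, `label`),
#'   `samples` (the sample sheet), `library_sizes` (miRNA-mapped reads per
#'   sample) and `clean_reads`.
#' @export
build_counts <- function(calls, sample_sheet, clean_reads = NULL) {
  stopifnot(all(c("sample", "condition") %in% names(sample_sheet)))
  if (anyDuplicated(sample_sheet$sample)) {
    stop("duplicate sample id(s) in sample sheet: ",
         paste(unique(sample_sheet$sample[duplicated(sample_sheet$sample)]),
               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(sample_sheet$sample, names(calls))
  if (length(missing)) {
    stop("no call table for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  calls <- lapply(calls[sample_sheet$sample], function(x) {
    if (inherits(x, "isomir_calls")) x$calls else x
  })
  feats <- unique(do.call(rbind, lapply(calls, function(x) {
    unique(x[, c("mature_id", "label")])
  })))
  if (is.null(feats) || nrow(feats) == 0L) {
    feats <- data.frame(mature_id = character(), label = character())
  }
  o <- order(feats$mature_id, .label_rank(feats$label), feats$label,
             method = "radix")
  feats <- feats[o, , drop = FALSE]
  rownames(feats) <- NULL
  key <- paste0(feats$mature_id, "::", feats$label)
  mat <- matrix(0L, nrow = length(key), ncol = nrow(sample_sheet),
                dimnames = list(key, sample_sheet$sample))
  for (s in sample_sheet$sample) {
    x <- calls[[s]]
    if (!nrow(x)) next
    k <- paste0(x$mature_id, "::", x$label)
    tab <- table(k)
    mat[names(tab), s] <- as.integer(tab)
  }
  mirna <- rowsum(mat, group = feats$mature_id, reorder = TRUE)
  structure(list(
    isomir = mat,
    mirna = mirna,
    features = feats,
    samples = sample_sheet,
    library_sizes = colSums(mat),
    clean_reads = clean_reads
  ), class = "isomir_counts")
}

#' @export
print.isomir_counts <- function(x, ...) {
  cat(sprintf("isomir_counts: %d isomiR features, %d miRNAs, %d samples\n",
              nrow(x$isomir), nrow(x$mirna), ncol(x$isomir)))
  invisible(x)
}

#' Reads-per-million normalization
#'
#' @param counts An `isomir_counts` object.
#' @param denominator `"mapped_mirna_reads"` (default; each RPM column then
#'   sums to exactly 1e6) or `"clean_reads"` (total preprocessed reads,
#'   requires `clean_reads` in `counts`).
#' @return Object of class `isomir_rpm`: list with `isomir` and `mirna` RPM
#'   matrices, `denominators`, `features`, `samples`.
#' @export
rpm_normalize <- function(counts,
                          denominator = c("mapped_mirna_reads", "clean_reads")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "mapped_mirna_reads") {
    counts$library_sizes
  } else {
    if (is.null(counts$clean_reads)) {
      stop("clean_reads totals not available in the count object", call. = FALSE)
    }
    counts$clean_reads[colnames(counts$isomir)]
  }
  zero <- den == 0 | is.na(den)
  if (any(zero)) {
    stop("zero RPM denominator for sample(s): ",
         paste(colnames(counts$isomir)[zero], collapse = ", "), call. = FALSE)
  }
  structure(list(
    isomir = sweep(counts$isomir, 2L, den, "/") * 1e6,
    mirna = sweep(counts$mirna, 2L, den, "/") * 1e6,
    denominators = den,
    features = counts$features,
    samples = counts$samples
  ), class = "isomir_rpm")
}

# mean RPM per condition (rows = features, cols = conditions)
.condition_means <- function(mat, samples) {
  conds <- unique(samples$condition)
  out <- vapply(conds, function(cc) {
    rowMeans(mat[, samples$sample[samples$condition == cc], drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat),
                                       dimnames = list(rownames(mat), conds))
  out
}

#' Abundance filter for mature miRNAs
#'
#' Keeps a miRNA iff its mean RPM reaches `min_rpm` (inclusive) in at least
#' one condition (mean across that condition's replicates).
#'
#' @param rpm An `isomir_rpm` object.
#' @param min_rpm Threshold in RPM (default 10).
#' @return Character vector of kept mature ids.
#' @export
filter_mature <- function(rpm, min_rpm = 10) {
  cm <- .condition_means(rpm$mirna, rpm$samples)
  rownames(cm)[apply(cm >= min_rpm, 1L, any)]
}

#' Abundance filter for isomiRs
#'
#' Keeps an isomiR iff its mean RPM reaches `min_rpm` (inclusive) in at
#' least one condition.
#'
#' @param rpm An `isomir_rpm` object.
#' @param min_rpm Threshold in RPM (default 1).
#' @return data.frame of kept features (`mature_id`, `label`).
#' @export
filter_isomirs <- function(rpm, min_rpm = 1) {
  cm <- .condition_means(rpm$isomir, rpm$samples)
  keep <- apply(cm >= min_rpm, 1L, any)
  out <- rpm$features[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-miRNA isomiR proportions
#'
#' For each (miRNA, sample), the proportion of each isomiR label relative to
#' the total reads of that miRNA over the included labels. By default only
#' templated labels are included (non-templated tails are excluded from both
#' numerator and denominator), reflecting variants attributable to shifted
#' Dicer cleavage. Cells whose miRNA has zero included reads in a sample are
#' `NA` (missing), never zero.
#'
#' @param counts An `isomir_counts` object.
#' @param templated_only Restrict to templated labels (default `TRUE`).
#' @param include_mismatch Keep mismatch-carrying labels in the analysis
#'   (default `TRUE`; they pass the caller's mismatch-tolerant window).
#' @return Object of class `isomir_proportions`: list with `proportions`
#'   (matrix, rows = included features), `features`, `denominators`
#'   (miRNA x sample matrix of included totals), `samples`.
#' @export
isomir_proportions <- function(counts, templated_only = TRUE,
                               include_mismatch = TRUE) {
  keep <- if (templated_only) {
    is_templated_label(counts$features$label, include_mismatch)
  } else if (!include_mismatch) {
    !grepl("|m", counts$features$label, fixed = TRUE)
  } else {
    rep(TRUE, nrow(counts$features))
  }
  sub <- counts$isomir[keep, , drop = FALSE]
  feats <- counts$features[keep, , drop = FALSE]
  rownames(feats) <- NULL
  den <- rowsum(sub, group = feats$mature_id, reorder = TRUE)
  den_exp <- den[feats$mature_id, , drop = FALSE]
  prop <- sub / den_exp
  prop[den_exp == 0] <- NA_real_
  structure(list(
    proportions = prop,
    features = feats,
    denominators = den,
    samples = counts$samples
  ), class = "isomir_proportions")
}

#' Wide (heatmap-shaped) isomiR proportion matrix
#'
#' Reshapes a proportion table to one row per miRNA and one column per 3'
#' offset label from `-k` to `+k` with the canonical `"0"` in the middle —
#' the familiar isomiR-matrix layout. Values are averaged over the samples
#' of one condition. Absent labels are `NA` ("non-existing" isomiRs).
#'
#' @param props An `isomir_proportions` object.
#' @param condition Condition whose replicate mean to show.
#' @param k Offset range (default 3).
#' @return Numeric matrix, rows = miRNAs, columns = labels `-k ... 0 ... +k`.
#' @export
proportions_wide <- function(props, condition, k = 3L) {
  sel <- props$samples$sample[props$samples$condition == condition]
  avg <- rowMeans(props$proportions[, sel, drop = FALSE])
  labs <- c(sprintf("%+d", seq(-k, -1L)), "0", sprintf("%+d", seq_len(k)))
  mirnas <- unique(props$features$mature_id)
  out <- matrix(NA_real_, nrow = length(mirnas), ncol = length(labs),
                dimnames = list(mirnas, labs))
  in_grid <- props$features$label %in% labs
  idx <- cbind(match(props$features$mature_id[in_grid], mirnas),
               match(props$features$label[in_grid], labs))
  out[idx] <- avg[in_grid]
  out
}

#' 5p/3p arm ratio
#'
#' For every hairpin with both arms annotated and quantified, the log2 ratio
#' of 5p to 3p abundance with a pseudocount:
#' `log2((RPM_5p + epsilon) / (RPM_3p + epsilon))`. Antisymmetric under arm
#' swap. Hairpins lacking an arm are excluded (recorded in the `excluded`
#' attribute).
#'
#' @param rpm An `isomir_rpm` object.
#' @param ref An `isomir_reference`.
#' @param epsilon Pseudocount in RPM (default 0.5).
#' @return Matrix of log2 ratios, rows = hairpin ids, columns = samples,
#'   with attribute `excluded` (hairpin ids lacking an arm).
#' @export
arm_ratio <- function(rpm, ref, epsilon = 0.5) {
  stopifnot(epsilon > 0)
  m <- ref$matures
  hp <- unique(m$hairpin_id)
  has5 <- hp %in% m$hairpin_id[m$arm == "5p" & m$mature_id %in% rownames(rpm$mirna)]
  has3 <- hp %in% m$hairpin_id[m$arm == "3p" & m$mature_id %in% rownames(rpm$mirna)]
  both <- hp[has5 & has3]
  excluded <- setdiff(hp, both)
  if (!length(both)) {
    out <- matrix(numeric(0), nrow = 0L, ncol = ncol(rpm$mirna),
                  dimnames = list(character(0), colnames(rpm$mirna)))
    attr(out, "excluded") <- excluded
    return(out)
  }
  id5 <- m$mature_id[match(paste(both, "5p"), paste(m$hairpin_id, m$arm))]
  id3 <- m$mature_id[match(paste(both, "3p"), paste(m$hairpin_id, m$arm))]
  out <- log2((rpm$mirna[id5, , drop = FALSE] + epsilon) /
                (rpm$mirna[id3, , drop = FALSE] + epsilon))
  rownames(out) <- both
  attr(out, "excluded") <- excluded
  out
}

#' Reconstruct an isomiR sequence from its call
#'
#' Rebuilds the read sequence implied by a (mature, offset5, offset3,
#' nt_tail) class: the hairpin slice for the templated portion plus any
#' non-templated tail.
#'
#' @param ref An `isomir_reference`.
#' @param mature_id Mature miRNA id.
#' @param offset5,offset3 Signed end offsets.
#' @param nt_tail Non-templated tail ("" if none).
#' @return Character scalar.
#' @export
isomir_sequence <- function(ref, mature_id, offset5 = 0L, offset3 = 0L,
                            nt_tail = "") {
  i <- match(mature_id, ref$matures$mature_id)
  if (is.na(i)) stop("unknown mature id: ", mature_id, call. = FALSE)
  h <- ref$hairpins[[ref$matures$hairpin_id[i]]]
  s0 <- ref$matures$start[i] - offset5
  e0 <- ref$matures$end[i] + if (nzchar(nt_tail)) offset3 - nchar(nt_tail) else offset3
  if (s0 < 0L || e0 > nchar(h) || e0 <= s0) {
    stop("isomiR span outside hairpin for ", mature_id, call. = FALSE)
  }
  paste0(substr(h, s0 + 1L, e0), nt_tail)
}

#' Sequence motif scan over isomiRs
#'
#' Flags which of the supplied sequences contain a motif (default the
#' AU-rich `UAAAU` element, written in the DNA alphabet as `TAAAT`) and
#' reports the aggregate fraction.
#'
#' @param sequences Character vector of isomiR sequences (DNA alphabet;
#'   `U` is converted to `T`).
#' @param motif Motif to scan for (default `"TAAAT"`).
#' @return List: `hits` (named logical vector) and `fraction` (numeric).
#' @export
motif_count <- function(sequences, motif = "TAAAT") {
  seqs <- toupper(chartr("Uu", "Tt", sequences))
  motif <- toupper(chartr("Uu", "Tt", motif))
  hits <- grepl(motif, seqs, fixed = TRUE)
  names(hits) <- names(sequences)
  list(hits = hits, fraction = if (length(hits)) mean(hits) else NA_real_)
}

#' Write a count or RPM matrix with its feature key
#'
#' @param x An `isomir_counts`, `isomir_rpm` or `isomir_proportions` object.
#' @param path Output TSV path.
#' @param what `"isomir"`, `"mirna"` or `"proportions"`.
#' @return Invisibly, `path`.
#' @export
write_isomir_table <- function(x, path, what = c("isomir", "mirna",
                                                 "proportions")) {
  what <- match.arg(what)
  if (what == "mirna") {
    df <- data.frame(mature_id = rownames(x$mirna), x$mirna,
                     check.names = FALSE)
  } else {
    mat <- if (what == "proportions") x$proportions else x$isomir
    df <- data.frame(mature_id = x$features$mature_id,
                     label = x$features$label, mat, check.names = FALSE,
                     row.names = NULL)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
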