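#' Differential test specification
#'
#' `variant` follows the spreadsheet TTEST nomenclature commonly used in
#' figure legends: type 2 is the two-sample pooled-variance (homoscedastic)
#' t-test, type 3 the Welch (heteroscedastic) t-test. The paired mode pairs
#' observations by replicate/experiment and tests the differences.
#'
#' @param variant `"type2"` or `"type3"`.
#' @param alpha Significance level.
#' @param paired Pair observations by replicate.
#' @return Object of class `test_spec`.
#' @export
test_spec <- function(variant = c("type2", "type3"), alpha = 0.05,
                      paired = FALSE) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(variant = variant, alpha = alpha, paired = paired),
            class = "test_spec")
}

#' Two-sample t-test (homoscedastic or Welch) on replicate values
#'
#' Type 2: pooled variance, `df = n_a + n_b - 2`. Type 3: Welch statistic
#' with Satterthwaite degrees of freedom. Two-tailed p-value. When the
#' standard error is zero: equal means give `t = 0, p = 1` by convention;
#' unequal means give an infinite statistic and the smallest representable
#' positive p.
#'
#' @param group_a,group_b Numeric vectors of replicate values (for
#'   `paired = TRUE`, equal length and pairwise matched).
#' @param spec A [test_spec()].
#' @return List: `t_stat`, `df`, `p_value`.
#' @export
t_test_replicates <- function(group_a, group_b, spec = test_spec()) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite replicate values", call. = FALSE)
  }
  if (spec$paired) {
    if (length(a) != length(b)) {
      stop("paired test requires equal-length groups", call. = FALSE)
    }
    if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
    d <- a - b
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    df <- n - 1
    tstat <- if (se == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      mean(d) / se
    }
  } else {
    na <- length(a)
    nb <- length(b)
    if (na < 2L || nb < 2L) stop("need at least 2 values per group", call. = FALSE)
    va <- stats::var(a)
    vb <- stats::var(b)
    if (spec$variant == "type2") {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- if (se == 0) na + nb - 2 else {
        (va / na + vb / nb)^2 /
          ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      }
    }
    delta <- mean(a) - mean(b)
    tstat <- if (se == 0) {
      if (delta == 0) 0 else sign(delta) * Inf
    } else {
      delta / se
    }
  }
  p <- if (is.infinite(tstat)) {
    .Machine$double.xmin
  } else {
    2 * stats::pt(-abs(tstat), df)
  }
  list(t_stat = tstat, df = df, p_value = max(p, .Machine$double.xmin))
}

# samples of a condition, ordered by replicate so groups pair up
.group_samples <- function(design, condition) {
  d <- design[design$condition == condition, , drop = FALSE]
  if ("replicate" %in% names(d)) d <- d[order(d$replicate), , drop = FALSE]
  d$sample
}

#' miRNA abundance volcano analysis
#'
#' Per miRNA: the average over replicate pairs of
#' `log2((RPM_treated + eps) / (RPM_control + eps))` (experiments paired by
#' replicate number), and a t-test on the per-sample `log2(RPM + eps)`
#' values between conditions. Results are sorted by p-value. A
#' Benjamini-Hochberg adjusted column (`padj`) is emitted alongside as an
#' extension; the `significant` flag uses the unadjusted p at `alpha`.
#'
#' @param rpm An `isomir_rpm` object.
#' @param contrast Character vector `c(treated, control)`: fold changes are
#'   `contrast[1]` over `contrast[2]`.
#' @param spec A [test_spec()].
#' @param features Optional mature ids to test (e.g. from
#'   [filter_mature()]); default all.
#' @param epsilon RPM pseudocount for fold changes and logs.
#' @return data.frame: `feature_id`, `mean_log2fc`, `t_stat`, `df`,
#'   `p_value`, `padj`, `significant`.
#' @export
mirna_volcano <- function(rpm, contrast, spec = test_spec(),
                          features = NULL, epsilon = 0.5) {
  design <- rpm$samples
  stopifnot(length(contrast) == 2L, all(contrast %in% design$condition))
  st <- .group_samples(design, contrast[1L])
  sc <- .group_samples(design, contrast[2L])
  if (spec$paired && length(st) != length(sc)) {
    stop("paired design requires equal replicate numbers per condition",
         call. = FALSE)
  }
  mat <- rpm$mirna
  if (!is.null(features)) mat <- mat[rownames(mat) %in% features, , drop = FALSE]
  nfc <- min(length(st), length(sc))
  res <- lapply(rownames(mat), function(f) {
    xt <- mat[f, st]
    xc <- mat[f, sc]
    fc <- mean(log2((xt[seq_len(nfc)] + epsilon) / (xc[seq_len(nfc)] + epsilon)))
    tt <- t_test_replicates(log2(xt + epsilon), log2(xc + epsilon), spec)
    data.frame(feature_id = f, mean_log2fc = fc, t_stat = tt$t_stat,
               df = tt$df, p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), mean_log2fc = numeric(),
                      t_stat = numeric(), df = numeric(), p_value = numeric())
  }
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < spec$alpha
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-isomiR proportion tests between conditions
#'
#' For each included (miRNA, label) feature, a t-test on the replicate-level
#' proportions between the two conditions, the proportion difference and its
#' log2 change. Replicates with a missing proportion (zero-denominator
#' miRNA-sample cells) are excluded for that feature; features with fewer
#' than 2 usable replicates in either group are skipped (flagged, not
#' tested). A per-miRNA flag reports whether any of its labels changed
#' significantly.
#'
#' @param props An `isomir_proportions` object (templated-only by default
#'   upstream).
#' @param contrast Character vector `c(treated, control)`.
#' @param spec A [test_spec()].
#' @param epsilon Proportion pseudocount for the log2 change column.
#' @return List of class `isomir_proportion_tests`: `results` (data.frame:
#'   `mature_id`, `label`, `mean_treated`, `mean_control`, `delta_prop`,
#'   `log2_change`, `t_stat`, `p_value`, `significant`, `skipped`) and
#'   `flags` (data.frame: `mature_id`, `any_label_significant`,
#'   `canonical_significant`, `canonical_direction`).
#' @export
isomir_proportion_test <- function(props, contrast, spec = test_spec(),
                                   epsilon = 1e-3) {
  design <- props$samples
  stopifnot(length(contrast) == 2L, all(contrast %in% design$condition))
  st <- .group_samples(design, contrast[1L])
  sc <- .group_samples(design, contrast[2L])
  pm <- props$proportions
  n <- nrow(pm)
  res <- data.frame(mature_id = props$features$mature_id,
                    label = props$features$label,
                    mean_treated = NA_real_, mean_control = NA_real_,
                    delta_prop = NA_real_, log2_change = NA_real_,
                    t_stat = NA_real_, p_value = NA_real_,
                    significant = FALSE, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    xt <- pm[i, st]
    xc <- pm[i, sc]
    xt <- xt[!is.na(xt)]
    xc <- xc[!is.na(xc)]
    if (length(xt) < 2L || length(xc) < 2L ||
        (spec$paired && length(xt) != length(xc))) {
      res$skipped[i] <- TRUE
      next
    }
    tt <- t_test_replicates(xt, xc, spec)
    res$mean_treated[i] <- mean(xt)
    res$mean_control[i] <- mean(xc)
    res$delta_prop[i] <- mean(xt) - mean(xc)
    res$log2_change[i] <- log2((mean(xt) + epsilon) / (mean(xc) + epsilon))
    res$t_stat[i] <- tt$t_stat
    res$p_value[i] <- tt$p_value
    res$significant[i] <- tt$p_value < spec$alpha
  }
  mirnas <- unique(res$mature_id)
  flags <- data.frame(
    mature_id = mirnas,
    any_label_significant = vapply(mirnas, function(m) {
      any(res$significant[res$mature_id == m])
    }, logical(1L)),
    canonical_significant = vapply(mirnas, function(m) {
      any(res$significant[res$mature_id == m & res$label == "0"])
    }, logical(1L)),
    canonical_direction = vapply(mirnas, function(m) {
      d <- res$delta_prop[res$mature_id == m & res$label == "0"]
      if (!length(d) || is.na(d[1L])) NA_real_ else sign(d[1L])
    }, numeric(1L)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(results = res, flags = flags),
            class = "isomir_proportion_tests")
}

#' Heatmap-shaped matrix of significant isomiR proportion changes
#'
#' One row per miRNA whose canonical ("0") proportion changed significantly,
#' one column per label from `-k` to `+k`, cell = log2 proportion change
#' (treated over control). Rows are ordered by increasing canonical p-value.
#' Labels absent from the data are `NA`.
#'
#' @param tests An `isomir_proportion_tests` object.
#' @param k Offset range (default 3).
#' @return Numeric matrix.
#' @export
proportion_change_matrix <- function(tests, k = 3L) {
  res <- tests$results
  canon <- res[res$label == "0" & res$significant & !res$skipped, , drop = FALSE]
  canon <- canon[order(canon$p_value), , drop = FALSE]
  labs <- c(sprintf("%+d", seq(-k, -1L)), "0", sprintf("%+d", seq_len(k)))
  out <- matrix(NA_real_, nrow = nrow(canon), ncol = length(labs),
                dimnames = list(canon$mature_id, labs))
  sub <- res[res$mature_id %in% canon$mature_id & res$label %in% labs, ,
             drop = FALSE]
  idx <- cbind(match(sub$mature_id, canon$mature_id),
               match(sub$label, labs))
  out[idx] <- sub$log2_change
  out
}
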