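# Independent brute-force oracle for the isomiR caller.
#
# Literally enumerates every variant string in the tolerance window as a
# character vector and compares it to the read base by base. Tails and
# mismatches follow the same contract as the caller (a 3' extension is
# templated only when it equals the hairpin flank exactly; otherwise the
# whole extension is a non-templated tail whose bases are never counted as
# mismatches), but the code path is naive string manipulation, with no
# shared internals.
oracle_enumerate <- function(read, ref, params = caller_params()) {
  rchars <- strsplit(read, "")[[1]]
  L <- length(rchars)
  rows <- list()
  for (i in seq_len(nrow(ref$matures))) {
    m <- ref$matures[i, ]
    hchars <- strsplit(ref$hairpins[[m$hairpin_id]], "")[[1]]
    H <- length(hchars)
    for (o5 in (-params$max_trim5):params$max_add5) {
      sp <- m$start - o5       # 0-based span start
      if (sp < 0 || sp >= m$end) next
      for (o3 in (-params$max_trim3):params$max_add3) {
        if (m$end - sp + o3 != L) next
        if (o3 <= 0) {
          be <- m$end + o3
          if (be <= sp) next
          variant <- hchars[(sp + 1):be]
          mm <- 0L
          for (k in seq_along(variant)) {
            if (variant[k] != rchars[k]) mm <- mm + 1L
          }
          if (mm <= params$max_mismatch) {
            rows[[length(rows) + 1L]] <- data.frame(
              mature_id = m$mature_id, offset5 = o5, offset3 = o3,
              mismatches = mm, templated3 = TRUE, tail_len = 0L,
              nt_tail = "", stringsAsFactors = FALSE)
          }
        } else {
          body <- hchars[(sp + 1):m$end]
          nb <- length(body)
          mm <- 0L
          for (k in seq_len(nb)) {
            if (body[k] != rchars[k]) mm <- mm + 1L
          }
          if (mm > params$max_mismatch) next
          ext <- rchars[(nb + 1):L]
          flank <- if (m$end + 1 <= H) {
            hchars[(m$end + 1):min(m$end + o3, H)]
          } else {
            character(0)
          }
          templated <- length(flank) == o3 && all(ext == flank)
          rows[[length(rows) + 1L]] <- data.frame(
            mature_id = m$mature_id, offset5 = o5, offset3 = o3,
            mismatches = mm, templated3 = templated,
            tail_len = if (templated) 0L else o3,
            nt_tail = if (templated) "" else paste(ext, collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mature_id = character(), offset5 = integer(),
                      offset3 = integer(), mismatches = integer(),
                      templated3 = logical(), tail_len = integer(),
                      nt_tail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# canonical ordering so candidate tables can be compared call-for-call
sort_candidates <- function(df) {
  df <- df[, c("mature_id", "offset5", "offset3", "mismatches",
               "templated3", "tail_len", "nt_tail")]
  o <- order(df$mature_id, df$offset5, df$offset3, df$mismatches)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Textbook two-sample t-tests, written out from the formulas.
oracle_t_type2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  ssa <- sum((a - ma)^2); ssb <- sum((b - mb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_t_type3 <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1); vb <- sum((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
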