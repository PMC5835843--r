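#' IsomiR caller parameters
#'
#' The tolerance window for assigning a read to a mature miRNA: up to
#' `max_mismatch` substitutions in the templated portion, up to
#' `max_trim5`/`max_trim3` nt trimmed from either end, up to `max_add5` nt
#' of templated 5' extension and `max_add3` nt of 3' extension (templated
#' or a non-templated tail).
#'
#' @param max_mismatch Maximum substitutions in the templated portion.
#' @param max_trim5,max_trim3 Maximum 5'/3' trimming, nt.
#' @param max_add5 Maximum templated 5' extension, nt.
#' @param max_add3 Maximum 3' extension (templated or tail), nt.
#' @return Object of class `caller_params`.
#' @export
caller_params <- function(max_mismatch = 1L, max_trim5 = 3L, max_trim3 = 3L,
                          max_add5 = 3L, max_add3 = 3L) {
  p <- list(max_mismatch = as.integer(max_mismatch),
            max_trim5 = as.integer(max_trim5),
            max_trim3 = as.integer(max_trim3),
            max_add5 = as.integer(max_add5),
            max_add3 = as.integer(max_add3))
  stopifnot(all(unlist(p) >= 0L))
  structure(p, class = "caller_params")
}

# Candidate generation over a set of unique read sequences.
#
# A candidate (mature, offset5, offset3) aligns the read to the hairpin span
# [start - offset5, end + offset3). 5' extensions are templated only (drawn
# from the hairpin; they cannot run past the hairpin start). A positive
# offset3 whose read bases equal the hairpin flank is a templated extension;
# otherwise the whole extension is recorded as a non-templated tail and its
# bases are never counted as mismatches. Mismatches are counted on the
# remaining (templated) portion and must not exceed max_mismatch.
#
# Returns a data.frame: seq_idx, mature_id, offset5, offset3, mismatches,
# templated3, tail_len. Total candidate length always equals the read length.
.enumerate_engine <- function(seqs, ref, params) {
  m <- ref$matures
  nseq <- length(seqs)
  lens <- nchar(seqs)
  by_len <- split(seq_len(nseq), lens)
  # byte matrix per read length, rows = reads
  mats <- lapply(by_len, function(ii) {
    L <- lens[ii[1L]]
    matrix(unlist(lapply(seqs[ii], charToRaw), use.names = FALSE),
           nrow = length(ii), ncol = L, byrow = TRUE)
  })
  acc <- list()
  na <- 0L
  emit <- function(idx, mature_id, o5, o3, mm, templ, tail_len) {
    na <<- na + 1L
    acc[[na]] <<- data.frame(seq_idx = idx, mature_id = mature_id,
                             offset5 = o5, offset3 = o3, mismatches = mm,
                             templated3 = templ, tail_len = tail_len,
                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(m))) {
    h <- ref$hairpins[[m$hairpin_id[i]]]
    H <- nchar(h)
    s0 <- m$start[i]
    e0 <- m$end[i]
    for (o5 in seq(-params$max_trim5, params$max_add5)) {
      sp0 <- s0 - o5
      if (sp0 < 0L) next            # 5' extension beyond hairpin start
      if (sp0 >= e0) next           # over-trimmed: empty body
      body_full <- substr(h, sp0 + 1L, e0)
      for (o3 in seq(-params$max_trim3, params$max_add3)) {
        L <- e0 - sp0 + o3
        if (L < 1L) next
        key <- as.character(L)
        ii <- by_len[[key]]
        if (is.null(ii)) next
        mat <- mats[[key]]
        if (o3 <= 0L) {
          if (e0 + o3 <= sp0) next
          variant <- substr(h, sp0 + 1L, e0 + o3)
          vb <- charToRaw(variant)
          mm <- rowSums(mat != matrix(vb, nrow = nrow(mat), ncol = L,
                                      byrow = TRUE))
          keep <- mm <= params$max_mismatch
          if (any(keep)) {
            emit(ii[keep], m$mature_id[i], o5, o3, as.integer(mm[keep]),
                 TRUE, 0L)
          }
        } else {
          Lb <- e0 - sp0
          bb <- charToRaw(body_full)
          mm <- rowSums(mat[, seq_len(Lb), drop = FALSE] !=
                          matrix(bb, nrow = nrow(mat), ncol = Lb,
                                 byrow = TRUE))
          flank <- substr(h, e0 + 1L, min(e0 + o3, H))
          if (nchar(flank) == o3) {
            fb <- charToRaw(flank)
            ext_mm <- rowSums(mat[, (Lb + 1L):L, drop = FALSE] !=
                                matrix(fb, nrow = nrow(mat), ncol = o3,
                                       byrow = TRUE))
            templ <- ext_mm == 0L
          } else {
            templ <- rep(FALSE, nrow(mat))
          }
          keep <- mm <= params$max_mismatch
          if (any(keep)) {
            emit(ii[keep], m$mature_id[i], o5, o3, as.integer(mm[keep]),
                 templ[keep], ifelse(templ[keep], 0L, o3))
          }
        }
      }
    }
  }
  if (na == 0L) {
    return(data.frame(seq_idx = integer(), mature_id = character(),
                      offset5 = integer(), offset3 = integer(),
                      mismatches = integer(), templated3 = logical(),
                      tail_len = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, acc[seq_len(na)])
}

#' Enumerate candidate isomiR assignments for one read
#'
#' Lists every (mature, 5' offset, 3' offset) interpretation of the read
#' within the caller window whose total length matches the read exactly,
#' with its mismatch count, templated-extension status and non-templated
#' tail length.
#'
#' @param read Read sequence (character scalar, DNA alphabet).
#' @param ref An `isomir_reference`.
#' @param params A [caller_params()] object.
#' @return data.frame with columns `mature_id`, `offset5`, `offset3`,
#'   `mismatches`, `templated3`, `tail_len`, `nt_tail`.
#' @export
enumerate_candidates <- function(read, ref, params = caller_params()) {
  stopifnot(is.character(read), length(read) == 1L, nchar(read) >= 1L)
  read <- toupper(read)
  cand <- .enumerate_engine(read, ref, params)
  cand$nt_tail <- if (nrow(cand)) {
    ifelse(cand$tail_len > 0L,
           substr(read, nchar(read) - cand$tail_len + 1L, nchar(read)),
           "")
  } else {
    character(0)
  }
  cand$seq_idx <- NULL
  cand
}

# order candidates by the resolution score:
# fewest mismatches, smallest |offset5| + |offset3|, templated before
# non-templated, shortest tail, then mature id for determinism
.score_order <- function(cand) {
  order(cand$seq_idx, cand$mismatches, abs(cand$offset5) + abs(cand$offset3),
        !cand$templated3, cand$tail_len, cand$mature_id, cand$offset5,
        cand$offset3, method = "radix")
}

#' Resolve candidate assignments to a single call
#'
#' Picks the best candidate by a lexicographic score: fewest mismatches,
#' then smallest total end-offset, then templated over non-templated, then
#' shortest non-templated tail. If two candidates from different matures tie
#' on this score the call is flagged ambiguous.
#'
#' @param candidates data.frame as returned by [enumerate_candidates()].
#' @param params A [caller_params()] object (unused fields reserved).
#' @return One-row data.frame with an added `ambiguous` column, or `NULL`
#'   when `candidates` is empty.
#' @export
resolve_candidates <- function(candidates, params = caller_params()) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  cand <- candidates
  if (is.null(cand$seq_idx)) cand$seq_idx <- 1L
  o <- .score_order(cand)
  best <- cand[o[1L], , drop = FALSE]
  best$ambiguous <- FALSE
  if (length(o) > 1L) {
    second <- cand[o[2L], , drop = FALSE]
    tie <- second$mismatches == best$mismatches &&
      abs(second$offset5) + abs(second$offset3) ==
        abs(best$offset5) + abs(best$offset3) &&
      second$templated3 == best$templated3 &&
      second$tail_len == best$tail_len &&
      second$mature_id != best$mature_id
    best$ambiguous <- isTRUE(tie)
  }
  best$seq_idx <- NULL
  rownames(best) <- NULL
  best
}

# vectorized resolution over the engine's candidate table
.resolve_engine <- function(cand) {
  if (nrow(cand) == 0L) {
    cand$ambiguous <- logical(0)
    return(cand)
  }
  o <- .score_order(cand)
  cand <- cand[o, , drop = FALSE]
  first <- !duplicated(cand$seq_idx)
  win <- which(first)
  res <- cand[first, , drop = FALSE]
  # runner-up (if any) sits directly after the winner in score order
  nxt <- win + 1L
  has2 <- nxt <= nrow(cand) & cand$seq_idx[pmin(nxt, nrow(cand))] == res$seq_idx
  amb <- rep(FALSE, nrow(res))
  if (any(has2)) {
    second <- cand[pmin(nxt, nrow(cand)), , drop = FALSE]
    amb <- has2 &
      second$mismatches == res$mismatches &
      abs(second$offset5) + abs(second$offset3) ==
        abs(res$offset5) + abs(res$offset3) &
      second$templated3 == res$templated3 &
      second$tail_len == res$tail_len &
      second$mature_id != res$mature_id
  }
  res$ambiguous <- amb
  res
}

#' IsomiR class label
#'
#' The compact nomenclature used throughout the package:
#' canonical reads are `"0"`; pure 3' variants are the signed end offset
#' (`"-2"`, `"+1"`); any 5' variant is reported under the compound
#' `"5p:+k"` label; non-templated 3' tails are `"nt:<tail>"`; calls carrying
#' internal substitutions get a `"|m<k>"` suffix so that `"0"` denotes an
#' exact canonical read only.
#'
#' @param offset5,offset3 Signed end offsets (negative = trimming).
#' @param nt_tail Non-templated tail sequence (empty if none).
#' @param mismatches Substitution count in the templated portion.
#' @return Character vector of labels.
#' @export
isomir_label <- function(offset5, offset3, nt_tail = "", mismatches = 0L) {
  n <- max(length(offset5), length(offset3), length(nt_tail),
           length(mismatches))
  offset5 <- rep_len(offset5, n)
  offset3 <- rep_len(offset3, n)
  nt_tail <- rep_len(nt_tail, n)
  mismatches <- rep_len(mismatches, n)
  lab <- character(n)
  is5 <- offset5 != 0L
  lab[is5] <- sprintf("5p:%+d", offset5[is5])
  tail <- !is5 & nzchar(nt_tail)
  lab[tail] <- paste0("nt:", nt_tail[tail])
  plain <- !is5 & !tail
  lab[plain & offset3 == 0L] <- "0"
  p3 <- plain & offset3 != 0L
  lab[p3] <- sprintf("%+d", offset3[p3])
  mm <- mismatches > 0L
  lab[mm] <- paste0(lab[mm], "|m", mismatches[mm])
  lab
}

#' Whether a label denotes a templated isomiR
#'
#' Non-templated tail labels (`"nt:..."`) are excluded from proportion
#' analyses; everything else (canonical, trims, templated additions, and
#' their mismatch-carrying variants) is templated.
#'
#' @param label Character vector of [isomir_label()] values.
#' @param include_mismatch Keep mismatch-carrying labels (`"...|m1"`).
#' @return Logical vector.
#' @export
is_templated_label <- function(label, include_mismatch = TRUE) {
  ok <- !startsWith(label, "nt:")
  if (!include_mismatch) ok <- ok & !grepl("|m", label, fixed = TRUE)
  ok
}

#' Assign preprocessed reads to isomiR classes
#'
#' Runs candidate enumeration and resolution for every read. Reads with
#' no in-window candidate are unassigned; ties between matures are
#' ambiguous and dropped by default. Identical inputs give identical
#' call tables (reads are processed as unique sequences and results mapped
#' back in input order).
#'
#' @param reads data.frame with columns `read_id`, `seq` (e.g. the `reads`
#'   element of [preprocess_fastq()]), or a character vector of sequences.
#' @param ref An `isomir_reference`.
#' @param params A [caller_params()] object.
#' @param drop_ambiguous Drop ambiguous calls (default) rather than keep the
#'   deterministically first mature.
#' @return List of class `isomir_calls`: `calls` (data.frame: `read_id`,
#'   `mature_id`, `offset5`, `offset3`, `templated3`, `nt_tail`,
#'   `mismatches`, `label`) and `summary` (list: `total_reads`, `assigned`,
#'   `unassigned`, `ambiguous_dropped`).
#' @export
call_reads <- function(reads, ref, params = caller_params(),
                       drop_ambiguous = TRUE) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = sprintf("read%d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  n <- nrow(reads)
  empty_calls <- data.frame(read_id = character(), mature_id = character(),
                            offset5 = integer(), offset3 = integer(),
                            templated3 = logical(), nt_tail = character(),
                            mismatches = integer(), ambiguous = logical(),
                            label = character(), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(calls = empty_calls,
                          summary = list(total_reads = 0L, assigned = 0L,
                                         unassigned = 0L,
                                         ambiguous_dropped = 0L)),
                     class = "isomir_calls"))
  }
  seqs <- toupper(reads$seq)
  valid <- !grepl("[^ACGTN]", seqs) & nchar(seqs) >= 1L
  uniq <- unique(seqs[valid])
  res <- if (length(uniq)) {
    .resolve_engine(.enumerate_engine(uniq, ref, params))
  } else {
    .resolve_engine(.enumerate_engine(character(0), ref, params))
  }
  # per-unique-sequence resolved call, indexed by sequence
  map <- match(seqs, uniq)
  hit <- rep(NA_integer_, n)
  if (!is.null(res) && nrow(res)) {
    hit_u <- rep(NA_integer_, length(uniq))
    hit_u[res$seq_idx] <- seq_len(nrow(res))
    hit[valid] <- hit_u[map[valid]]
  }
  assigned_rows <- which(!is.na(hit))
  r <- if (length(assigned_rows)) res[hit[assigned_rows], , drop = FALSE] else res[0L, ]
  amb <- r$ambiguous
  n_amb <- sum(amb)
  take <- if (drop_ambiguous) !amb else rep(TRUE, length(amb))
  rows <- assigned_rows[take]
  rr <- r[take, , drop = FALSE]
  L <- nchar(seqs[rows])
  calls <- data.frame(
    read_id = reads$read_id[rows],
    mature_id = rr$mature_id,
    offset5 = rr$offset5,
    offset3 = rr$offset3,
    templated3 = rr$templated3,
    nt_tail = ifelse(rr$tail_len > 0L,
                     substr(seqs[rows], L - rr$tail_len + 1L, L), ""),
    mismatches = rr$mismatches,
    ambiguous = rr$ambiguous,
    stringsAsFactors = FALSE
  )
  calls$label <- isomir_label(calls$offset5, calls$offset3, calls$nt_tail,
                              calls$mismatches)
  summary <- list(
    total_reads = n,
    assigned = nrow(calls),
    unassigned = n - length(assigned_rows),
    ambiguous_dropped = if (drop_ambiguous) n_amb else 0L
  )
  structure(list(calls = calls, summary = summary), class = "isomir_calls")
}

#' @export
print.isomir_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("isomir_calls: %d reads, %d assigned, %d unassigned, %d ambiguous dropped\n",
              s$total_reads, s$assigned, s$unassigned, s$ambiguous_dropped))
  invisible(x)
}
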