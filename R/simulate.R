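# random DNA string(s)
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

#' Generate a toy hairpin reference
#'
#' Builds random pre-miRNA hairpins, each a 5' flank, a 5p mature (20-23
#' nt), a loop, a 3p mature (20-23 nt) and a 3' flank, so that templated
#' flanks exist on both sides of every mature. Canonical mature sequences
#' are regenerated until pairwise edit distance is at least `min_edit`, so
#' toy references never produce ambiguous assignments by accident.
#' Deterministic under `seed`.
#'
#' @param n_hairpins Number of hairpins (`>= 1`).
#' @param seed Optional RNG seed.
#' @param min_edit Minimum pairwise Levenshtein distance between canonical
#'   mature sequences.
#' @return An `isomir_reference` with hairpins `toy-mir-1 ...` and matures
#'   `toy-mir-<i>-5p` / `toy-mir-<i>-3p`.
#' @export
make_toy_reference <- function(n_hairpins = 3L, seed = NULL, min_edit = 6L) {
  stopifnot(n_hairpins >= 1L)
  if (!is.null(seed)) set.seed(seed)
  matures <- character(0L)
  hairpins <- character(n_hairpins)
  rows <- vector("list", n_hairpins)
  for (i in seq_len(n_hairpins)) {
    for (try in seq_len(200L)) {
      l5 <- sample(20:23, 1L)
      l3 <- sample(20:23, 1L)
      m5 <- .random_dna(1L, l5)
      m3 <- .random_dna(1L, l3)
      cand <- c(matures, m5, m3)
      d <- utils::adist(cand)
      if (all(d[upper.tri(d)] >= min_edit)) break
      if (try == 200L) stop("could not place distinct matures; lower min_edit")
    }
    matures <- c(matures, m5, m3)
    flank5 <- .random_dna(1L, 5L)
    loop <- .random_dna(1L, sample(15:18, 1L))
    flank3 <- .random_dna(1L, 5L)
    hairpins[i] <- paste0(flank5, m5, loop, m3, flank3)
    s5 <- nchar(flank5)
    s3 <- nchar(flank5) + l5 + nchar(loop)
    hid <- sprintf("toy-mir-%d", i)
    rows[[i]] <- data.frame(
      mature_id = sprintf("toy-mir-%d-%s", i, c("5p", "3p")),
      hairpin_id = hid,
      arm = c("5p", "3p"),
      start = c(s5, s3),
      end = c(s5 + l5, s3 + l3),
      stringsAsFactors = FALSE
    )
  }
  names(hairpins) <- sprintf("toy-mir-%d", seq_len(n_hairpins))
  reference_set(hairpins, do.call(rbind, rows))
}

# default per-condition isomiR class mixture: mostly canonical, a ladder of
# 3' trims, one templated +1 addition and a small mono-nucleotide tail
.default_mixture <- function() {
  data.frame(
    offset5 = c(0L, 0L, 0L, 0L, 0L, 0L),
    offset3 = c(0L, -1L, -2L, -3L, 1L, 1L),
    nt_tail = c("", "", "", "", "", "auto"),
    prob = c(0.60, 0.15, 0.07, 0.05, 0.08, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Simulation design for two-condition small-RNA libraries
#'
#' Describes the generative model for a 2-condition x `replicates` study:
#' per-miRNA expected abundance weights, per-miRNA isomiR class mixtures,
#' a per-base substitution error rate, a simple quality model (a fixed high
#' Phred score plus a designed fraction of uniformly low-quality reads that
#' fail the 90/30 rule), adapter read-through to a fixed read length, and
#' replicate-level log-normal noise on both abundances and mixtures.
#'
#' In a mixture, `nt_tail = "auto"` with `offset3 = k` means a length-`k`
#' non-templated tail whose first base is chosen to differ from the hairpin
#' flank (so the class is genuinely non-templated).
#'
#' @param ref An `isomir_reference` the design is built against.
#' @param reads_per_sample Reads per library.
#' @param replicates Replicates per condition.
#' @param conditions Two condition names.
#' @param abundance Named numeric weights per mature id, or a list with one
#'   weight vector per condition. Default: a deterministic 50-fold geometric
#'   spread over the matures, identical in both conditions.
#' @param mixture A mixture data.frame (`offset5`, `offset3`, `nt_tail`,
#'   `prob`) applied to every miRNA, or a nested list
#'   `mixture[[condition]][[mature_id]]`.
#' @param error_rate Per-base substitution probability on the insert.
#' @param low_quality_fraction Fraction of reads emitted with uniformly low
#'   quality (they fail the default quality filter).
#' @param q_high,q_low Phred scores for normal and low-quality reads.
#' @param read_length Instrument read length (adapter read-through).
#' @param adapter 3' adapter sequence.
#' @param abundance_noise_sd,prop_noise_sd Replicate-level log-normal noise
#'   (sd on the log scale) on abundance weights and mixture probabilities.
#' @return Object of class `sim_design`.
#' @export
sim_design <- function(ref,
                       reads_per_sample = 200000L,
                       replicates = 3L,
                       conditions = c("control", "treated"),
                       abundance = NULL,
                       mixture = NULL,
                       error_rate = 0.001,
                       low_quality_fraction = 0.02,
                       q_high = 40L,
                       q_low = 2L,
                       read_length = 50L,
                       adapter = "AGATCGGAAGAGCACACGTCT",
                       abundance_noise_sd = 0.05,
                       prop_noise_sd = 0.05) {
  stopifnot(inherits(ref, "isomir_reference"), reads_per_sample > 0,
            replicates >= 1L, length(conditions) == 2L,
            error_rate >= 0, error_rate <= 1,
            low_quality_fraction >= 0, low_quality_fraction <= 1)
  ids <- ref$matures$mature_id
  if (is.null(abundance)) {
    w <- 2^seq(0, -log2(50), length.out = length(ids))
    abundance <- stats::setNames(w / sum(w), ids)
  }
  if (!is.list(abundance)) {
    abundance <- stats::setNames(list(abundance, abundance), conditions)
  }
  for (cc in conditions) {
    stopifnot(all(ids %in% names(abundance[[cc]])))
  }
  if (is.null(mixture)) mixture <- .default_mixture()
  if (is.data.frame(mixture)) {
    per <- stats::setNames(rep(list(mixture), length(ids)), ids)
    mixture <- stats::setNames(list(per, per), conditions)
  }
  design <- structure(list(
    mature_ids = ids,
    reads_per_sample = as.integer(reads_per_sample),
    replicates = as.integer(replicates),
    conditions = conditions,
    abundance = abundance,
    mixture = mixture,
    error_rate = error_rate,
    low_quality_fraction = low_quality_fraction,
    q_high = as.integer(q_high),
    q_low = as.integer(q_low),
    read_length = as.integer(read_length),
    adapter = toupper(adapter),
    abundance_noise_sd = abundance_noise_sd,
    prop_noise_sd = prop_noise_sd
  ), class = "sim_design")
  validate_sim_design(design, ref)
  design
}

#' Validate a simulation design against a reference and caller window
#'
#' Checks that every mixture sums to 1, that every class lies inside the
#' caller window and is constructible from the hairpin (templated flanks
#' available, 5' extensions within the hairpin), before any I/O happens.
#'
#' @param design A `sim_design`.
#' @param ref An `isomir_reference`.
#' @param params A [caller_params()] window to validate against.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_sim_design <- function(design, ref, params = caller_params()) {
  for (cc in design$conditions) {
    for (id in design$mature_ids) {
      mx <- design$mixture[[cc]][[id]]
      if (is.null(mx)) stop("no mixture for ", id, " in ", cc, call. = FALSE)
      if (abs(sum(mx$prob) - 1) > 1e-8) {
        stop("mixture for ", id, " in ", cc, " does not sum to 1", call. = FALSE)
      }
      for (j in seq_len(nrow(mx))) {
        o5 <- mx$offset5[j]; o3 <- mx$offset3[j]; tail <- mx$nt_tail[j]
        if (o5 > params$max_add5 || -o5 > params$max_trim5 ||
            o3 > params$max_add3 || -o3 > params$max_trim3) {
          stop("class (", o5, ",", o3, ") for ", id,
               " outside the caller window", call. = FALSE)
        }
        if (nzchar(tail) && o3 <= 0L) {
          stop("non-templated tail requires a positive 3' offset (", id, ")",
               call. = FALSE)
        }
        if (nzchar(tail) && !identical(tail, "auto") && nchar(tail) != o3) {
          stop("tail length must equal the 3' offset for ", id, call. = FALSE)
        }
        i <- match(id, ref$matures$mature_id)
        s0 <- ref$matures$start[i]; e0 <- ref$matures$end[i]
        h <- ref$hairpins[[ref$matures$hairpin_id[i]]]
        if (s0 - o5 < 0L) stop("5' extension beyond hairpin for ", id, call. = FALSE)
        e_t <- if (nzchar(tail)) e0 else e0 + o3
        if (e_t > nchar(h)) stop("templated 3' extension beyond hairpin for ",
                                 id, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# construct the insert string for one class, resolving "auto" tails to a
# base different from the hairpin flank
.class_insert <- function(ref, mature_id, offset5, offset3, nt_tail) {
  if (identical(nt_tail, "auto")) {
    flank1 <- substr(templated_flank(ref, mature_id, "3prime", 1L), 1L, 1L)
    base1 <- setdiff(c("T", "A", "G", "C"), flank1)[1L]
    nt_tail <- paste(rep(base1, offset3), collapse = "")
  }
  list(seq = isomir_sequence(ref, mature_id, offset5,
                             if (nzchar(nt_tail)) nchar(nt_tail) else offset3,
                             nt_tail),
       nt_tail = nt_tail)
}

#' Simulate two-condition small-RNA FASTQ libraries with ground truth
#'
#' For every sample (condition x replicate): draws per-read miRNA identity
#' from the (noise-perturbed) abundance weights, then the isomiR class from
#' the (noise-perturbed) mixture, constructs the insert from the hairpin
#' (templated classes) or with the designed tail, applies per-base
#' substitution errors, appends the 3' adapter and random post-adapter
#' filler up to the read length, and emits Phred+33 qualities under the
#' design's quality model. Returns a machine-readable truth table of
#' realized class counts. Byte-identical output under the same seed.
#'
#' @param design A [sim_design()].
#' @param ref The `isomir_reference` the design was built against.
#' @param seed RNG seed for the whole run.
#' @param write_dir Optional directory; per-sample FASTQ (`<sample>.fastq.gz`),
#'   the reference and `truth.json` + `design.yaml` are written there.
#' @return List of class `sim_result`: `samples` (named list of read
#'   data.frames `read_id`, `seq`, `qual`), `sample_sheet`, `truth`
#'   (data.frame: `sample`, `mature_id`, `offset5`, `offset3`, `nt_tail`,
#'   `label`, `count`, `count_error_free`, `designed_prob`), `design`.
#' @export
simulate_libraries <- function(design, ref, seed = NULL, write_dir = NULL) {
  validate_sim_design(design, ref)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  sheet <- expand.grid(replicate = seq_len(design$replicates),
                       condition = design$conditions,
                       stringsAsFactors = FALSE)[, c(2L, 1L)]
  sheet$sample <- paste0(sheet$condition, "_", sheet$replicate)
  sheet <- sheet[, c("sample", "condition", "replicate")]
  ids <- design$mature_ids
  qc_high <- strrep(intToUtf8(design$q_high + 33L), design$read_length)
  qc_low <- strrep(intToUtf8(design$q_low + 33L), design$read_length)
  # random pool for post-adapter filler
  pool <- paste(sample(c("A", "C", "G", "T"), 20000L, replace = TRUE),
                collapse = "")
  samples <- vector("list", nrow(sheet))
  names(samples) <- sheet$sample
  truth <- list()
  for (si in seq_len(nrow(sheet))) {
    cc <- sheet$condition[si]
    sname <- sheet$sample[si]
    w <- design$abundance[[cc]][ids]
    w <- w * exp(stats::rnorm(length(w), 0, design$abundance_noise_sd))
    n_mirna <- as.integer(stats::rmultinom(1L, design$reads_per_sample,
                                           w / sum(w)))
    seq_acc <- character(0L)
    truth_acc <- list()
    for (mi in seq_along(ids)) {
      id <- ids[mi]
      nm <- n_mirna[mi]
      mx <- design$mixture[[cc]][[id]]
      p <- mx$prob * exp(stats::rnorm(nrow(mx), 0, design$prop_noise_sd))
      n_class <- if (nm > 0L) {
        as.integer(stats::rmultinom(1L, nm, p / sum(p)))
      } else {
        integer(nrow(mx))
      }
      inserts <- character(nrow(mx))
      tails <- character(nrow(mx))
      for (j in seq_len(nrow(mx))) {
        ci <- .class_insert(ref, id, mx$offset5[j], mx$offset3[j],
                            mx$nt_tail[j])
        inserts[j] <- ci$seq
        tails[j] <- ci$nt_tail
      }
      seq_acc <- c(seq_acc, rep(inserts, n_class))
      truth_acc[[mi]] <- data.frame(
        sample = sname, mature_id = id,
        offset5 = mx$offset5, offset3 = mx$offset3, nt_tail = tails,
        label = isomir_label(mx$offset5, mx$offset3, tails),
        count = n_class, designed_prob = mx$prob,
        stringsAsFactors = FALSE
      )
    }
    n <- length(seq_acc)
    # substitution errors on the insert
    errored <- rep(FALSE, n)
    if (design$error_rate > 0 && n > 0L) {
      lens <- nchar(seq_acc)
      nerr <- stats::rbinom(n, lens, design$error_rate)
      idx <- which(nerr > 0L)
      errored[idx] <- TRUE
      for (k in idx) {
        pos <- sample.int(lens[k], nerr[k])
        s <- seq_acc[k]
        for (p1 in pos) {
          old <- substr(s, p1, p1)
          substr(s, p1, p1) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
        seq_acc[k] <- s
      }
    }
    # error-free per-class accounting (errors can move a read off its class)
    truth_s <- do.call(rbind, truth_acc)
    err_per_class <- integer(nrow(truth_s))
    if (n > 0L) {
      class_of_read <- rep(seq_len(nrow(truth_s)),
                           truth_s$count)
      tab <- table(factor(class_of_read[errored],
                          levels = seq_len(nrow(truth_s))))
      err_per_class <- as.integer(tab)
    }
    truth_s$count_error_free <- truth_s$count - err_per_class
    # assemble full-length reads: insert + adapter + filler
    if (n > 0L) {
      with_ad <- paste0(seq_acc, design$adapter)
      lens <- nchar(with_ad)
      fill_len <- pmax(design$read_length - lens, 0L)
      starts <- sample.int(nchar(pool) - max(fill_len, 1L), n, replace = TRUE)
      filler <- substring(pool, starts, starts + fill_len - 1L)
      reads <- substr(paste0(with_ad, filler), 1L, design$read_length)
      lowq <- stats::runif(n) < design$low_quality_fraction
      quals <- ifelse(lowq, qc_low, qc_high)
      samples[[sname]] <- data.frame(
        read_id = sprintf("%s_r%07d", sname, seq_len(n)),
        seq = reads, qual = quals, stringsAsFactors = FALSE
      )
    } else {
      samples[[sname]] <- data.frame(read_id = character(),
                                     seq = character(), qual = character(),
                                     stringsAsFactors = FALSE)
    }
    truth[[si]] <- truth_s
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- structure(list(samples = samples, sample_sheet = sheet,
                        truth = truth, design = design),
                   class = "sim_result")
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(samples)) {
      write_fastq(samples[[s]], file.path(write_dir, paste0(s, ".fastq.gz")))
    }
    write_reference(ref, file.path(write_dir, "reference.fa"),
                    file.path(write_dir, "reference.gff3"))
    jsonlite::write_json(truth, file.path(write_dir, "truth.json"),
                         dataframe = "rows", digits = NA)
    write_sim_design(design, file.path(write_dir, "design.yaml"))
  }
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d samples x %d reads, %d miRNAs\n",
              length(x$samples), x$design$reads_per_sample,
              length(x$design$mature_ids)))
  invisible(x)
}

#' Serialize / restore a simulation design as YAML
#'
#' @param design A `sim_design`.
#' @param path YAML file path.
#' @return `write_sim_design`: invisibly `path`. `read_sim_design`: the
#'   restored list (plain; re-validate with [validate_sim_design()]).
#' @export
write_sim_design <- function(design, path) {
  x <- unclass(design)
  x$abundance <- lapply(x$abundance, as.list)   # keep names in YAML maps
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_design
#' @export
read_sim_design <- function(path) {
  x <- yaml::read_yaml(path)
  x$abundance <- lapply(x$abundance, unlist)
  x$mixture <- lapply(x$mixture, function(per) {
    lapply(per, function(mx) as.data.frame(mx, stringsAsFactors = FALSE))
  })
  structure(x, class = "sim_design")
}

#' Null, proportion-shift and abundance-effect scenarios
#'
#' Derives the three standard validation scenarios from a base design:
#' \describe{
#'   \item{null}{identical generative settings in both conditions (the base
#'     design as-is).}
#'   \item{proportion_shift}{one miRNA's canonical-class probability moved
#'     from `prop_from` to `prop_to` in the second condition, with the
#'     difference added to a shorter isomiR class (`gain_offset3`).}
#'   \item{abundance}{one miRNA's expected abundance scaled by
#'     `abundance_factor` in the second condition.}
#' }
#'
#' @param base A [sim_design()] whose target mixture contains classes at
#'   `offset3 = 0` and `gain_offset3` with the required probabilities.
#' @param target Mature id to perturb (default: first mature).
#' @param prop_from,prop_to Canonical proportion in control and treated.
#' @param gain_offset3 3' offset of the shorter class that absorbs the
#'   shifted mass (default -3).
#' @param abundance_factor Abundance scaling in the treated condition.
#' @return Named list of three `sim_design` objects.
#' @export
null_and_effect_scenarios <- function(base, target = NULL,
                                      prop_from = 0.60, prop_to = 0.45,
                                      gain_offset3 = -3L,
                                      abundance_factor = 0.5) {
  if (is.null(target)) target <- base$mature_ids[1L]
  stopifnot(target %in% base$mature_ids)
  treated <- base$conditions[2L]

  shift <- base
  mx <- shift$mixture[[treated]][[target]]
  i0 <- which(mx$offset5 == 0L & mx$offset3 == 0L & !nzchar(mx$nt_tail))
  ig <- which(mx$offset5 == 0L & mx$offset3 == gain_offset3 &
                !nzchar(mx$nt_tail))
  if (length(i0) != 1L || length(ig) != 1L) {
    stop("base mixture must contain a canonical class and a class at ",
         "offset3 = ", gain_offset3, call. = FALSE)
  }
  if (abs(mx$prob[i0] - prop_from) > 1e-8) {
    # rescale so that control matches prop_from exactly in expectation
    mx$prob[ig] <- mx$prob[ig] + (mx$prob[i0] - prop_from)
    mx$prob[i0] <- prop_from
    shift$mixture[[base$conditions[1L]]][[target]] <- mx
  }
  mx$prob[ig] <- mx$prob[ig] + (mx$prob[i0] - prop_to)
  mx$prob[i0] <- prop_to
  shift$mixture[[treated]][[target]] <- mx

  abund <- base
  abund$abundance[[treated]][target] <-
    abund$abundance[[treated]][target] * abundance_factor

  list(null = base, proportion_shift = shift, abundance = abund)
}
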