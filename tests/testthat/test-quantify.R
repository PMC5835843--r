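# minimal call table for count building
mk_calls <- function(mature, label, n) {
  data.frame(read_id = sprintf("r%d", seq_len(sum(n))),
             mature_id = rep(rep_len(mature, length(n)), n),
             label = rep(rep_len(label, length(n)), n),
             stringsAsFactors = FALSE)
}

two_cond_sheet <- function(nrep = 1L) {
  data.frame(sample = c(paste0("ctl_", seq_len(nrep)),
                        paste0("trt_", seq_len(nrep))),
             condition = rep(c("ctl", "trt"), each = nrep),
             replicate = rep(seq_len(nrep), 2L), stringsAsFactors = FALSE)
}

test_that("count tables aggregate calls with zero-fill and stable row order", {
  sheet <- two_cond_sheet()
  calls <- list(
    ctl_1 = mk_calls("miR-a-5p", c("0", "-1", "+1", "nt:T"), c(10L, 4L, 2L, 1L)),
    trt_1 = mk_calls("miR-a-5p", "0", 7L)
  )
  ct <- build_counts(calls, sheet)
  expect_equal(ct$isomir["miR-a-5p::0", ], c(ctl_1 = 10L, trt_1 = 7L))
  expect_equal(ct$isomir["miR-a-5p::-1", "trt_1"], 0L)        # zero-filled
  expect_equal(unname(ct$mirna["miR-a-5p", ]), c(17L, 7L))
  expect_equal(ct$features$label, c("0", "-1", "+1", "nt:T"))  # canonical first
  expect_equal(unname(ct$library_sizes), c(17L, 7L))
  # sample with no calls gives an all-zero column
  calls$trt_1 <- calls$trt_1[0, ]
  ct0 <- build_counts(calls, sheet)
  expect_true(all(ct0$isomir[, "trt_1"] == 0L))
  # duplicate sample ids are rejected
  bad <- sheet
  bad$sample <- c("ctl_1", "ctl_1")
  expect_error(build_counts(calls, bad), "duplicate sample")
})

test_that("RPM normalization conserves column sums and flags zero denominators", {
  sheet <- two_cond_sheet()
  calls <- list(ctl_1 = mk_calls("miR-a-5p", c("0", "-1"), c(75L, 25L)),
                trt_1 = mk_calls("miR-a-5p", "0", 50L))
  ct <- build_counts(calls, sheet)
  rpm <- rpm_normalize(ct)
  expect_equal(unname(colSums(rpm$isomir)), c(1e6, 1e6))
  expect_equal(rpm$isomir["miR-a-5p::0", "ctl_1"], 750000)
  # explicit count/denominator arithmetic via the clean-read denominator
  ct$clean_reads <- c(ctl_1 = 1e6, trt_1 = 1e6)
  rpm2 <- rpm_normalize(ct, denominator = "clean_reads")
  expect_equal(rpm2$isomir["miR-a-5p::-1", "ctl_1"], 25)
  # zero denominator errors with the sample named
  calls0 <- list(ctl_1 = mk_calls("miR-a-5p", "0", 5L),
                 trt_1 = mk_calls("miR-a-5p", "0", 0L))
  ct0 <- build_counts(calls0, sheet)
  expect_error(rpm_normalize(ct0), "trt_1")
})

test_that("abundance filters use condition means and inclusive thresholds", {
  sheet <- two_cond_sheet(nrep = 2L)
  # miR-a: exactly 10 RPM in ctl (mean of 8 and 12 per 1e6 mapped scaled);
  # construct via clean-read denominators for exact control of RPM
  calls <- list(
    ctl_1 = mk_calls(c("miR-a-5p", "miR-b-5p"), c("0", "0"), c(8L, 9L)),
    ctl_2 = mk_calls(c("miR-a-5p", "miR-b-5p"), c("0", "0"), c(12L, 9L)),
    trt_1 = mk_calls(c("miR-a-5p", "miR-b-5p"), c("0", "0"), c(1L, 9L)),
    trt_2 = mk_calls(c("miR-a-5p", "miR-b-5p"), c("0", "0"), c(1L, 10L))
  )
  ct <- build_counts(calls, sheet,
                     clean_reads = c(ctl_1 = 1e6, ctl_2 = 1e6,
                                     trt_1 = 1e6, trt_2 = 1e6))
  rpm <- rpm_normalize(ct, denominator = "clean_reads")
  kept <- filter_mature(rpm, min_rpm = 10)
  expect_true("miR-a-5p" %in% kept)        # mean exactly 10 in ctl: inclusive
  expect_false("miR-b-5p" %in% kept)       # 9 and 9.5: below everywhere
  kept_i <- filter_isomirs(rpm, min_rpm = 1)
  expect_true(nrow(kept_i) == 2L)          # both isomiRs reach 1 RPM somewhere
  kept_i9 <- filter_isomirs(rpm, min_rpm = 9.6)
  expect_equal(kept_i9$mature_id, "miR-a-5p")
})

test_that("isomiR proportions exclude non-templated tails and sum to one", {
  sheet <- two_cond_sheet()
  calls <- list(
    ctl_1 = mk_calls("miR-a-5p", c("0", "-1", "nt:T"), c(80L, 10L, 10L)),
    trt_1 = mk_calls("miR-a-5p", c("0", "-1"), c(80L, 20L))
  )
  ct <- build_counts(calls, sheet)
  pr <- isomir_proportions(ct, templated_only = TRUE)
  expect_equal(pr$proportions["miR-a-5p::0", "ctl_1"], 8 / 9)
  expect_equal(pr$proportions["miR-a-5p::-1", "ctl_1"], 1 / 9)
  expect_false("miR-a-5p::nt:T" %in% rownames(pr$proportions))
  expect_equal(pr$proportions["miR-a-5p::0", "trt_1"], 0.8)
  # per-(miRNA, sample) sums are exactly 1
  sums <- rowsum(pr$proportions, pr$features$mature_id)
  expect_true(all(abs(sums - 1) < 1e-9))
  # denominator-inclusive mode keeps the tail
  pr_all <- isomir_proportions(ct, templated_only = FALSE)
  expect_equal(pr_all$proportions["miR-a-5p::0", "ctl_1"], 0.8)
  # all-zero miRNA-sample cells are missing, not zero
  calls$trt_1 <- mk_calls("miR-b-5p", "0", 5L)
  pr2 <- isomir_proportions(build_counts(calls, sheet))
  expect_true(is.na(pr2$proportions["miR-a-5p::0", "trt_1"]))
})

test_that("arm ratios are symmetric at equality and antisymmetric under swap", {
  ref <- toy_fixed_reference()
  sheet <- two_cond_sheet()
  calls <- list(
    ctl_1 = mk_calls(c("toy-miR-1-5p", "toy-miR-1-3p"), c("0", "0"),
                     c(100L, 100L)),
    trt_1 = mk_calls(c("toy-miR-1-5p", "toy-miR-1-3p"), c("0", "0"),
                     c(200L, 100L))
  )
  ct <- build_counts(calls, sheet,
                     clean_reads = c(ctl_1 = 1e6, trt_1 = 1e6))
  rpm <- rpm_normalize(ct, denominator = "clean_reads")
  ar <- arm_ratio(rpm, ref, epsilon = 1e-9)
  expect_equal(ar["toy-hp-1", "ctl_1"], 0)
  expect_equal(ar["toy-hp-1", "trt_1"], 1, tolerance = 1e-7)
  # swapping the arms negates the ratio
  swapped <- ref
  swapped$matures$arm <- rev(swapped$matures$arm)
  ar2 <- arm_ratio(rpm, swapped, epsilon = 1e-9)
  expect_equal(unname(ar2["toy-hp-1", ]), unname(-ar["toy-hp-1", ]))
  # hairpins lacking an arm are excluded and reported
  calls_one <- list(ctl_1 = mk_calls("toy-miR-1-5p", "0", 10L),
                    trt_1 = mk_calls("toy-miR-1-5p", "0", 10L))
  rpm1 <- rpm_normalize(build_counts(calls_one, sheet))
  ar1 <- arm_ratio(rpm1, ref)
  expect_equal(nrow(ar1), 0L)
  expect_equal(attr(ar1, "excluded"), "toy-hp-1")
})

test_that("motif scan flags UAAAU/TAAAT-containing sequences", {
  expect_true(motif_count("ACGTAAATG")$hits[[1]])
  expect_false(motif_count(strrep("ACGT", 5))$hits[[1]])
  # RNA alphabet input works
  expect_true(motif_count("acguaaaug")$hits[[1]])
  seqs <- c("TTAAATT", "ACGTACGT", "GGTAAATGG", "AAAA", "TAAAT",
            "CCCCC", "TATATA", "CTAAATC", "GGGGG", "TTTTT")
  mc <- motif_count(seqs)
  expect_equal(sum(mc$hits), 4L)   # hand count: seqs 1, 3, 5, 8
  expect_equal(mc$fraction, 0.4)
})

test_that("isomiR sequences reconstruct from calls and label ranks order rows", {
  ref <- toy_fixed_reference()
  canon <- canonical_sequences(ref)[["toy-miR-1-5p"]]
  expect_equal(isomir_sequence(ref, "toy-miR-1-5p"), canon)
  expect_equal(isomir_sequence(ref, "toy-miR-1-5p", 0L, -2L),
               substr(canon, 1, nchar(canon) - 2))
  fl <- templated_flank(ref, "toy-miR-1-5p", "3prime", 1)
  expect_equal(isomir_sequence(ref, "toy-miR-1-5p", 0L, 1L), paste0(canon, fl))
  expect_equal(isomir_sequence(ref, "toy-miR-1-5p", 0L, 2L, "TT"),
               paste0(canon, "TT"))
  # wide proportion layout puts labels -3..0..+3 in order
  sheet <- two_cond_sheet()
  calls <- list(ctl_1 = mk_calls("miR-a-5p", c("0", "-1", "+2"), c(6L, 3L, 1L)),
                trt_1 = mk_calls("miR-a-5p", "0", 5L))
  pr <- isomir_proportions(build_counts(calls, sheet))
  w <- proportions_wide(pr, "ctl")
  expect_equal(colnames(w), c("-3", "-2", "-1", "0", "+1", "+2", "+3"))
  expect_equal(w["miR-a-5p", "0"], 0.6)
  expect_equal(w["miR-a-5p", "-1"], 0.3)
  expect_true(is.na(w["miR-a-5p", "+3"]))
})
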