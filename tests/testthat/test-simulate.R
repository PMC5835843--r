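test_that("toy references are deterministic, well-formed and unambiguous", {
  r1 <- make_toy_reference(3, seed = 5)
  r2 <- make_toy_reference(3, seed = 5)
  expect_identical(r1, r2)
  expect_equal(length(r1$hairpins), 3L)
  expect_equal(nrow(r1$matures), 6L)
  expect_true(all(nchar(r1$hairpins) >= 50 & nchar(r1$hairpins) <= 80))
  expect_true(all(nchar(r1$matures$canonical) >= 20 &
                    nchar(r1$matures$canonical) <= 23))
  d <- utils::adist(r1$matures$canonical)
  expect_true(all(d[upper.tri(d)] >= 6))
  # both arms, non-overlapping, inside the hairpin
  for (hp in names(r1$hairpins)) {
    m <- r1$matures[r1$matures$hairpin_id == hp, ]
    expect_setequal(m$arm, c("5p", "3p"))
    expect_true(m$end[m$arm == "5p"] < m$start[m$arm == "3p"])
  }
})

test_that("simulated libraries are byte-identical under a fixed seed", {
  ref <- make_toy_reference(2, seed = 13)
  d <- sim_design(ref, reads_per_sample = 2000L)
  s1 <- simulate_libraries(d, ref, seed = 99)
  s2 <- simulate_libraries(d, ref, seed = 99)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$sample_sheet), 6L)
  # realized counts sum to reads_per_sample in every library
  sums <- tapply(s1$truth$count, s1$truth$sample, sum)
  expect_true(all(sums == 2000L))
})

test_that("design validation rejects out-of-window or inconsistent classes", {
  ref <- make_toy_reference(1, seed = 3)
  id <- ref$matures$mature_id[1]
  bad_mix <- data.frame(offset5 = 0L, offset3 = -4L, nt_tail = "", prob = 1)
  expect_error(sim_design(ref, mixture = bad_mix), "outside the caller window")
  bad_sum <- data.frame(offset5 = 0L, offset3 = 0L, nt_tail = "", prob = 0.9)
  expect_error(sim_design(ref, mixture = bad_sum), "sum to 1")
  bad_tail <- data.frame(offset5 = c(0L, 0L), offset3 = c(0L, -1L),
                         nt_tail = c("", "T"), prob = c(0.5, 0.5))
  expect_error(sim_design(ref, mixture = bad_tail), "positive 3' offset")
})

test_that("noise-free all-canonical libraries round-trip through the caller", {
  ref <- make_toy_reference(2, seed = 19)
  mix <- data.frame(offset5 = 0L, offset3 = 0L, nt_tail = "", prob = 1)
  d <- sim_design(ref, reads_per_sample = 3000L, mixture = mix,
                  error_rate = 0, low_quality_fraction = 0)
  sim <- simulate_libraries(d, ref, seed = 8)
  pp <- preprocess_fastq(sim$samples[[1]])
  expect_equal(pp$report$kept_reads, 3000L)
  cl <- call_reads(pp$reads, ref)
  expect_equal(cl$summary$assigned, 3000L)
  expect_true(all(cl$calls$label == "0"))
})

test_that("realized class proportions match the design within sampling noise", {
  ref <- make_toy_reference(2, seed = 29)
  d <- sim_design(ref, reads_per_sample = 50000L, error_rate = 0,
                  low_quality_fraction = 0, prop_noise_sd = 0,
                  abundance_noise_sd = 0)
  sim <- simulate_libraries(d, ref, seed = 31)
  tr <- sim$truth[sim$truth$sample == "control_1", ]
  for (id in unique(tr$mature_id)) {
    sub <- tr[tr$mature_id == id, ]
    if (sum(sub$count) < 2000) next
    realized <- sub$count / sum(sub$count)
    # multinomial sd at p ~ 0.6, n > 2000 is < 0.011; allow 4 sd
    expect_true(all(abs(realized - sub$designed_prob) < 0.045))
  }
  # the caller recovers the truth table exactly at error rate 0
  pp <- preprocess_fastq(sim$samples[["control_1"]])
  cl <- call_reads(pp$reads, ref)
  got <- table(paste0(cl$calls$mature_id, "::", cl$calls$label))
  want <- tapply(tr$count, paste0(tr$mature_id, "::", tr$label), sum)
  want <- want[want > 0]
  expect_equal(sort(names(got)), sort(names(want)))
  expect_equal(as.integer(got[names(want)]), unname(as.integer(want)))
})

test_that("the designed low-quality fraction shows up in the preprocess report", {
  ref <- make_toy_reference(1, seed = 37)
  d <- sim_design(ref, reads_per_sample = 20000L, error_rate = 0,
                  low_quality_fraction = 0.1)
  sim <- simulate_libraries(d, ref, seed = 41)
  pp <- preprocess_fastq(sim$samples[[1]])
  frac <- pp$report$dropped_quality / pp$report$input_reads
  # binomial sd at p = 0.1, n = 20000 is 0.0021; allow 5 sd
  expect_true(abs(frac - 0.1) < 0.011)
})

test_that("scenario bundle: null is symmetric, effects are concentrated as designed", {
  ref <- make_toy_reference(2, seed = 43)
  base <- sim_design(ref, reads_per_sample = 1000L)
  sc <- null_and_effect_scenarios(base, target = ref$matures$mature_id[1])
  # null: identical generative settings in both conditions
  expect_identical(sc$null$mixture[["control"]], sc$null$mixture[["treated"]])
  expect_identical(sc$null$abundance[["control"]], sc$null$abundance[["treated"]])
  # proportion shift: difference concentrated on labels {0, -3}
  t1 <- ref$matures$mature_id[1]
  mc <- sc$proportion_shift$mixture[["control"]][[t1]]
  mt <- sc$proportion_shift$mixture[["treated"]][[t1]]
  dd <- mt$prob - mc$prob
  moved <- mc$offset3 %in% c(0L, -3L) & mc$offset5 == 0L & !nzchar(mc$nt_tail)
  expect_equal(dd[moved], c(-0.15, 0.15), tolerance = 1e-12)
  expect_true(all(abs(dd[!moved]) < 1e-12))
  expect_equal(sum(mt$prob), 1, tolerance = 1e-12)
  # untouched miRNAs keep their mixtures
  t2 <- ref$matures$mature_id[2]
  expect_identical(sc$proportion_shift$mixture[["control"]][[t2]],
                   sc$proportion_shift$mixture[["treated"]][[t2]])
  # abundance scenario: designed log2 fold change is exactly -1
  w <- sc$abundance
  expect_equal(log2(w$abundance[["treated"]][[t1]] /
                      w$abundance[["control"]][[t1]]), -1)
})

test_that("designs round-trip through YAML", {
  ref <- make_toy_reference(1, seed = 47)
  d <- sim_design(ref, reads_per_sample = 500L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_design(d, f)
  d2 <- read_sim_design(f)
  expect_equal(d2$reads_per_sample, d$reads_per_sample)
  expect_equal(d2$adapter, d$adapter)
  expect_equal(unlist(d2$abundance), unlist(d$abundance), tolerance = 1e-12)
  expect_equal(d2$mixture[["control"]][[ref$matures$mature_id[1]]]$prob,
               d$mixture[["control"]][[ref$matures$mature_id[1]]]$prob)
  validate_sim_design(d2, ref)
})

test_that("simulation output writes FASTQ and truth files that reload", {
  ref <- make_toy_reference(1, seed = 53)
  d <- sim_design(ref, reads_per_sample = 300L)
  dir <- withr::local_tempdir()
  sim <- simulate_libraries(d, ref, seed = 3, write_dir = dir)
  fq <- file.path(dir, "control_1.fastq.gz")
  expect_true(file.exists(fq))
  back <- preprocess_fastq(fq)
  direct <- preprocess_fastq(sim$samples[["control_1"]])
  expect_equal(back$report, direct$report)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "reference.fa")))
  ref2 <- load_mature_annotations(file.path(dir, "reference.gff3"),
                                  read_hairpins(file.path(dir, "reference.fa")))
  expect_equal(sort(ref2$matures$canonical), sort(ref$matures$canonical))
})
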