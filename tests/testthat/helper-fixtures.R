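# Hand-built two-arm hairpin with known coordinates, used across tests.
# Layout: 5' flank (5 nt) | 5p mature (22 nt) | loop (17 nt) | 3p mature
# (22 nt) | 3' flank (5 nt); total 71 nt.
toy_fixed_reference <- function() {
  m5 <- "TAGCAGCACGTAAATATTGGCG"
  m3 <- "CCAGTATTAACTGTGCTGCTGA"
  hairpin <- paste0("GGACC", m5, "TTTTTGGGGGAAAAACC", m3, "ACGTC")
  matures <- data.frame(
    mature_id = c("toy-miR-1-5p", "toy-miR-1-3p"),
    hairpin_id = "toy-hp-1",
    arm = c("5p", "3p"),
    start = c(5L, 44L),
    end = c(27L, 66L),
    stringsAsFactors = FALSE
  )
  reference_set(c("toy-hp-1" = hairpin), matures)
}

ADAPTER <- "AGATCGGAAGAGCACACGTCT"

# read of fixed total length with adapter read-through and uniform quality
toy_read <- function(insert, q = 40L, read_length = 50L,
                     adapter = ADAPTER, filler = "ACGT") {
  s <- paste0(insert, adapter)
  while (nchar(s) < read_length) s <- paste0(s, filler)
  s <- substr(s, 1L, read_length)
  list(seq = s, qual = strrep(intToUtf8(q + 33L), nchar(s)))
}

reads_df <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(seqs))
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  data.frame(read_id = ids, seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

write_fastq_lines <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$read_id[i]), reads$seq[i], "+",
                 reads$qual[i]), con)
  }
  invisible(path)
}

# random read sequences over ACGT (len recycled per read)
random_seqs <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# mutate k random positions of a sequence
mutate_seq <- function(s, k) {
  pos <- sample.int(nchar(s), k)
  for (p in pos) {
    old <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  s
}
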