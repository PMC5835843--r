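#' Read hairpin precursor sequences from FASTA
#'
#' Loads precursor (pre-miRNA hairpin) sequences and normalizes them to an
#' uppercase DNA alphabet (`U` is converted to `T`) so that sequenced reads
#' and miRBase-style RNA references compare directly.
#'
#' @param path Path to a FASTA file of hairpin sequences.
#' @return Named character vector of sequences, names are hairpin ids
#'   (FASTA header up to the first whitespace). Record order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">h1", "uagcagcacg"), fa)
#' read_hairpins(fa)
#' @export
read_hairpins <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("FASTA '", path, "' contains no records", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate hairpin id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGT/U characters in hairpin record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Load mature-miRNA annotations and build a reference set
#'
#' Reads mature miRNA coordinates on hairpin precursors from a miRBase-style
#' GFF3 file (1-based inclusive coordinates, landmark = hairpin id, feature
#' type `miRNA`) or from a 5-column TSV (`mature_id`, `hairpin_id`, `arm`,
#' `start`, `end`; 1-based inclusive). Coordinates are converted to the
#' internal 0-based half-open convention and the canonical mature sequence is
#' sliced out of the hairpin.
#'
#' The arm (5p/3p) is taken from a `-5p`/`-3p` suffix on the mature id when
#' present; otherwise it is inferred from which half of the hairpin the
#' mature's midpoint falls in.
#'
#' @param path Path to a GFF3 or TSV annotation file.
#' @param hairpins Named character vector from [read_hairpins()].
#' @return An `isomir_reference` object; see [reference_set()].
#' @export
load_mature_annotations <- function(path, hairpins) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  fmt <- .sniff_annotation_format(path)
  mat <- if (fmt == "gff3") .read_mature_gff3(path) else .read_mature_tsv(path)
  reference_set(hairpins, mat)
}

.sniff_annotation_format <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) return("gff3")
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) return("tsv")
  lines <- readLines(path, n = 50L)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("annotation file '", path, "' has no data lines", call. = FALSE)
  nf <- length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  if (nf == 9L) "gff3" else "tsv"
}

# miRBase dialect: landmark = hairpin id, type "miRNA", Name/ID attribute
.read_mature_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) && "type" %in% names(S4Vectors::mcols(gr))) {
    is_mat <- as.character(gr$type) == "miRNA"
    if (any(is_mat)) gr <- gr[is_mat]
  }
  if (!length(gr)) stop("no mature (type 'miRNA') records in GFF3 '", path, "'", call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  ids <- if ("Name" %in% names(mc) && !all(is.na(mc$Name))) {
    as.character(mc$Name)
  } else if ("ID" %in% names(mc)) {
    as.character(mc$ID)
  } else {
    stop("GFF3 '", path, "' lacks Name/ID attributes for mature records", call. = FALSE)
  }
  data.frame(
    mature_id = ids,
    hairpin_id = as.character(GenomicRanges::seqnames(gr)),
    arm = NA_character_,
    # GFF3 1-based inclusive -> 0-based half-open
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.read_mature_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("mature_id", "hairpin_id", "arm", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    mature_id = as.character(tab$mature_id),
    hairpin_id = as.character(tab$hairpin_id),
    arm = as.character(tab$arm),
    start = as.integer(tab$start) - 1L,
    end = as.integer(tab$end),
    stringsAsFactors = FALSE
  )
}

#' Construct a validated reference set
#'
#' @param hairpins Named character vector of hairpin sequences (DNA alphabet).
#' @param matures data.frame with columns `mature_id`, `hairpin_id`, `arm`
#'   (may be `NA`, then inferred), `start`, `end` in 0-based half-open
#'   hairpin coordinates.
#' @return Object of class `isomir_reference`: list with elements `hairpins`
#'   (named character) and `matures` (data.frame with the columns above plus
#'   `canonical`, the mature sequence sliced from the hairpin).
#' @export
reference_set <- function(hairpins, matures) {
  stopifnot(is.character(hairpins), !is.null(names(hairpins)))
  if (anyDuplicated(matures$mature_id)) {
    stop("duplicate mature id(s): ",
         paste(unique(matures$mature_id[duplicated(matures$mature_id)]),
               collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(matures$hairpin_id, names(hairpins))
  if (length(unknown)) {
    stop("mature annotation(s) reference unknown hairpin landmark(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hlen <- nchar(hairpins)[matures$hairpin_id]
  bad <- matures$start < 0L | matures$end <= matures$start | matures$end > hlen
  if (any(bad)) {
    stop("mature span outside hairpin for: ",
         paste(matures$mature_id[bad], collapse = ", "), call. = FALSE)
  }
  arm <- as.character(matures$arm)
  if (!length(arm)) arm <- rep(NA_character_, nrow(matures))
  needs <- is.na(arm) | !arm %in% c("5p", "3p")
  if (any(needs)) {
    has_sfx <- grepl("-(5p|3p)$", matures$mature_id, ignore.case = TRUE)
    sfx <- tolower(sub("^.*-(5p|3p)$", "\\1", matures$mature_id,
                       ignore.case = TRUE))
    arm[needs & has_sfx] <- sfx[needs & has_sfx]
    # fallback: which half of the hairpin does the midpoint fall in
    still <- is.na(arm) | !arm %in% c("5p", "3p")
    mid <- (matures$start + matures$end) / 2
    arm[still] <- ifelse(mid[still] < hlen[still] / 2, "5p", "3p")
  }
  matures$arm <- arm
  dup_arm <- duplicated(paste(matures$hairpin_id, matures$arm))
  if (any(dup_arm)) {
    stop("more than one ", paste(unique(matures$arm[dup_arm]), collapse = "/"),
         " mature on hairpin(s): ",
         paste(unique(matures$hairpin_id[dup_arm]), collapse = ", "),
         call. = FALSE)
  }
  matures$canonical <- substr(hairpins[matures$hairpin_id],
                              matures$start + 1L, matures$end)
  rownames(matures) <- NULL
  structure(list(hairpins = hairpins, matures = matures),
            class = "isomir_reference")
}

#' @export
print.isomir_reference <- function(x, ...) {
  cat("isomir_reference:", length(x$hairpins), "hairpin(s),",
      nrow(x$matures), "mature miRNA(s)\n")
  invisible(x)
}

#' Canonical mature sequences of a reference set
#'
#' @param ref An `isomir_reference`.
#' @return Named character vector, names are mature ids.
#' @export
canonical_sequences <- function(ref) {
  stats::setNames(ref$matures$canonical, ref$matures$mature_id)
}

#' Hairpin sequence flanking a mature miRNA
#'
#' Returns up to `k` hairpin nucleotides immediately adjacent to the mature
#' end on the requested side (shorter if the hairpin terminates). These are
#' the templated bases that a shifted Dicer cleavage would append, and they
#' are what distinguishes templated extensions from non-templated tails.
#'
#' @param ref An `isomir_reference`.
#' @param mature_id Mature miRNA id.
#' @param side `"5prime"` (bases before the mature start) or `"3prime"`
#'   (bases after the mature end).
#' @param k Maximum number of flank nucleotides (`k >= 0`).
#' @return Character scalar of length at most `k`.
#' @export
templated_flank <- function(ref, mature_id, side = c("5prime", "3prime"), k) {
  side <- match.arg(side)
  stopifnot(length(k) == 1L, k >= 0)
  i <- match(mature_id, ref$matures$mature_id)
  if (is.na(i)) stop("unknown mature id: ", mature_id, call. = FALSE)
  h <- ref$hairpins[[ref$matures$hairpin_id[i]]]
  if (k == 0) return("")
  if (side == "5prime") {
    s0 <- ref$matures$start[i]
    substr(h, max(1L, s0 - k + 1L), s0)
  } else {
    e0 <- ref$matures$end[i]
    substr(h, e0 + 1L, min(e0 + k, nchar(h)))
  }
}

#' Write a reference set to FASTA + GFF3
#'
#' Inverse of [read_hairpins()] + [load_mature_annotations()]; coordinates
#' are converted back to the GFF3 1-based inclusive convention.
#'
#' @param ref An `isomir_reference`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, `c(fasta_path, gff3_path)`.
#' @export
write_reference <- function(ref, fasta_path, gff3_path) {
  seqs <- Biostrings::DNAStringSet(ref$hairpins)
  Biostrings::writeXStringSet(seqs, fasta_path)
  m <- ref$matures
  gr <- GenomicRanges::GRanges(
    seqnames = m$hairpin_id,
    ranges = IRanges::IRanges(start = m$start + 1L, end = m$end),
    type = "miRNA",
    source = "isomiRpipe",
    ID = m$mature_id,
    Name = m$mature_id
  )
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta_path, gff3_path))
}
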