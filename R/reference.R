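#' Reference map of the cT-DNA locus
#'
#' A `ref_map` bundles the reference sequence of the analyzed window (the
#' cT-DNA plus its plant flanks) with 1-based inclusive feature intervals:
#' the cT-DNA span, the two terminal inverted repeats, and the three T-DNA
#' gene homologs (acs, susL, rolB). All coordinates used anywhere in the
#' package refer to this local window; conversion to half-open indices
#' happens only inside low-level helpers.
#'
#' @param sequence DNA string of the full analyzed window.
#' @param features data.frame with columns `name`, `start`, `end` and
#'   optionally `strand` ("+"/"-", default "+"). Must contain features
#'   `ctdna`, `left_ir`, `right_ir`.
#' @param flank_len nucleotides of plant flank on each side of the cT-DNA.
#' @return object of class `ref_map`.
#' @export
ref_map <- function(sequence, features, flank_len = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence contains non-ACGTN characters")
  }
  if (is.null(features$strand)) features$strand <- "+"
  features <- features[, c("name", "start", "end", "strand")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  n <- nchar(sequence)
  bad <- features$start < 1 | features$end > n | features$end < features$start
  if (any(bad)) {
    stop(
      "malformed feature interval(s): ",
      paste(features$name[bad], collapse = ", ")
    )
  }
  for (need in c("ctdna", "left_ir", "right_ir")) {
    if (!need %in% features$name) stop("missing required feature: ", need)
  }
  li <- features[features$name == "left_ir", ]
  ri <- features[features$name == "right_ir", ]
  if (li$end >= ri$start) {
    stop("left_ir must precede right_ir without overlap")
  }
  obj <- list(
    sequence = sequence,
    features = features,
    flank_len = as.integer(flank_len)
  )
  class(obj) <- "ref_map"
  obj
}

#' Load a reference map from FASTA plus a feature table
#'
#' The feature table is tab-separated with columns name/start/end (optional
#' fourth column strand); lines starting with `#` are ignored. All intervals
#' are 1-based inclusive on the FASTA sequence.
#'
#' @param fasta_path path to a single-record FASTA file.
#' @param features_path path to the TSV feature table.
#' @return a [ref_map()] object.
#' @export
load_reference <- function(fasta_path, features_path) {
  seqs <- read_fasta(fasta_path)
  if (length(seqs) != 1) {
    stop("reference FASTA must contain exactly one record, found ", length(seqs))
  }
  ft <- read.table(features_path,
    sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE, header = FALSE
  )
  if (ncol(ft) == 3) ft$V4 <- "+"
  names(ft) <- c("name", "start", "end", "strand")
  flank <- if ("left_flank" %in% ft$name) {
    f <- ft[ft$name == "left_flank", ]
    f$end - f$start + 1L
  } else 0L
  ref_map(unname(seqs), ft, flank_len = flank)
}

#' Write a reference map to FASTA + feature TSV
#'
#' @param map a [ref_map()] object.
#' @param fasta_path,features_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(map, fasta_path, features_path) {
  write_fasta(c(reference = map$sequence), fasta_path)
  con <- file(features_path, "w")
  writeLines("# name\tstart\tend\tstrand", con)
  write.table(map$features, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  close(con)
  invisible(c(fasta_path, features_path))
}

feature_interval <- function(map, feature) {
  f <- map$features[map$features$name == feature, ]
  if (nrow(f) == 0) stop("unknown feature: ", feature)
  c(start = f$start[1], end = f$end[1])
}

#' Length of a named feature
#'
#' @param map a [ref_map()] object.
#' @param feature feature name as in the feature table.
#' @return interval length in nucleotides (end - start + 1).
#' @export
feature_length <- function(map, feature) {
  iv <- feature_interval(map, feature)
  unname(iv["end"] - iv["start"] + 1L)
}

#' Extract the sequence of a named feature
#'
#' Returns the forward-strand subsequence; reverse-complementation for
#' minus-strand features is applied only where a caller asks for it.
#'
#' @param map a [ref_map()] object.
#' @param feature feature name.
#' @return DNA string.
#' @export
feature_seq <- function(map, feature) {
  iv <- feature_interval(map, feature)
  substr(map$sequence, iv["start"], iv["end"])
}

#' @export
print.ref_map <- function(x, ...) {
  cat("cT-DNA reference map:", nchar(x$sequence), "nt,",
      nrow(x$features), "features, flank", x$flank_len, "nt\n")
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Path to the bundled synthetic reference
#'
#' The package ships a small synthetic reference locus (sequence generated in
#' code; geometry matching the published coordinates: 5687-nt window, cT-DNA
#' 201..5487, inverted repeats 201..1148 and 4528..5487, genes acs/susL/rolB)
#' used by examples and tests.
#'
#' @param what `"fasta"` or `"features"`.
#' @return file path inside the installed package.
#' @export
synthetic_reference_path <- function(what = c("fasta", "features")) {
  what <- match.arg(what)
  fn <- switch(what,
    fasta = "synthetic_reference.fasta",
    features = "synthetic_reference_features.tsv"
  )
  system.file("extdata", fn, package = "ctdnatools", mustWork = TRUE)
}
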