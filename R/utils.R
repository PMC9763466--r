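#' @importFrom methods as is
#' @importFrom stats rbinom rpois runif setNames quantile sd binom.test
#' @importFrom utils write.table read.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA string
#'
#' @param n length in nucleotides.
#' @return a single DNA string drawn uniformly over A/C/G/T using the
#'   current RNG state.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## split a string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## substitute characters at positions `pos` with random different bases
mutate_bases <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

## scoring used for all nucleotide pairwise alignments in the package
.ctdna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
}

#' Global pairwise alignment of an allele against the reference
#'
#' Affine-gap Needleman-Wunsch (match +1, mismatch -1, gap open -4,
#' gap extend -1) via Biostrings. Returns the aligned character rows plus a
#' coordinate map between reference and query positions.
#'
#' @param query DNA string (e.g. a phased allele).
#' @param ref DNA string (reference).
#' @param type alignment type passed to [Biostrings::pairwiseAlignment()].
#' @return list with elements `q` and `r` (aligned character vectors of equal
#'   length), `score`, and `map` (integer vector: `map[i]` is the query
#'   position aligned to reference position `i`, `NA` where the reference
#'   base is deleted in the query).
#' @export
align_pair <- function(query, ref, type = "global") {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = ref, type = type,
    substitutionMatrix = .ctdna_submat(),
    gapOpening = 4, gapExtension = 1
  )
  q <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  r <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  stopifnot(length(q) == length(r))
  ## for local-in-subject types the aligned rows cover only part of the
  ## subject and positions must be offset by the local start; for global
  ## types the rows cover the whole sequence (terminal gaps included) and no
  ## offset applies -- distinguish by row coverage
  n_sub_rows <- sum(r != "-")
  n_pat_rows <- sum(q != "-")
  sub_off <- if (n_sub_rows == nchar(ref)) 0L else
    Biostrings::start(Biostrings::subject(aln)) - 1L
  pat_off <- if (n_pat_rows == nchar(query)) 0L else
    Biostrings::start(Biostrings::pattern(aln)) - 1L
  rpos <- cumsum(r != "-") + sub_off
  qpos <- cumsum(q != "-") + pat_off
  n_ref <- max(rpos)
  map <- rep(NA_integer_, n_ref)
  keep <- r != "-" & q != "-"
  map[rpos[keep]] <- qpos[keep]
  list(q = q, r = r, score = Biostrings::score(aln), map = map,
       sub_off = sub_off, pat_off = pat_off, aln = aln)
}

#' Alignment cache shared across pipeline stages
#'
#' Per-allele global alignments are the dominant cost of the analysis stages;
#' a cache created once and passed to each stage avoids re-aligning the same
#' allele.
#'
#' @return an environment used as a key-value store.
#' @export
alignment_cache <- function() new.env(parent = emptyenv())

cached_align <- function(cache, key, query, ref) {
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  a <- align_pair(query, ref)
  if (!is.null(cache)) cache[[key]] <- a
  a
}

#' Left-align (5'-normalize) an indel against a reference sequence
#'
#' Shifts an insertion or deletion to its 5'-most equivalent placement, the
#' convention used for all reported indel positions ("last nucleotide before
#' the modification").
#'
#' @param ref_chars reference sequence as a character vector.
#' @param pos 1-based reference coordinate of the last unchanged base before
#'   the event.
#' @param type `"ins"` or `"del"`.
#' @param seq the inserted sequence (for `ins`) or deleted reference segment
#'   (for `del`) as a single string.
#' @return list with normalized `pos` and `seq`.
#' @export
left_align_indel <- function(ref_chars, pos, type, seq) {
  s <- seq_chars(seq)
  L <- length(s)
  if (type == "del") {
    ## deletion of ref[pos+1 .. pos+L]; shift while base before the gap
    ## equals the last deleted base
    while (pos >= 1 && ref_chars[pos] == ref_chars[pos + L]) {
      pos <- pos - 1L
    }
    seq <- paste(ref_chars[(pos + 1):(pos + L)], collapse = "")
  } else {
    ## insertion of s after pos; rotating the last base to the front is
    ## equivalent whenever it matches ref[pos]
    while (pos >= 1 && s[L] == ref_chars[pos]) {
      s <- c(ref_chars[pos], s[-L])
      pos <- pos - 1L
    }
    seq <- paste(s, collapse = "")
  }
  list(pos = as.integer(pos), seq = seq)
}

## extract indel ops (>=1 nt) and substitutions from an alignment produced by
## align_pair(); positions are reference coordinates, indels left-aligned
alignment_ops <- function(a, ref_chars, ref_offset = 0L) {
  q <- a$q; r <- a$r
  n <- length(q)
  if (!is.null(a$sub_off)) ref_offset <- ref_offset + a$sub_off
  rpos <- cumsum(r != "-")
  ops <- list()
  i <- 1L
  while (i <= n) {
    if (q[i] == "-" && r[i] != "-") {         # deletion in query
      j <- i
      while (j < n && q[j + 1L] == "-" && r[j + 1L] != "-") j <- j + 1L
      pos <- rpos[i] - 1L + ref_offset
      seq <- paste(r[i:j], collapse = "")
      la <- left_align_indel(ref_chars, pos, "del", seq)
      ops[[length(ops) + 1L]] <- list(pos = la$pos, type = "del", seq = la$seq)
      i <- j + 1L
    } else if (r[i] == "-" && q[i] != "-") {  # insertion in query
      j <- i
      while (j < n && r[j + 1L] == "-" && q[j + 1L] != "-") j <- j + 1L
      pos <- rpos[i] + ref_offset   # rpos[i] is last ref base before the gap
      seq <- paste(q[i:j], collapse = "")
      la <- left_align_indel(ref_chars, pos, "ins", seq)
      ops[[length(ops) + 1L]] <- list(pos = la$pos, type = "ins", seq = la$seq)
      i <- j + 1L
    } else {
      if (q[i] != r[i] && q[i] != "N" && r[i] != "N") {
        ops[[length(ops) + 1L]] <- list(
          pos = rpos[i] + ref_offset, type = "sub",
          seq = q[i], ref = r[i]
        )
      }
      i <- i + 1L
    }
  }
  ops
}

## apply a set of ops (sub/ins/del, reference coordinates) to a reference
## character vector; ops applied in descending position order so coordinates
## stay valid
apply_ops <- function(ref_chars, ops) {
  if (length(ops) == 0) return(ref_chars)
  ord <- order(vapply(ops, function(o) o$pos, numeric(1)), decreasing = TRUE)
  out <- ref_chars
  for (o in ops[ord]) {
    if (o$type == "sub") {
      out[o$pos] <- o$seq
    } else if (o$type == "del") {
      L <- nchar(o$seq)
      out <- out[-((o$pos + 1):(o$pos + L))]
    } else if (o$type %in% c("ins", "dupl", "plant_insert")) {
      ins <- seq_chars(o$seq)
      out <- append(out, ins, after = o$pos)
    } else {
      stop("unknown op type: ", o$type)
    }
  }
  out
}

#' FASTA/FASTQ helpers
#'
#' Thin wrappers around Biostrings I/O keeping plain character vectors and
#' data.frames on the package side: `read_fasta()` returns a named character
#' vector, `read_fastq()` a data.frame with `id`/`seq`, the writers accept
#' the same shapes.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @param reads data.frame with columns `id`, `seq`.
#' @return sequences (readers) or, invisibly, the path (writers).
#' @name sequence_io
NULL

#' @rdname sequence_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname sequence_io
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

#' @rdname sequence_io
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

## deterministic derived seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299709) %% 2147483647)
}
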