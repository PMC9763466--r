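## ---- terminal inverted repeat comparison -----------------------------------

allele_seq_of <- function(allele) {
  if (inherits(allele, "phased_allele")) allele$sequence
  else if (is.character(allele) && length(allele) == 1) allele
  else stop("allele must be a phased_allele or a single DNA string")
}

allele_id_of <- function(allele, default = "allele") {
  if (inherits(allele, "phased_allele")) allele$allele_id else default
}

## identity over the aligned span: columns between the first and last aligned
## pair; terminal overhangs are excluded and each internal gap run counts as
## one difference (one mutational event), so an indel does not masquerade as
## a run of substitutions
aligned_identity <- function(q, r) {
  both <- which(q != "-" & r != "-")
  if (length(both) == 0) return(list(identity = NA_real_, cols = 0L, matches = 0L))
  span <- both[1]:both[length(both)]
  qs <- q[span]; rs <- r[span]
  informative <- qs != "N" & rs != "N"
  gap <- (qs == "-" | rs == "-") & informative
  n_gap_runs <- sum(rle(gap)$values)
  base_cols <- informative & !gap
  matches <- sum(qs == rs & base_cols)
  cols <- sum(base_cols) + n_gap_runs
  list(identity = 100 * matches / cols, cols = cols, matches = matches)
}

#' Extract and compare the terminal inverted repeats of an allele
#'
#' Lifts the two inverted-repeat intervals from reference to allele
#' coordinates through a global pairwise alignment, reverse-complements the
#' right copy into left orientation, aligns the two copies globally
#' (end-free at the termini), and reports percent identity (internal gap
#' columns count as mismatch) and divergence (1 - identity/100).
#'
#' @param allele a `phased_allele` or DNA string.
#' @param map a [ref_map()] object.
#' @param cache optional [alignment_cache()] shared across pipeline stages.
#' @return object of class `repeat_pair`: `allele_id`, `left_seq`,
#'   `right_seq` (reverse-complemented), `aligned_cols`, `n_match`,
#'   `identity` (percent), `divergence` (fraction), `status`
#'   (`ok`/`unresolved`).
#' @export
extract_repeats <- function(allele, map, cache = NULL) {
  seq <- allele_seq_of(allele)
  id <- allele_id_of(allele)
  out <- list(
    allele_id = id, left_seq = NA_character_, right_seq = NA_character_,
    aligned_cols = 0L, n_match = 0L, identity = NA_real_,
    divergence = NA_real_, status = "unresolved", reason = ""
  )
  class(out) <- "repeat_pair"
  ## orient the allele against the reference first (the result must not
  ## depend on which strand the allele was assembled on)
  votes <- .orientation_votes(seq, map$sequence)
  if (votes["rev"] > votes["fwd"]) {
    seq <- revcomp(seq)
    id <- paste0(id, "::rc")
  }
  a <- cached_align(cache, id, seq, map$sequence)
  lift <- function(feature) {
    iv <- feature_interval(map, feature)
    qs <- a$map[iv["start"]:iv["end"]]
    qs <- qs[!is.na(qs)]
    if (length(qs) == 0) return(NULL)
    substr(seq, min(qs), max(qs))
  }
  left <- lift("left_ir")
  right <- lift("right_ir")
  min_frac <- 0.5
  if (is.null(left) || nchar(left) < min_frac * feature_length(map, "left_ir")) {
    out$reason <- "left repeat absent or mostly deleted in allele"
    return(out)
  }
  if (is.null(right) || nchar(right) < min_frac * feature_length(map, "right_ir")) {
    out$reason <- "right repeat absent or mostly deleted in allele"
    return(out)
  }
  right_rc <- revcomp(right)
  ra <- align_pair(left, right_rc)
  idn <- aligned_identity(ra$q, ra$r)
  out$left_seq <- left
  out$right_seq <- right_rc
  out$aligned_cols <- idn$cols
  out$n_match <- idn$matches
  out$identity <- idn$identity
  out$divergence <- 1 - idn$identity / 100
  out$status <- "ok"
  out
}

#' @export
print.repeat_pair <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("repeat pair %s: %.2f%% identity over %d columns (divergence %.4f)\n",
                x$allele_id, x$identity, x$aligned_cols, x$divergence))
  } else {
    cat("repeat pair", x$allele_id, ": unresolved (", x$reason, ")\n")
  }
  invisible(x)
}

## ---- structural classification ---------------------------------------------

## orientation vote: shared exact k-mers of x with y versus with revcomp(y)
.orientation_votes <- function(x, y, k = 21L) {
  nx <- nchar(x)
  if (nx < k) return(c(fwd = 0L, rev = 0L))
  starts <- seq(1L, nx - k + 1L, by = 4L)
  km <- substring(x, starts, starts + k - 1L)
  ny <- nchar(y)
  yk <- substring(y, 1:(ny - k + 1L), k:ny)
  yrc <- revcomp(y)
  yk_rc <- substring(yrc, 1:(ny - k + 1L), k:ny)
  c(fwd = sum(km %in% yk), rev = sum(km %in% yk_rc))
}

#' Classify the structural architecture of an allele
#'
#' Locates both inverted repeats on the allele, extracts the unique central
#' segment between them, and orients it against the reference center:
#' `inverted_center` when the reverse complement matches better by a clear
#' margin (k-mer orientation vote, with an alignment-score fallback for
#' ambiguous cases). For inverted alleles the gap runs of the oriented
#' alignment near the segment ends are reported as breakpoint deletions.
#'
#' @param allele a `phased_allele` or DNA string.
#' @param map a [ref_map()] object.
#' @param margin minimum score difference (alignment fallback) to call an
#'   orientation.
#' @param min_center minimum central segment length to attempt orientation.
#' @return object of class `structure_call`: `allele_id`, `class`
#'   (`standard` / `inverted_center` / `unresolved`), `evidence`, and
#'   `breakpoint_deletions` (data.frame pos/len in reference-center
#'   coordinates).
#' @export
classify_structure <- function(allele, map, margin = 20, min_center = 200L) {
  seq <- allele_seq_of(allele)
  id <- allele_id_of(allele)
  out <- list(allele_id = id, class = "unresolved", evidence = "",
              breakpoint_deletions = data.frame(pos = integer(0), len = integer(0)))
  class(out) <- "structure_call"

  locate <- function(feature) {
    pat <- feature_seq(map, feature)
    aln <- Biostrings::pairwiseAlignment(
      pattern = pat, subject = seq, type = "local",
      substitutionMatrix = .ctdna_submat(), gapOpening = 4, gapExtension = 1
    )
    c(Biostrings::start(Biostrings::subject(aln)),
      Biostrings::end(Biostrings::subject(aln)))
  }
  li <- locate("left_ir")
  ri <- locate("right_ir")
  if (ri[1] <= li[2]) {
    out$evidence <- "repeat placement inconsistent"
    return(out)
  }
  center <- substr(seq, li[2] + 1L, ri[1] - 1L)
  if (nchar(center) < min_center) {
    out$evidence <- "central segment too short to orient"
    return(out)
  }
  li_ref <- feature_interval(map, "left_ir")
  ri_ref <- feature_interval(map, "right_ir")
  ref_center <- substr(map$sequence, li_ref["end"] + 1L, ri_ref["start"] - 1L)

  votes <- .orientation_votes(center, ref_center)
  if (abs(votes["fwd"] - votes["rev"]) >= 10) {
    inverted <- votes["rev"] > votes["fwd"]
    out$evidence <- sprintf("kmer votes fwd=%d rev=%d", votes["fwd"], votes["rev"])
  } else {
    sc <- function(x) Biostrings::score(Biostrings::pairwiseAlignment(
      pattern = x, subject = ref_center, type = "local",
      substitutionMatrix = .ctdna_submat(), gapOpening = 4, gapExtension = 1
    ))
    s_f <- sc(center); s_r <- sc(revcomp(center))
    if (abs(s_f - s_r) < margin) {
      out$evidence <- sprintf("ambiguous orientation scores f=%.0f r=%.0f", s_f, s_r)
      return(out)
    }
    inverted <- s_r > s_f
    out$evidence <- sprintf("alignment scores fwd=%.0f rev=%.0f", s_f, s_r)
  }

  out$class <- if (inverted) "inverted_center" else "standard"
  if (inverted) {
    oriented <- revcomp(center)
    a <- align_pair(oriented, ref_center)
    ops <- alignment_ops(a, seq_chars(ref_center))
    dels <- Filter(function(o) o$type == "del" && nchar(o$seq) >= 30, ops)
    if (length(dels)) {
      out$breakpoint_deletions <- data.frame(
        pos = vapply(dels, function(o) o$pos + unname(li_ref["end"]), integer(1)),
        len = vapply(dels, function(o) nchar(o$seq), integer(1))
      )
    }
  }
  out
}

#' @export
print.structure_call <- function(x, ...) {
  cat("structure of", x$allele_id, ":", x$class, "(", x$evidence, ")\n")
  invisible(x)
}

## ---- gene disruption scan ---------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan annotated genes of an allele for disrupting mutations
#'
#' Lifts each annotated gene interval onto the allele through the global
#' alignment, then reports premature stop codons (translated in the
#' annotated frame, with a 12-nt context string ending at the stop),
#' frameshifts (indels within the gene whose length is not a multiple of 3),
#' and truncations (less than half of the gene interval recovered).
#'
#' @param allele a `phased_allele` or DNA string.
#' @param map a [ref_map()] object.
#' @param cache optional [alignment_cache()].
#' @return data.frame with columns `allele_id`, `gene`, `kind`
#'   (`premature_stop` / `frameshift` / `truncation`), `pos` (1-based
#'   reference coordinate), `context`. Zero rows mean all genes intact.
#' @export
scan_gene_disruptions <- function(allele, map, cache = NULL) {
  seq <- allele_seq_of(allele)
  id <- allele_id_of(allele)
  a <- cached_align(cache, id, seq, map$sequence)
  genes <- intersect(c("acs", "susL", "rolB"), map$features$name)
  rows <- list()
  add <- function(gene, kind, pos, context) {
    rows[[length(rows) + 1L]] <<- data.frame(
      allele_id = id, gene = gene, kind = kind, pos = as.integer(pos),
      context = context, stringsAsFactors = FALSE
    )
  }
  ref_chars <- seq_chars(map$sequence)
  ops <- alignment_ops(a, ref_chars)
  for (gene in genes) {
    iv <- feature_interval(map, gene)
    qs <- a$map[iv["start"]:iv["end"]]
    present <- which(!is.na(qs))
    if (length(present) < 0.5 * (iv["end"] - iv["start"] + 1L)) {
      add(gene, "truncation", iv["start"], "")
      next
    }
    ## frameshifts: net-length-changing indels inside the gene
    for (o in ops) {
      if (!o$type %in% c("ins", "del")) next
      if (o$pos < iv["start"] || o$pos > iv["end"]) next
      if (nchar(o$seq) %% 3L != 0L) {
        ctx_lo <- max(1L, o$pos - 8L)
        add(gene, "frameshift", o$pos,
            substr(map$sequence, ctx_lo, min(nchar(map$sequence), o$pos + 3L)))
      }
    }
    ## premature stops in the annotated frame
    q_lo <- qs[present[1]]
    q_hi <- qs[present[length(present)]]
    gseq <- substr(seq, q_lo, q_hi)
    strand <- map$features$strand[map$features$name == gene][1]
    if (identical(strand, "-")) gseq <- revcomp(gseq)
    gl <- nchar(gseq)
    ncod <- gl %/% 3L
    if (ncod < 3L) next
    codons <- substring(gseq, seq(1L, by = 3L, length.out = ncod),
                        seq(3L, by = 3L, length.out = ncod))
    stops <- which(codons %in% STOP_CODONS)
    stops <- stops[stops < ncod]       # terminal stop is not a disruption
    for (s in stops) {
      q_start <- q_lo + (s - 1L) * 3L  # first base of the stop codon (allele)
      q_end <- q_start + 2L
      ## report the reference coordinate aligned to the codon start
      rpos <- which(a$map == q_start)
      pos <- if (length(rpos)) rpos[1] else iv["start"]
      context <- substr(seq, max(1L, q_end - 11L), q_end)
      add(gene, "premature_stop", pos, context)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      allele_id = character(0), gene = character(0), kind = character(0),
      pos = integer(0), context = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}
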