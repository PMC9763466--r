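## ---- indel calling ----------------------------------------------------------

.empty_events <- function() {
  data.frame(
    allele_id = character(0), pos = integer(0), type = character(0),
    seq = character(0), len = integer(0), direct_repeat = character(0),
    copies = integer(0), compound = logical(0), partial = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Call indels of an allele against the reference
#'
#' Pairwise global alignment; gap runs of at least `min_len` become events.
#' Every event is left-aligned (shifted to its 5'-most equivalent placement)
#' and reported at the reference coordinate of the last unchanged nucleotide
#' before the modification. Events closer than 3 nt to each other are flagged
#' `compound` (the alignment cannot uniquely decompose them); insertions
#' containing `N` (unresolved repeat content from phasing) are flagged
#' `partial`, their length a lower bound.
#'
#' @param allele a `phased_allele` or DNA string.
#' @param map a [ref_map()] object.
#' @param min_len minimum event length in nt (default 3: indels longer than
#'   2 nucleotides).
#' @param cache optional [alignment_cache()].
#' @return data.frame of events (`allele_id`, `pos`, `type` in del/ins,
#'   `seq`, `len`, `direct_repeat`, `copies`, `compound`, `partial`).
#' @export
call_indels <- function(allele, map, min_len = 3L, cache = NULL) {
  seq <- allele_seq_of(allele)
  id <- allele_id_of(allele)
  a <- cached_align(cache, id, seq, map$sequence)
  ref_chars <- seq_chars(map$sequence)
  ops <- alignment_ops(a, ref_chars)
  ops <- Filter(function(o) o$type %in% c("ins", "del") && nchar(o$seq) >= min_len, ops)
  if (length(ops) == 0) return(.empty_events())
  df <- data.frame(
    allele_id = id,
    pos = vapply(ops, function(o) as.integer(o$pos), integer(1)),
    type = vapply(ops, function(o) o$type, character(1)),
    seq = vapply(ops, function(o) o$seq, character(1)),
    stringsAsFactors = FALSE
  )
  df$len <- nchar(df$seq)
  df$direct_repeat <- ""
  df$copies <- 1L
  df <- df[order(df$pos), , drop = FALSE]
  ## footprint intervals for the compound flag
  lo <- df$pos
  hi <- ifelse(df$type == "del", df$pos + df$len + 1L, df$pos + 1L)
  n <- nrow(df)
  df$compound <- FALSE
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      if (lo[i + 1L] - hi[i] < 3L) {
        df$compound[c(i, i + 1L)] <- TRUE
      }
    }
  }
  df$partial <- df$type == "ins" & grepl("N", df$seq, fixed = TRUE)
  rownames(df) <- NULL
  df
}

## smallest period t of string s (s is a whole number of repeats of s[1..t])
.smallest_period <- function(s) {
  n <- nchar(s)
  ch <- seq_chars(s)
  for (t in seq_len(n)) {
    if (n %% t != 0L) next
    if (all(ch == rep(ch[seq_len(t)], n %/% t))) return(t)
  }
  n
}

#' Re-type an insertion as a tandem duplication
#'
#' An insertion whose repeat unit equals the reference segment immediately
#' 5' (or, for the left-aligned representation, immediately 3') of the
#' insertion point is a tandem duplication of local sequence; `copies` is
#' the number of inserted unit copies.
#'
#' @param event one-row data.frame as produced by [call_indels()].
#' @param map a [ref_map()] object.
#' @param min_unit minimum duplication unit length (shorter periodic inserts
#'   are microsatellite-like and stay `ins`).
#' @return the event row, re-typed to `dupl` when the check succeeds.
#' @export
detect_tandem_duplication <- function(event, map, min_unit = 3L) {
  if (event$type != "ins") return(event)
  ref <- map$sequence
  s <- event$seq
  L <- nchar(s)
  t <- .smallest_period(s)
  if (t < min_unit) return(event)
  unit <- substr(s, 1L, t)
  pos <- event$pos
  before <- if (pos - t + 1L >= 1L) substr(ref, pos - t + 1L, pos) else ""
  after <- if (pos + t <= nchar(ref)) substr(ref, pos + 1L, pos + t) else ""
  if (identical(unit, before) || identical(unit, after)) {
    event$type <- "dupl"
    event$copies <- as.integer(L %/% t)
    event$seq <- s
  }
  event
}

#' Classify an insertion as a plant insert with a direct-repeat flank
#'
#' A plant sequence inserted into the locus duplicates a short target motif,
#' leaving the motif immediately on both sides of the insert in the carrier
#' allele. Under the left-aligned representation the duplicated motif appears
#' as the insert's head and as the reference sequence immediately after the
#' insertion point; the detector also accepts the unnormalized tail-side
#' placement. The longest duplicated k-mer (`3 <= k <= max_tsd`) wins.
#'
#' @param event one-row data.frame as produced by [call_indels()].
#' @param map a [ref_map()] object.
#' @param allele unused; accepted for call-site symmetry with the other
#'   classifiers.
#' @param max_tsd maximum direct-repeat length searched.
#' @return the event row, re-typed to `plant_insert` with `direct_repeat`
#'   set when a duplicated motif is found.
#' @export
classify_plant_insert <- function(event, map, allele = NULL, max_tsd = 12L) {
  if (event$type != "ins") return(event)
  ref <- map$sequence
  s <- event$seq
  L <- nchar(s)
  if (L < 3L) return(event)
  pos <- event$pos
  best <- ""
  for (k in seq(min(max_tsd, L), 3L)) {
    head_motif <- substr(s, 1L, k)
    tail_motif <- substr(s, L - k + 1L, L)
    after <- if (pos + k <= nchar(ref)) substr(ref, pos + 1L, pos + k) else ""
    before <- if (pos - k + 1L >= 1L) substr(ref, pos - k + 1L, pos) else ""
    if (identical(head_motif, after)) { best <- head_motif; break }
    if (identical(tail_motif, before)) { best <- tail_motif; break }
  }
  if (nzchar(best)) {
    event$type <- "plant_insert"
    event$direct_repeat <- best
  }
  event
}

#' Apply duplication and plant-insert classification to called events
#'
#' @param events data.frame from [call_indels()].
#' @param map a [ref_map()] object.
#' @param max_tsd maximum direct-repeat length searched.
#' @return the events with `ins` rows re-typed where appropriate (tandem
#'   duplication checked first).
#' @export
classify_insertions <- function(events, map, max_tsd = 12L) {
  if (nrow(events) == 0) return(events)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, , drop = FALSE]
    ev <- detect_tandem_duplication(ev, map)
    ev <- classify_plant_insert(ev, map, max_tsd = max_tsd)
    events[i, ] <- ev
  }
  events
}

#' Aggregate per-allele indel events into a catalog
#'
#' Events sharing (position, type, normalized sequence) merge into one row;
#' `x` counts the carrying alleles.
#'
#' @param events data.frame of per-allele events (rbind of [call_indels()]
#'   outputs, possibly classified).
#' @return catalog data.frame sorted by position with columns `pos`, `type`,
#'   `seq`, `len`, `direct_repeat`, `copies`, `x`, `alleles`
#'   (comma-separated carrier ids).
#' @export
aggregate_catalog <- function(events) {
  if (nrow(events) == 0) {
    return(data.frame(
      pos = integer(0), type = character(0), seq = character(0),
      len = integer(0), direct_repeat = character(0), copies = integer(0),
      x = integer(0), alleles = character(0), stringsAsFactors = FALSE
    ))
  }
  key <- paste(events$pos, events$type, events$seq, sep = "|")
  split_idx <- split(seq_len(nrow(events)), key)
  rows <- lapply(split_idx, function(ii) {
    e <- events[ii[1], , drop = FALSE]
    carriers <- sort(unique(events$allele_id[ii]))
    data.frame(
      pos = e$pos, type = e$type, seq = e$seq, len = e$len,
      direct_repeat = e$direct_repeat, copies = e$copies,
      x = length(carriers), alleles = paste(carriers, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$type, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report hypervariable regions of the catalog
#'
#' Slides a window over catalog positions and reports maximal intervals in
#' which some window contains at least `min_events` distinct modified
#' positions (distinct positions, not rows: one position carrying many
#' alternative events counts once).
#'
#' @param catalog data.frame from [aggregate_catalog()].
#' @param window window width in nt.
#' @param min_events minimum distinct positions within one window.
#' @return data.frame with columns `start`, `end`, `n_positions`.
#' @export
report_hypervariable_regions <- function(catalog, window = 15L, min_events = 5L) {
  empty <- data.frame(start = integer(0), end = integer(0), n_positions = integer(0))
  if (nrow(catalog) == 0) return(empty)
  pos <- sort(unique(catalog$pos))
  qualified <- logical(length(pos))
  for (i in seq_along(pos)) {
    inw <- pos >= pos[i] & pos <= pos[i] + window - 1L
    if (sum(inw) >= min_events) qualified <- qualified | inw
  }
  qp <- pos[qualified]
  if (length(qp) == 0) return(empty)
  breaks <- c(0L, which(diff(qp) > window), length(qp))
  rows <- lapply(seq_len(length(breaks) - 1L), function(b) {
    run <- qp[(breaks[b] + 1L):breaks[b + 1L]]
    data.frame(start = min(run), end = max(run), n_positions = length(run))
  })
  do.call(rbind, rows)
}

#' Write a hypervariable-region report as BED
#'
#' BED uses 0-based half-open intervals; the catalog's 1-based inclusive
#' `start`/`end` convert as `start-1`/`end`.
#'
#' @param regions data.frame from [report_hypervariable_regions()].
#' @param path output path.
#' @param chrom chromosome/sequence name for the BED records.
#' @return invisibly, the path.
#' @export
write_regions_bed <- function(regions, path, chrom = "reference") {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = sprintf("hypervariable_%d", seq_len(nrow(regions)))
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
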