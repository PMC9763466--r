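## ---- empty-site vs filled-site comparison -----------------------------------

## positions of k-mers that occur exactly once in each of two sequences and
## are shared between them
.shared_unique_kmers <- function(x, y, k) {
  kx <- substring(x, 1:(nchar(x) - k + 1L), k:nchar(x))
  ky <- substring(y, 1:(nchar(y) - k + 1L), k:nchar(y))
  ux <- names(which(table(kx) == 1L))
  uy <- names(which(table(ky) == 1L))
  shared <- intersect(ux, uy)
  data.frame(
    pe = match(shared, kx),
    pf = match(shared, ky)
  )
}

## collapse colinear anchors on the same diagonal into blocks, then chain the
## blocks (both coordinates strictly increasing) by maximal covered length
.chain_blocks <- function(anchors, k, max_gap = 50L) {
  a <- anchors[order(anchors$pe, anchors$pf), , drop = FALSE]
  d <- a$pf - a$pe
  blocks <- list()
  i <- 1L
  n <- nrow(a)
  while (i <= n) {
    j <- i
    while (j < n && d[j + 1L] == d[i] && a$pe[j + 1L] - a$pe[j] <= max_gap) j <- j + 1L
    blocks[[length(blocks) + 1L]] <- data.frame(
      e1 = a$pe[i], e2 = a$pe[j] + k - 1L,
      f1 = a$pf[i], f2 = a$pf[j] + k - 1L,
      len = a$pe[j] + k - a$pe[i]
    )
    i <- j + 1L
  }
  b <- do.call(rbind, blocks)
  b <- b[order(b$e1), , drop = FALSE]
  nb <- nrow(b)
  ## DP chain: maximize covered length, e and f both increasing; chance
  ## matches at junctions may extend a block a few bases into a divergent
  ## region, so overlaps smaller than k are tolerated (trimmed downstream)
  best <- b$len
  prev <- rep(0L, nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(i - 1L)) {
      ok <- b$e1[j] < b$e1[i] && b$f1[j] < b$f1[i] &&
        b$e2[j] < b$e1[i] + k && b$f2[j] < b$f1[i] + k
      if (ok && best[j] + b$len[i] > best[i]) {
        best[i] <- best[j] + b$len[i]
        prev[i] <- j
      }
    }
  }
  chain <- integer(0)
  i <- which.max(best)
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  b[chain, , drop = FALSE]
}

#' Align an empty-site sequence against a filled-site sequence
#'
#' Chains exact unique k-mer anchors colinearly and reports every gap between
#' consecutive chained blocks as a structure: segments present only in the
#' filled sequence (`filled_only`, e.g. the inserted cT-DNA or sequences
#' ligated to it) and segments present only in the empty-site sequence
#' (`empty_only`, sequence lost in the filled lineage). Block boundaries are
#' refined base-by-base; when flank duplication makes the boundary ambiguous
#' the call is shifted to a canonical placement (overlaps are trimmed from
#' the downstream block).
#'
#' @param empty DNA string of the empty-site (insertion-free) locus.
#' @param filled DNA string of the filled locus.
#' @param k anchor k-mer length.
#' @param min_len minimum reported structure length.
#' @return data.frame of insert calls: `insert_id`, `kind`, `start`, `end`
#'   (1-based inclusive on the carrier sequence), `length`, `carrier`
#'   (`filled`/`empty`), plus empty `tsd`/`terminal_ir` fields to be filled
#'   by [detect_tsd()] and [detect_terminal_ir()].
#' @export
align_empty_vs_filled <- function(empty, filled, k = 21L, min_len = 1L) {
  anchors <- .shared_unique_kmers(empty, filled, k)
  if (nrow(anchors) == 0) stop("no colinear chain found between the sequences")
  blocks <- .chain_blocks(anchors, k)
  if (nrow(blocks) == 0) stop("no colinear chain found between the sequences")
  ec <- seq_chars(empty); fc <- seq_chars(filled)

  ## extend block boundaries base-by-base
  nb <- nrow(blocks)
  for (i in seq_len(nb)) {
    while (blocks$e1[i] > 1L && blocks$f1[i] > 1L &&
           ec[blocks$e1[i] - 1L] == fc[blocks$f1[i] - 1L] &&
           (i == 1L || (blocks$e1[i] - 1L > blocks$e2[i - 1L] ||
                        blocks$f1[i] - 1L > blocks$f2[i - 1L]))) {
      blocks$e1[i] <- blocks$e1[i] - 1L
      blocks$f1[i] <- blocks$f1[i] - 1L
    }
    while (blocks$e2[i] < length(ec) && blocks$f2[i] < length(fc) &&
           ec[blocks$e2[i] + 1L] == fc[blocks$f2[i] + 1L] &&
           (i == nb || (blocks$e2[i] + 1L < blocks$e1[i + 1L] ||
                        blocks$f2[i] + 1L < blocks$f1[i + 1L]))) {
      blocks$e2[i] <- blocks$e2[i] + 1L
      blocks$f2[i] <- blocks$f2[i] + 1L
    }
  }

  calls <- list()
  add_call <- function(kind, start, end, carrier) {
    calls[[length(calls) + 1L]] <<- data.frame(
      kind = kind, start = start, end = end, length = end - start + 1L,
      carrier = carrier, tsd = "", tsd_len = 0L,
      terminal_ir_len = 0L, terminal_ir_seq = "", stringsAsFactors = FALSE
    )
  }
  if (nb > 1) {
    for (i in seq_len(nb - 1L)) {
      gap_e <- blocks$e1[i + 1L] - blocks$e2[i] - 1L
      gap_f <- blocks$f1[i + 1L] - blocks$f2[i] - 1L
      ## trim block overlaps created by duplicated flank sequence
      while (gap_e < 0L || gap_f < 0L) {
        o <- max(-gap_e, -gap_f)
        blocks$e1[i + 1L] <- blocks$e1[i + 1L] + o
        blocks$f1[i + 1L] <- blocks$f1[i + 1L] + o
        gap_e <- gap_e + o
        gap_f <- gap_f + o
      }
      if (gap_f >= min_len && gap_e == 0L) {
        add_call("filled_only", blocks$f2[i] + 1L, blocks$f1[i + 1L] - 1L, "filled")
      } else if (gap_e >= min_len && gap_f == 0L) {
        add_call("empty_only", blocks$e2[i] + 1L, blocks$e1[i + 1L] - 1L, "empty")
      } else if (gap_e > 0L && gap_f > 0L) {
        add_call("filled_only", blocks$f2[i] + 1L, blocks$f1[i + 1L] - 1L, "filled")
        add_call("empty_only", blocks$e2[i] + 1L, blocks$e1[i + 1L] - 1L, "empty")
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(
      insert_id = character(0), kind = character(0), start = integer(0),
      end = integer(0), length = integer(0), carrier = character(0),
      tsd = character(0), tsd_len = integer(0), terminal_ir_len = integer(0),
      terminal_ir_seq = character(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, calls)
  out <- cbind(insert_id = sprintf("ins%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect a target-site duplication at an insert's flanks
#'
#' Searches for the longest k-mer (`3 <= k <= max_len`) duplicated on both
#' sides of the insert: either already duplicated at the two immediate flanks
#' of the call interval, or shifted into the insert's own head/tail (the
#' equivalent placements of an insertion between duplicated motifs), in which
#' case the interval is shrunk to the insert core so the motif lies once on
#' each flank.
#'
#' @param call one-row data.frame as from [align_empty_vs_filled()].
#' @param seq the carrier sequence (the sequence the `start`/`end` refer to).
#' @param max_len maximum duplication length searched.
#' @return the call with `tsd`, `tsd_len`, and possibly adjusted interval.
#' @export
detect_tsd <- function(call, seq, max_len = 15L) {
  n <- nchar(seq)
  ch <- seq_chars(seq)
  if (is.null(call$tsd)) call$tsd <- ""
  if (is.null(call$tsd_len)) call$tsd_len <- 0L
  sub <- function(a, b) if (a >= 1L && b <= n && a <= b) substr(seq, a, b) else NULL

  ## enumerate equivalent placements of the call interval (the boundary is
  ## ambiguous wherever flank and insert share characters)
  placements <- list(c(call$start, call$end))
  s <- call$start; e <- call$end
  for (i in seq_len(max_len + 3L)) {
    if (s - 1L < 1L || ch[e] != ch[s - 1L]) break
    s <- s - 1L; e <- e - 1L
    placements[[length(placements) + 1L]] <- c(s, e)
  }
  s <- call$start; e <- call$end
  for (i in seq_len(max_len + 3L)) {
    if (e + 1L > n || ch[e + 1L] != ch[s]) break
    s <- s + 1L; e <- e + 1L
    placements[[length(placements) + 1L]] <- c(s, e)
  }

  best_k <- 0L; best_motif <- ""; best_iv <- c(call$start, call$end)
  for (pl in placements) {
    s <- pl[1]; e <- pl[2]
    for (k in seq_len(min(max_len, e - s + 1L))) {
      before <- sub(s - k, s - 1L)
      after <- sub(e + 1L, e + k)
      head_m <- sub(s, s + k - 1L)
      tail_m <- sub(e - k + 1L, e)
      if (!is.null(before) && !is.null(after) && identical(before, after) &&
          k > best_k) {
        best_k <- k; best_motif <- before; best_iv <- c(s, e)
      }
      if (!is.null(before) && !is.null(tail_m) && identical(before, tail_m) &&
          k > best_k && e - k >= s) {
        best_k <- k; best_motif <- before; best_iv <- c(s, e - k)
      }
      if (!is.null(after) && !is.null(head_m) && identical(after, head_m) &&
          k > best_k && s + k <= e) {
        best_k <- k; best_motif <- after; best_iv <- c(s + k, e)
      }
    }
  }
  if (best_k >= 3L) {
    call$tsd <- best_motif
    call$tsd_len <- best_k
    call$start <- best_iv[1]
    call$end <- best_iv[2]
    call$length <- best_iv[2] - best_iv[1] + 1L
  }
  call
}

#' Detect a terminal inverted repeat at an insert's ends
#'
#' Finds the longest prefix whose reverse complement equals the insert's
#' suffix, allowing at most `max_mismatch` mismatches (brute-force scan over
#' prefix lengths, longest first).
#'
#' @param call one-row data.frame as from [align_empty_vs_filled()] (after
#'   [detect_tsd()] if boundary shifting is wanted).
#' @param seq the carrier sequence.
#' @param min_len minimum repeat length reported.
#' @param max_mismatch allowed mismatches between prefix and
#'   reverse-complemented suffix.
#' @return the call with `terminal_ir_len` and `terminal_ir_seq` set (0 and
#'   empty when no terminal complementarity of at least `min_len` exists).
#' @export
detect_terminal_ir <- function(call, seq, min_len = 5L, max_mismatch = 0L) {
  ins <- substr(seq, call$start, call$end)
  L <- nchar(ins)
  call$terminal_ir_len <- 0L
  call$terminal_ir_seq <- ""
  if (L < 2L * min_len) return(call)
  ins_chars <- seq_chars(ins)
  rc_chars <- seq_chars(revcomp(ins))
  for (len in seq(L %/% 2L, min_len)) {
    mm <- sum(ins_chars[seq_len(len)] != rc_chars[seq_len(len)])
    if (mm <= max_mismatch) {
      call$terminal_ir_len <- as.integer(len)
      call$terminal_ir_seq <- substr(ins, 1L, len)
      break
    }
  }
  call
}

#' Presence of an insert across additional empty-site sequences
#'
#' @param call a call row with `tsd` context on its carrier.
#' @param seq the carrier sequence.
#' @param others named character vector of other sequences to screen.
#' @param k probe k-mer length taken from the insert interior.
#' @return named logical vector: does each other sequence contain the probe?
#' @export
insert_presence <- function(call, seq, others, k = 31L) {
  ins <- substr(seq, call$start, call$end)
  if (nchar(ins) < k) k <- nchar(ins)
  probe <- substr(ins, max(1L, (nchar(ins) - k) %/% 2L), max(1L, (nchar(ins) - k) %/% 2L) + k - 1L)
  vapply(others, function(s) {
    grepl(probe, s, fixed = TRUE) || grepl(revcomp(probe), s, fixed = TRUE)
  }, logical(1))
}
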