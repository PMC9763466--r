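## ---- read recruitment -----------------------------------------------------

## k-mer anchoring constants
.ANCHOR_K <- 13L
.ANCHOR_STEP <- 7L

## per-orientation k-mer anchoring: for each read, the modal reference offset
## and the number of supporting seed k-mers
.anchor_offsets <- function(seqs, ref_kmers, k, step) {
  n_reads <- length(seqs)
  rl <- nchar(seqs)
  res_off <- integer(n_reads); res_votes <- integer(n_reads)
  res_multi <- logical(n_reads)
  ## group reads by length so substring() vectorizes
  for (L in unique(rl)) {
    idx <- which(rl == L)
    if (L < k) { res_off[idx] <- NA; next }
    starts <- unique(c(seq(1L, L - k + 1L, by = step), L - k + 1L))
    ns <- length(starts)
    big <- substring(rep(seqs[idx], each = ns), rep(starts, length(idx)),
                     rep(starts + k - 1L, length(idx)))
    hit <- match(big, ref_kmers)
    off <- hit - rep(starts, length(idx)) + 1L
    for (j in seq_along(idx)) {
      o <- off[((j - 1L) * ns + 1L):(j * ns)]
      o <- o[!is.na(o)]
      if (length(o) == 0) { res_off[idx[j]] <- NA_integer_; next }
      tab <- table(o)
      res_off[idx[j]] <- as.integer(names(tab)[which.max(tab)])
      res_votes[idx[j]] <- max(tab)
      res_multi[idx[j]] <- sum(tab >= 2L) > 1L
    }
  }
  list(offset = res_off, votes = res_votes, multi = res_multi)
}

#' Recruit reads homologous to the reference locus
#'
#' Seed-and-extend recruitment: reads are anchored on the reference by exact
#' 13-mer seeds in both orientations; anchored reads are verified by
#' base-level identity over the overlap (with an affine-gap alignment
#' fallback for reads whose seeds disagree, i.e. indel-spanning reads).
#' Retained reads are reverse-complemented into reference orientation.
#'
#' @param reads data.frame with columns `id`, `seq` (as from [read_fastq()]),
#'   or a character vector of read sequences.
#' @param map a [ref_map()] object.
#' @param min_identity minimum identity over the overlap (fraction).
#' @param min_overlap minimum overlap with the reference (nt).
#' @param accession accession label carried through to downstream reports.
#' @return object of class `recruited_reads`: data.frame of retained reads
#'   (`id`, `seq` in reference orientation, `anchor` = 1-based reference
#'   position of the read start, `strand`, `identity`, `dp` flag), plus the
#'   locus mean coverage.
#' @export
recruit_reads <- function(reads, map, min_identity = 0.8, min_overlap = 50L,
                          accession = "sample") {
  if (is.character(reads)) {
    reads <- data.frame(
      id = sprintf("read%05d", seq_along(reads)),
      seq = unname(reads), stringsAsFactors = FALSE
    )
  }
  ref <- map$sequence
  n <- nchar(ref)
  empty <- data.frame(
    id = character(0), seq = character(0), anchor = integer(0),
    strand = character(0), identity = numeric(0), dp = logical(0),
    stringsAsFactors = FALSE
  )
  out <- list(accession = accession, reads = empty, mean_coverage = 0,
              ref_len = n)
  class(out) <- "recruited_reads"
  if (nrow(reads) == 0) return(out)

  k <- .ANCHOR_K
  ref_kmers <- substring(ref, 1:(n - k + 1L), k:n)
  fwd <- reads$seq
  rcv <- revcomp(fwd)
  af <- .anchor_offsets(fwd, ref_kmers, k, .ANCHOR_STEP)
  ar <- .anchor_offsets(rcv, ref_kmers, k, .ANCHOR_STEP)

  ref_int <- utf8ToInt(ref)
  ## mismatch count of a read placed at a given offset (NA if placement
  ## impossible)
  place_mm <- function(seq, o) {
    if (is.na(o)) return(NA_integer_)
    rl <- nchar(seq)
    lo <- max(1L, o); hi <- min(n, o + rl - 1L)
    if (hi < lo) return(NA_integer_)
    sum(utf8ToInt(seq)[(lo - o + 1L):(hi - o + 1L)] != ref_int[lo:hi])
  }

  use_rc <- ar$votes > af$votes
  ## seed-count ties (e.g. reads from inside an inverted repeat, which match
  ## both copies): resolve by base-level mismatches of the two placements;
  ## exact ties are ambiguous placements and are dropped, as standard
  ## mapping-quality filtering would do
  ambiguous <- logical(nrow(reads))
  tie <- which(ar$votes == af$votes & af$votes > 0L)
  for (i in tie) {
    mf <- place_mm(fwd[i], af$offset[i])
    mr <- place_mm(rcv[i], ar$offset[i])
    if (!is.na(mf) && !is.na(mr) && mf == mr) { ambiguous[i] <- TRUE; next }
    use_rc[i] <- !is.na(mr) && (is.na(mf) || mr < mf)
  }
  offset <- ifelse(use_rc, ar$offset, af$offset)
  multi <- ifelse(use_rc, ar$multi, af$multi)
  oriented <- ifelse(use_rc, rcv, fwd)
  strand <- ifelse(use_rc, "-", "+")
  keep <- logical(nrow(reads))
  anchor <- integer(nrow(reads))
  ident <- numeric(nrow(reads))
  dpflag <- logical(nrow(reads))
  need_dp <- integer(0)

  for (i in seq_len(nrow(reads))) {
    o <- offset[i]
    if (is.na(o) || ambiguous[i]) next
    rl <- nchar(oriented[i])
    if (isTRUE(multi[i])) { need_dp <- c(need_dp, i); next }
    lo <- max(1L, o); hi <- min(n, o + rl - 1L)
    ov <- hi - lo + 1L
    if (ov < min_overlap) next
    rseg <- utf8ToInt(oriented[i])[(lo - o + 1L):(hi - o + 1L)]
    neq <- rseg != ref_int[lo:hi]
    mm <- sum(neq)
    id_frac <- 1 - mm / ov
    ## a dense mismatch run at either end is the signature of an indel near
    ## the read end (too close for the seed vote to notice): realign
    w <- min(25L, ov)
    end_run <- sum(neq[seq_len(w)]) >= 10L ||
      sum(neq[(ov - w + 1L):ov]) >= 10L
    if (id_frac >= min_identity && !end_run) {
      keep[i] <- TRUE; anchor[i] <- lo; ident[i] <- id_frac
    } else if (end_run || mm / ov < 2 * (1 - min_identity) + 0.1) {
      need_dp <- c(need_dp, i)   # borderline: maybe an indel shifted things
    }
  }

  for (i in need_dp) {
    o <- offset[i]
    rl <- nchar(oriented[i])
    wlo <- max(1L, o - 80L); whi <- min(n, o + rl + 80L)
    window <- substr(ref, wlo, whi)
    aln <- Biostrings::pairwiseAlignment(
      pattern = oriented[i], subject = window, type = "global-local",
      substitutionMatrix = .ctdna_submat(), gapOpening = 4, gapExtension = 1
    )
    ## identity over aligned columns: inserted bases (e.g. a plant insert
    ## carried by the read but absent from the reference) are not mismatches
    nm <- Biostrings::nmatch(aln)
    ov2 <- nm + Biostrings::nmismatch(aln)
    id_frac <- if (ov2 > 0) nm / ov2 else 0
    sp <- Biostrings::start(Biostrings::subject(aln)) + wlo - 1L
    if (ov2 >= min_overlap && id_frac >= min_identity) {
      keep[i] <- TRUE; anchor[i] <- sp; ident[i] <- id_frac; dpflag[i] <- TRUE
    }
  }

  res <- data.frame(
    id = reads$id[keep], seq = oriented[keep], anchor = anchor[keep],
    strand = strand[keep], identity = ident[keep], dp = dpflag[keep],
    stringsAsFactors = FALSE
  )
  out$reads <- res
  out$mean_coverage <- sum(nchar(res$seq)) / n
  out
}

#' @export
print.recruited_reads <- function(x, ...) {
  cat("recruited reads:", nrow(x$reads), "reads, mean coverage",
      round(x$mean_coverage, 2), "x over", x$ref_len, "nt\n")
  invisible(x)
}

## ---- per-read variant extraction ------------------------------------------

op_key <- function(type, pos, seq) paste(type, pos, seq, sep = ":")

parse_op_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  list(type = parts[1], pos = as.integer(parts[2]), seq = parts[3])
}

## ops + covered reference span for one recruited read
.read_ops <- function(seq, anchor, dp, ref, ref_chars, ref_int, n) {
  rl <- nchar(seq)
  if (!dp) {
    lo <- max(1L, anchor); hi <- min(n, anchor + rl - 1L)
    rseg <- utf8ToInt(seq)[(lo - anchor + 1L):(hi - anchor + 1L)]
    mism <- which(rseg != ref_int[lo:hi])
    keys <- if (length(mism)) {
      op_key("sub", lo + mism - 1L, intToUtf8(rseg[mism], multiple = TRUE))
    } else character(0)
    return(list(keys = keys, span = c(lo, hi)))
  }
  wlo <- max(1L, anchor - 100L); whi <- min(n, anchor + rl + 100L)
  a <- align_pair(seq, substr(ref, wlo, whi), type = "global-local")
  rpos <- cumsum(a$r != "-") + a$sub_off + wlo - 1L
  ## soft-clip emulation: the aligner must place the whole read, so a read
  ## starting or ending inside an insertion smears its overhang as dense
  ## mismatches; keep only the region between the outermost clean match runs
  is_match <- a$q == a$r & a$q != "-"
  rr <- rle(is_match)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1L
  clean <- which(rr$values & rr$lengths >= 15L)
  if (length(clean) == 0) {
    return(list(keys = character(0), span = c(NA_integer_, NA_integer_)))
  }
  keep_lo <- starts[clean[1]]
  keep_hi <- ends[clean[length(clean)]]
  ops <- alignment_ops(a, ref_chars, ref_offset = wlo - 1L)
  lo_pos <- rpos[keep_lo]; hi_pos <- rpos[keep_hi]
  ops <- Filter(function(o) o$pos >= lo_pos && o$pos <= hi_pos, ops)
  keys <- vapply(ops, function(o) op_key(o$type, o$pos, o$seq), character(1))
  list(keys = keys, span = c(lo_pos, hi_pos))
}

## ---- allele phasing --------------------------------------------------------

#' Separate recruited reads into one or two haplotype alleles
#'
#' Pileup against the reference identifies candidate variant columns
#' (positions where two states each have at least `min_var_reads` supporting
#' reads and a minor fraction of at least `min_minor_frac`; singleton
#' discrepancies are treated as sequencing error). Reads are then partitioned
#' into at most two groups by transitive linkage over shared variant columns,
#' requiring exact within-group agreement (`max_within_allele_mismatch = 0`:
#' the strictest separation, able to split alleles down to a handful of
#' differences over the locus). Each group yields an indel-aware majority
#' consensus built on the reference scaffold.
#'
#' @param readset a `recruited_reads` object from [recruit_reads()].
#' @param map a [ref_map()] object.
#' @param min_coverage minimum mean fold coverage over the locus; below it
#'   the accession is flagged `insufficient` and no sequence is emitted.
#' @param max_within_allele_mismatch allowed disagreements at shared variant
#'   columns within a group (default 0).
#' @param min_var_reads minimum reads supporting each state of a variant column.
#' @param min_minor_frac minimum minor-state fraction of a variant column.
#' @return object of class `phasing_result`: `status` (`paired`, `unique`, or
#'   `insufficient`), `alleles` (list of `phased_allele`: `accession`,
#'   `allele_index`, `sequence`, `n_reads`, `mean_depth`, `status`),
#'   `n_variant_columns`, `n_conflicting_reads`, and `excess_haplotypes` flag.
#' @export
phase_alleles <- function(readset, map, min_coverage = 10,
                          max_within_allele_mismatch = 0L,
                          min_var_reads = 2L, min_minor_frac = 0.2) {
  stopifnot(inherits(readset, "recruited_reads"))
  acc <- readset$accession
  result <- list(
    accession = acc, status = "insufficient", alleles = list(),
    n_variant_columns = 0L, n_conflicting_reads = 0L,
    excess_haplotypes = FALSE, mean_coverage = readset$mean_coverage
  )
  class(result) <- "phasing_result"
  if (nrow(readset$reads) == 0 || readset$mean_coverage < min_coverage) {
    return(result)
  }

  ref <- map$sequence
  n <- nchar(ref)
  ref_chars <- seq_chars(ref)
  ref_int <- utf8ToInt(ref)
  rd <- readset$reads
  nr <- nrow(rd)

  read_keys <- vector("list", nr)
  span_lo <- integer(nr); span_hi <- integer(nr)
  for (i in seq_len(nr)) {
    ro <- .read_ops(rd$seq[i], rd$anchor[i], rd$dp[i], ref, ref_chars, ref_int, n)
    read_keys[[i]] <- ro$keys
    span_lo[i] <- ro$span[1]; span_hi[i] <- ro$span[2]
  }
  ok <- !is.na(span_lo)
  read_keys <- read_keys[ok]; span_lo <- span_lo[ok]; span_hi <- span_hi[ok]
  nr <- sum(ok)

  ## position coverage (reads covering each reference position)
  covv <- integer(n + 1L)
  for (i in seq_len(nr)) {
    covv[span_lo[i]] <- covv[span_lo[i]] + 1L
    covv[span_hi[i] + 1L] <- covv[span_hi[i] + 1L] - 1L
  }
  covv <- cumsum(covv)[seq_len(n)]

  ## op support
  all_keys <- unlist(read_keys)
  op_support <- if (length(all_keys)) table(all_keys) else table(character(0))
  op_info <- lapply(names(op_support), parse_op_key)
  op_pos <- vapply(op_info, function(o) o$pos, integer(1))
  op_type <- vapply(op_info, function(o) o$type, character(1))
  op_len <- vapply(op_info, function(o) nchar(o$seq), integer(1))
  ## span a read must cover to attest the reference state of an op; indel
  ## footprints are padded so only reads with enough flank on both sides
  ## (whose alignment represents the event reliably) enter the denominator
  op_end <- ifelse(op_type == "sub", op_pos,
            ifelse(op_type == "ins", op_pos + 1L, op_pos + op_len + 1L))
  op_pad <- ifelse(op_type == "sub", 0L, 25L)

  ## coverage of the padded footprint per op (reads spanning it fully)
  op_cov <- vapply(seq_along(op_pos), function(j) {
    sum(span_lo <= op_pos[j] - op_pad[j] & span_hi >= op_end[j] + op_pad[j])
  }, integer(1))
  names(op_cov) <- names(op_support)

  ## candidate variant columns: substitution sites away from indels. Columns
  ## near supported indels are excluded from phasing (alignments there admit
  ## alternative representations that mimic heterozygosity); indel
  ## heterozygosity itself is resolved per read group at consensus time.
  supp <- as.integer(op_support)
  names(supp) <- names(op_support)
  mask_pad <- 5L
  indel_j <- which(op_type != "sub" & supp >= 3L)
  masked <- function(p) {
    any(p >= op_pos[indel_j] - mask_pad & p <= op_end[indel_j] + mask_pad)
  }
  col_pos <- integer(0)
  col_states <- list()
  sub_positions <- unique(op_pos[op_type == "sub"])
  for (p in setdiff(sub_positions, sub_positions[vapply(sub_positions, masked, logical(1))])) {
    jj <- which(op_pos == p & op_type == "sub")
    cv <- max(op_cov[jj])
    s_ref <- cv - sum(supp[jj])
    st <- c(setNames(as.integer(supp[jj]), names(supp)[jj]), ref = max(0L, s_ref))
    st <- sort(st, decreasing = TRUE)
    if (length(st) < 2) next
    s1 <- st[1]; s2 <- st[2]
    if (s2 >= min_var_reads && s1 >= min_var_reads &&
        cv > 0 && s2 / cv >= min_minor_frac) {
      col_pos <- c(col_pos, p)
      col_states[[length(col_states) + 1L]] <-
        c(names(st)[1], names(st)[2])
    }
  }
  result$n_variant_columns <- length(col_pos)

  ## helper: key of read i at column position p ("ref" if covering, NA if not)
  key_at <- function(i, p, cend) {
    if (span_lo[i] > p || span_hi[i] < cend) return(NA_character_)
    ks <- read_keys[[i]]
    if (length(ks)) {
      kp <- as.integer(sub("^[a-z]+:([0-9]+):.*$", "\\1", ks))
      hit <- which(kp == p)
      if (length(hit)) return(ks[hit[1]])
    }
    "ref"
  }

  consensus_from <- function(member) {
    ## majority ops among member reads
    keys <- unlist(read_keys[member])
    if (length(keys) == 0) {
      apply_keys <- character(0)
    } else {
      tab <- table(keys)
      apply_keys <- character(0)
      for (kk in names(tab)) {
        j <- match(kk, names(op_support))
        p <- op_pos[j] - op_pad[j]
        cend <- op_end[j] + op_pad[j]
        cv <- sum(span_lo[member] <= p & span_hi[member] >= cend)
        if (cv > 0 && tab[kk] / cv > 0.5 && tab[kk] >= min_var_reads) {
          apply_keys <- c(apply_keys, kk)
        }
      }
    }
    ops <- lapply(apply_keys, parse_op_key)
    chars <- ref_chars
    ## mark uncovered reference positions before applying indels
    covg <- integer(n + 1L)
    for (i in member) {
      covg[span_lo[i]] <- covg[span_lo[i]] + 1L
      covg[span_hi[i] + 1L] <- covg[span_hi[i] + 1L] - 1L
    }
    covg <- cumsum(covg)[seq_len(n)]
    chars[covg == 0L] <- "N"
    seqv <- apply_ops(chars, ops)
    list(seq = paste(seqv, collapse = ""), depth = mean(covg), ops = apply_keys)
  }

  make_allele <- function(index, cons, nreads, status) {
    al <- list(
      accession = acc, allele_index = index, sequence = cons$seq,
      n_reads = nreads, mean_depth = cons$depth, status = status,
      allele_id = paste0(acc, "_", index)
    )
    class(al) <- "phased_allele"
    al
  }

  if (length(col_pos) == 0) {
    cons <- consensus_from(seq_len(nr))
    result$status <- "unique"
    result$alleles <- list(make_allele("un", cons, nr, "unique"))
    return(result)
  }

  ## order columns; seed = best-covered column
  ordc <- order(col_pos)
  col_pos <- col_pos[ordc]; col_states <- col_states[ordc]
  ncol_ <- length(col_pos)
  col_end <- vapply(seq_len(ncol_), function(ci) {
    ks <- setdiff(col_states[[ci]], "ref")
    if (length(ks) == 0) return(col_pos[ci])
    max(op_end[match(ks, names(op_support))])
  }, integer(1))
  col_cov <- vapply(seq_len(ncol_), function(ci)
    sum(span_lo <= col_pos[ci] & span_hi >= col_end[ci]), integer(1))

  ## which columns each read covers (and its state key there)
  read_cols <- lapply(seq_len(nr), function(i)
    which(span_lo[i] <= col_pos & span_hi[i] >= col_end))
  read_col_keys <- lapply(seq_len(nr), function(i) {
    vapply(read_cols[[i]], function(ci)
      key_at(i, col_pos[ci], col_end[ci]), character(1))
  })
  ## inverse index: reads covering each column, with their keys
  col_reads <- vector("list", ncol_)
  col_read_keys <- vector("list", ncol_)
  for (i in seq_len(nr)) {
    for (j in seq_along(read_cols[[i]])) {
      ci <- read_cols[[i]][j]
      col_reads[[ci]] <- c(col_reads[[ci]], i)
      col_read_keys[[ci]] <- c(col_read_keys[[ci]], read_col_keys[[i]][j])
    }
  }

  ## linkage blocks: connected components of columns co-spanned by reads;
  ## phase is read-backed only within a block
  parent <- seq_len(ncol_)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nr)) {
    cs <- read_cols[[i]]
    if (length(cs) > 1) {
      r0 <- find(cs[1])
      for (c2 in cs[-1]) { r2 <- find(c2); if (r2 != r0) parent[r2] <- r0 }
    }
  }
  block_id <- vapply(seq_len(ncol_), find, integer(1))

  assign <- rep(0L, nr)   # 0 unassigned, 1, 2, -1 conflicted
  H1_all <- rep(NA_character_, ncol_); H2_all <- rep(NA_character_, ncol_)
  for (b in unique(block_id)) {
    bcols <- which(block_id == b)
    breads <- sort(unique(unlist(col_reads[bcols])))
    H1 <- rep(NA_character_, ncol_); H2 <- rep(NA_character_, ncol_)
    seed <- bcols[which.max(col_cov[bcols])]
    H1[seed] <- col_states[[seed]][1]
    H2[seed] <- col_states[[seed]][2]
    bassign <- rep(0L, nr)
    max_pass <- length(bcols) + 2L   # propagation crosses one column per pass
    for (pass in seq_len(max_pass)) {
      changed <- FALSE
      for (i in breads) {
        if (bassign[i] %in% c(1L, 2L)) next
        cs <- read_cols[[i]]
        ks <- read_col_keys[[i]]
        def1 <- !is.na(H1[cs]); def2 <- !is.na(H2[cs])
        m1 <- sum(def1 & ks == H1[cs]); c1 <- sum(def1 & ks != H1[cs])
        m2 <- sum(def2 & ks == H2[cs]); c2 <- sum(def2 & ks != H2[cs])
        newg <- 0L
        if (c1 <= max_within_allele_mismatch && m1 > 0 &&
            (c2 > max_within_allele_mismatch || m2 == 0)) newg <- 1L
        if (c2 <= max_within_allele_mismatch && m2 > 0 &&
            (c1 > max_within_allele_mismatch || m1 == 0)) newg <- 2L
        if ((m1 + c1 + m2 + c2) > 0 && c1 > max_within_allele_mismatch &&
            c2 > max_within_allele_mismatch) newg <- -1L
        if (newg != bassign[i]) { bassign[i] <- newg; changed <- TRUE }
      }
      ## extend haplotypes to undefined block columns: the column's two
      ## states are known (its top-2 supported states); assigned reads vote
      ## only on how they pair with the groups
      for (ci in bcols) {
        if (!is.na(H1[ci])) next
        sts <- col_states[[ci]]
        ga <- bassign[col_reads[[ci]]]
        ck <- col_read_keys[[ci]]
        straight <- sum(ga == 1L & ck == sts[1]) + sum(ga == 2L & ck == sts[2])
        crossed <- sum(ga == 1L & ck == sts[2]) + sum(ga == 2L & ck == sts[1])
        if (straight + crossed < min_var_reads || straight == crossed) next
        if (straight > crossed) {
          H1[ci] <- sts[1]; H2[ci] <- sts[2]
        } else {
          H1[ci] <- sts[2]; H2[ci] <- sts[1]
        }
        changed <- TRUE
      }
      if (!changed) break
    }
    ## finalize columns the linkage could not define (too few or tied
    ## linking reads): orient by whatever assigned reads cover them, falling
    ## back to the reference-preferring convention, then sweep once more
    undef <- bcols[is.na(H1[bcols])]
    if (length(undef)) {
      for (ci in undef) {
        sts <- col_states[[ci]]
        ga <- bassign[col_reads[[ci]]]
        ck <- col_read_keys[[ci]]
        straight <- sum(ga == 1L & ck == sts[1]) + sum(ga == 2L & ck == sts[2])
        crossed <- sum(ga == 1L & ck == sts[2]) + sum(ga == 2L & ck == sts[1])
        first <- if (straight != crossed) {
          if (straight > crossed) sts[1] else sts[2]
        } else if ("ref" %in% sts) "ref" else sts[1]
        H1[ci] <- first
        H2[ci] <- setdiff(sts, first)[1]
      }
      for (i in breads) {
        if (bassign[i] %in% c(1L, 2L)) next
        cs <- read_cols[[i]]
        ks <- read_col_keys[[i]]
        def1 <- !is.na(H1[cs]); def2 <- !is.na(H2[cs])
        m1 <- sum(def1 & ks == H1[cs]); c1 <- sum(def1 & ks != H1[cs])
        m2 <- sum(def2 & ks == H2[cs]); c2 <- sum(def2 & ks != H2[cs])
        if (c1 <= max_within_allele_mismatch && m1 > 0 &&
            (c2 > max_within_allele_mismatch || m2 == 0)) bassign[i] <- 1L
        else if (c2 <= max_within_allele_mismatch && m2 > 0 &&
            (c1 > max_within_allele_mismatch || m1 == 0)) bassign[i] <- 2L
        else if ((m1 + c1 + m2 + c2) > 0 && c1 > max_within_allele_mismatch &&
            c2 > max_within_allele_mismatch) bassign[i] <- -1L
      }
    }
    ## orient the block: phase 1 carries the reference-agreeing states
    ## (cross-block phase is not identifiable from short reads; this join is
    ## the package's deterministic convention)
    n_ref1 <- sum(H1[bcols] == "ref", na.rm = TRUE)
    n_ref2 <- sum(H2[bcols] == "ref", na.rm = TRUE)
    flip <- n_ref2 > n_ref1 ||
      (n_ref2 == n_ref1 && sum(bassign == 2L) > sum(bassign == 1L))
    if (flip) {
      bassign[bassign == 1L] <- 3L
      bassign[bassign == 2L] <- 1L
      bassign[bassign == 3L] <- 2L
    }
    sel <- bassign != 0L
    assign[sel] <- bassign[sel]
    H1_all[bcols] <- H1[bcols]
    H2_all[bcols] <- H2[bcols]
  }
  result$diag <- list(
    n_blocks = length(unique(block_id)),
    n_cols = ncol_,
    block_sizes = as.integer(table(block_id)),
    ncols_defined = sum(!is.na(H1_all)),
    col_pos = col_pos, H1 = H1_all, H2 = H2_all, block_id = block_id,
    assign_table = table(factor(assign, levels = c(-1, 0, 1, 2)))
  )

  result$n_conflicting_reads <- sum(assign == -1L)
  if (result$n_conflicting_reads > max(3L, ceiling(0.02 * nr))) {
    result$excess_haplotypes <- TRUE
    warning("read linkage is inconsistent with two haplotypes (",
            result$n_conflicting_reads, " conflicting reads); reporting the ",
            "best two-group partition", call. = FALSE)
  }

  g1 <- which(assign == 1L); g2 <- which(assign == 2L)
  neutral <- which(assign == 0L & vapply(read_cols, length, integer(1)) == 0)
  if (length(g1) < min_var_reads || length(g2) < min_var_reads) {
    cons <- consensus_from(setdiff(seq_len(nr), which(assign == -1L)))
    result$status <- "unique"
    result$alleles <- list(make_allele("un", cons, nr, "unique"))
    return(result)
  }

  cons1 <- consensus_from(c(g1, neutral))
  cons2 <- consensus_from(c(g2, neutral))
  if (identical(cons1$seq, cons2$seq)) {
    result$status <- "unique"
    result$alleles <- list(make_allele("un", cons1, nr, "unique"))
    return(result)
  }
  ## deterministic ordering: larger read group first; ties lexicographic
  if (length(g2) > length(g1) ||
      (length(g2) == length(g1) && cons2$seq < cons1$seq)) {
    tmp <- cons1; cons1 <- cons2; cons2 <- tmp
    tmpg <- g1; g1 <- g2; g2 <- tmpg
  }
  result$status <- "paired"
  result$alleles <- list(
    make_allele("1", cons1, length(g1) + length(neutral), "paired"),
    make_allele("2", cons2, length(g2) + length(neutral), "paired")
  )
  result
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("phasing of", x$accession, ":", x$status, "(",
      length(x$alleles), "allele(s),", x$n_variant_columns,
      "variant columns, coverage", round(x$mean_coverage, 1), "x )\n")
  invisible(x)
}

#' Phase one accession end-to-end (recruit + phase)
#'
#' @param reads data.frame of reads (`id`, `seq`) or character vector.
#' @param map a [ref_map()] object.
#' @param accession accession label.
#' @param ... passed to [recruit_reads()] and [phase_alleles()].
#' @inheritParams phase_alleles
#' @inheritParams recruit_reads
#' @return a `phasing_result`, see [phase_alleles()].
#' @export
phase_accession <- function(reads, map, accession = "sample",
                            min_identity = 0.8, min_overlap = 50L,
                            min_coverage = 10, ...) {
  rs <- recruit_reads(reads, map, min_identity = min_identity,
                      min_overlap = min_overlap, accession = accession)
  phase_alleles(rs, map, min_coverage = min_coverage, ...)
}
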