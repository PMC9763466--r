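#' Default indel spectrum for the population simulator
#'
#' Event templates modeled on the observed catalog of a ~5.3 kb cT-DNA locus:
#' mostly deletions of 3-49 nt, some insertions of 3-40 nt, rare tandem
#' duplications of the preceding 12-20 nt, and plant-derived inserts flanked
#' by a 5-10 nt target-site duplication.
#'
#' @return data.frame with columns `type`, `weight`, `min_len`, `max_len`,
#'   `tsd_min`, `tsd_max`.
#' @export
default_indel_spectrum <- function() {
  data.frame(
    type = c("del", "ins", "dupl", "plant_insert"),
    weight = c(0.66, 0.12, 0.02, 0.20),
    min_len = c(3L, 3L, 12L, 20L),
    max_len = c(49L, 40L, 20L, 60L),
    tsd_min = c(NA, NA, NA, 5L),
    tsd_max = c(NA, NA, NA, 10L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the seeded cT-DNA population generator. Defaults are the
#' study conditions the analysis assumes: a two-clade allele genealogy whose
#' diploid accessions often pair one allele from each clade, terminal
#' inverted repeats diverging at 6.5e-9 substitutions/site/year over 15
#' million years, pairwise allele divergence in the ~0.2-7% range, an indel
#' spectrum per [default_indel_spectrum()], an occasional lineage carrying an
#' inverted-center rearrangement, and error-free 150-nt reads at 50-fold
#' per-haplotype coverage.
#'
#' @param seed integer seed; a fixed seed yields byte-identical outputs.
#' @param n_accessions number of diploid accessions.
#' @param substitution_rate substitutions per site per year (mu).
#' @param insertion_age age of the cT-DNA insertion in years (T).
#' @param dating_convention `"one_sided"` (repeat divergence d = mu*T) or
#'   `"two_sided"` (d = 2*mu*T, the standard two-lineage accumulation).
#' @param clade_divergence expected pairwise divergence between the two
#'   clade ancestors (fraction).
#' @param allele_divergence_range range of per-allele private divergence from
#'   its clade ancestor (fraction, uniform).
#' @param indel_spectrum event template table, see [default_indel_spectrum()].
#' @param n_clade_markers shared marker indels given to each clade ancestor.
#' @param indels_per_allele Poisson mean of private indels per allele.
#' @param p_heterozygous probability an accession carries two distinct alleles.
#' @param p_cross_clade probability a heterozygous accession pairs one allele
#'   from each clade.
#' @param p_rearranged_lineage per-accession probability of the
#'   inverted-center rearranged structure.
#' @param n_homoplasy number of clade-marker indels additionally granted to a
#'   random allele of the opposite clade (recorded as injected homoplasies).
#' @param read_length read length in nt.
#' @param coverage fold coverage per haplotype.
#' @param read_error_rate per-base substitution error probability of reads.
#' @param min_event_separation minimum nt between injected indel events
#'   within one allele (large enough that each event is independently
#'   alignable; events still cluster across alleles).
#' @param sub_guard no substitution is placed within this many nt of an indel
#'   boundary, so injected and called indel representations coincide.
#' @param flank_len plant flank length on each side of the cT-DNA.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_accessions = 20L,
                       substitution_rate = 6.5e-9,
                       insertion_age = 15e6,
                       dating_convention = c("one_sided", "two_sided"),
                       clade_divergence = 0.04,
                       allele_divergence_range = c(0.001, 0.017),
                       indel_spectrum = default_indel_spectrum(),
                       n_clade_markers = 2L,
                       indels_per_allele = 2,
                       p_heterozygous = 0.58,
                       p_cross_clade = 0.5,
                       p_rearranged_lineage = 0.05,
                       n_homoplasy = 0L,
                       read_length = 150L,
                       coverage = 50,
                       read_error_rate = 0,
                       min_event_separation = 60L,
                       sub_guard = 5L,
                       flank_len = 200L) {
  dating_convention <- match.arg(dating_convention)
  probs <- c(p_heterozygous, p_cross_clade, p_rearranged_lineage, read_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (substitution_rate <= 0) stop("substitution_rate must be positive")
  if (insertion_age < 0) stop("insertion_age must be non-negative")
  if (n_accessions < 1) stop("n_accessions must be at least 1")
  cfg <- list(
    seed = as.integer(seed), n_accessions = as.integer(n_accessions),
    substitution_rate = substitution_rate, insertion_age = insertion_age,
    dating_convention = dating_convention,
    clade_divergence = clade_divergence,
    allele_divergence_range = allele_divergence_range,
    indel_spectrum = indel_spectrum,
    n_clade_markers = as.integer(n_clade_markers),
    indels_per_allele = indels_per_allele,
    p_heterozygous = p_heterozygous, p_cross_clade = p_cross_clade,
    p_rearranged_lineage = p_rearranged_lineage,
    n_homoplasy = as.integer(n_homoplasy),
    read_length = as.integer(read_length), coverage = coverage,
    read_error_rate = read_error_rate,
    min_event_separation = as.integer(min_event_separation),
    sub_guard = as.integer(sub_guard),
    flank_len = as.integer(flank_len)
  )
  class(cfg) <- "sim_config"
  cfg
}

## stop-free codon pool (64 codons minus TAA/TAG/TGA)
.codon_pool <- function() {
  all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

## write an open reading frame into chars[start..end]: ATG, stop-free codons,
## terminal TAA at the last full codon, leftover bases stop-neutral
write_orf <- function(chars, start, end) {
  len <- end - start + 1L
  ncod <- len %/% 3L
  pool <- .codon_pool()
  codons <- c("ATG", sample(pool, ncod - 2L, replace = TRUE), "TAA")
  body <- seq_chars(paste(codons, collapse = ""))
  chars[start:(start + ncod * 3L - 1L)] <- body
  if (len %% 3L > 0) {
    chars[(start + ncod * 3L):end] <- rep("A", len %% 3L)
  }
  chars
}

#' Build the ancestral cT-DNA locus
#'
#' Constructs a synthetic reference window with the published locus geometry:
#' `flank_len` nt of plant flank on each side of a 5287-nt cT-DNA whose left
#' inverted repeat (948 nt) is, by construction, identical to the reverse
#' complement of the corresponding part of the right inverted repeat (960 nt)
#' -- the repeats are taken to have been identical at insertion. Open reading
#' frames occupy the acs, susL and rolB intervals (rolB's tail is interrupted
#' by the right repeat, as in the real locus).
#'
#' @param config a [sim_config()] object.
#' @return a [ref_map()] of the ancestral locus.
#' @export
build_ancestral_ctdna <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  off <- config$flank_len - 200L
  n <- 5287L + 2L * config$flank_len
  ft <- data.frame(
    name = c("left_flank", "ctdna", "left_ir", "acs", "susL", "rolB",
             "right_ir", "right_flank"),
    start = c(1L, 201L, 201L, 642L, 2677L, 4218L, 4528L, 5488L) + c(0L, rep(off, 7L)),
    end = c(200L + off, 5487L, 1148L, 1840L, 3657L, 4532L, 5487L, 5687L) +
      c(0L, rep(off, 6L), 2L * off),
    strand = "+",
    stringsAsFactors = FALSE
  )
  ft$start[1] <- 1L
  chars <- seq_chars(random_dna(n))
  iv <- function(f) unlist(ft[ft$name == f, c("start", "end")])
  a <- iv("acs"); s <- iv("susL"); r <- iv("rolB")
  chars <- write_orf(chars, a[1], a[2])
  chars <- write_orf(chars, s[1], s[2])
  chars <- write_orf(chars, r[1], r[2])
  ## the reported position of an insertion is the last unchanged base before
  ## it; keep the known susL landmark position (3182) unambiguous under
  ## left-alignment, as in the real locus (C at codon 2nd position never
  ## forms a stop)
  p3182 <- 3182L + off
  if (chars[p3182] == "G") chars[p3182] <- "C"
  li <- iv("left_ir"); ri <- iv("right_ir")
  unit_len <- ri[2] - ri[1] + 1L          # 960
  u <- chars[li[1]:(li[1] + unit_len - 1L)]
  chars[ri[1]:ri[2]] <- seq_chars(revcomp(paste(u, collapse = "")))
  ref_map(paste(chars, collapse = ""), ft, flank_len = config$flank_len)
}

## complement single bases
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## flip each inverted-repeat position (both copies) with probability
## p_per_copy to a random different base
.ir_flip <- function(chars, map, p_per_copy) {
  for (f in c("left_ir", "right_ir")) {
    iv <- feature_interval(map, f)
    pos <- iv["start"]:iv["end"]
    flip <- runif(length(pos)) < p_per_copy
    chars <- mutate_bases(chars, pos[flip])
  }
  chars
}

#' Apply repeat divergence to a locus
#'
#' Mutates each inverted-repeat copy independently so that the expected
#' pairwise divergence between the two copies is about `divergence` (each
#' position of each copy substituted with probability `divergence / 2`).
#' Used to derive a present-day-like reference locus from the ancestral one.
#'
#' @param map a [ref_map()] object.
#' @param divergence target pairwise repeat divergence (fraction).
#' @param seed optional RNG seed.
#' @return a [ref_map()] with mutated repeat copies.
#' @export
apply_repeat_divergence <- function(map, divergence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- .ir_flip(seq_chars(map$sequence), map, divergence / 2)
  ref_map(paste(chars, collapse = ""), map$features, flank_len = map$flank_len)
}

## pick a guarded substitution position set: n positions uniform over 1..N,
## excluding indel guard zones
.guarded_positions <- function(n_sub, n_total, forbidden) {
  if (n_sub == 0) return(integer(0))
  ok <- setdiff(seq_len(n_total), forbidden)
  sample(ok, min(n_sub, length(ok)))
}

## guard zone (indices) around an indel op; insertions that duplicate local
## sequence (plant inserts, tandem duplications) also protect the reference
## copy of the duplicated segment -- a substitution there would let the
## aligner swap the pristine and mutated copies between insert and reference
.op_guard <- function(op, guard) {
  if (op$type == "del") {
    lo <- op$pos - guard
    hi <- op$pos + nchar(op$seq) + guard
  } else {
    dup_ctx <- if (op$type == "dupl") {
      nchar(op$seq)
    } else if (!is.null(op$direct_repeat) && nzchar(op$direct_repeat)) {
      nchar(op$direct_repeat)
    } else 0L
    lo <- op$pos - guard
    hi <- op$pos + dup_ctx + guard + 1L
  }
  seq.int(max(1L, lo), hi)
}

## occupied reference interval of an op (for separation checks)
.op_interval <- function(op) {
  if (op$type == "del") c(op$pos, op$pos + nchar(op$seq) + 1L) else c(op$pos, op$pos + 1L)
}

## draw one indel event from the spectrum, left-aligned against the
## reference, respecting separation from existing ops
draw_indel <- function(refc, ctdna_iv, spectrum, existing, min_sep, max_try = 200L) {
  for (i in seq_len(max_try)) {
    t_idx <- sample.int(nrow(spectrum), 1L, prob = spectrum$weight)
    tpl <- spectrum[t_idx, ]
    len <- sample(tpl$min_len:tpl$max_len, 1L)
    lo <- ctdna_iv[1] + 80L
    hi <- ctdna_iv[2] - 80L - len
    pos <- sample(lo:hi, 1L)
    op <- switch(tpl$type,
      del = {
        seqd <- paste(refc[(pos + 1):(pos + len)], collapse = "")
        la <- left_align_indel(refc, pos, "del", seqd)
        list(pos = la$pos, type = "del", seq = la$seq, direct_repeat = "", copies = 1L)
      },
      ins = {
        s <- random_dna(len)
        ## screen: no accidental target-site duplication (>=3 nt) or tandem
        ## identity with the flank, so the injected type is unambiguous
        la <- left_align_indel(refc, pos, "ins", s)
        p2 <- la$pos; s2 <- seq_chars(la$seq)
        tsd3 <- identical(s2[1:3], refc[(p2 + 1):(p2 + 3)])
        tand <- identical(s2, refc[(p2 - len + 1):(p2)])
        if (tsd3 || tand) NULL else {
          list(pos = la$pos, type = "ins", seq = la$seq, direct_repeat = "", copies = 1L)
        }
      },
      dupl = {
        copies <- sample(c(1L, 2L), 1L, prob = c(0.8, 0.2))
        unit <- paste(refc[(pos - len + 1):(pos)], collapse = "")
        s <- paste(rep(unit, copies), collapse = "")
        la <- left_align_indel(refc, pos, "ins", s)
        list(pos = la$pos, type = "dupl", seq = la$seq,
             direct_repeat = "", copies = copies)
      },
      plant_insert = {
        k <- sample(tpl$tsd_min:tpl$tsd_max, 1L)
        m <- refc[(pos - k + 1):(pos)]
        p1_forbid <- refc[pos + 1L]
        pl_forbid <- refc[pos - k]
        p <- seq_chars(random_dna(len))
        ## detector exactness: the duplicated motif must not extend by chance
        if (p[1] == p1_forbid) p[1] <- sample(setdiff(DNA_BASES, p1_forbid), 1L)
        if (p[len] == pl_forbid) p[len] <- sample(setdiff(DNA_BASES, pl_forbid), 1L)
        s <- paste(c(p, m), collapse = "")
        la <- left_align_indel(refc, pos, "ins", s)
        ## canonical (left-aligned) form is motif + plant sequence
        if (la$pos != pos - k) NULL else {
          list(pos = la$pos, type = "plant_insert", seq = la$seq,
               direct_repeat = paste(m, collapse = ""), copies = 1L)
        }
      }
    )
    if (is.null(op)) next
    iv <- .op_interval(op)
    ok <- TRUE
    for (e in existing) {
      ive <- .op_interval(e)
      if (iv[1] <= ive[2] + min_sep && ive[1] <= iv[2] + min_sep) { ok <- FALSE; break }
    }
    if (ok && iv[1] > ctdna_iv[1] + 20L && iv[2] < ctdna_iv[2] - 20L) return(op)
  }
  NULL
}

op_id <- function(op) paste0(op$type, op$pos)

ops_to_df <- function(ops, allele_id = NA_character_) {
  if (length(ops) == 0) {
    return(data.frame(
      allele_id = character(0), pos = integer(0), type = character(0),
      seq = character(0), direct_repeat = character(0), copies = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  data.frame(
    allele_id = allele_id,
    pos = vapply(ops, function(o) as.integer(o$pos), integer(1)),
    type = vapply(ops, function(o) o$type, character(1)),
    seq = vapply(ops, function(o) o$seq, character(1)),
    direct_repeat = vapply(ops, function(o)
      if (is.null(o$direct_repeat)) "" else o$direct_repeat, character(1)),
    copies = vapply(ops, function(o)
      if (is.null(o$copies)) 1L else o$copies, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Evolve a cT-DNA allele population from the ancestral locus
#'
#' Simulates a two-clade genealogy. The two inverted-repeat copies first
#' accumulate the shared ("trunk") part of their substitution load, then the
#' two clade ancestors and finally each allele lineage accumulate genome-wide
#' substitutions, so that the total per-copy repeat load matches the
#' configured insertion age under the configured dating convention. Indels
#' are drawn from the spectrum: clade-ancestral marker indels shared by a
#' clade, plus private per-allele events; all are recorded left-aligned in
#' reference coordinates. With probability `p_rearranged_lineage` an
#' accession carries the inverted-center structure (reverse complement of the
#' segment between the repeats plus two breakpoint deletions; such alleles
#' carry no cataloged indels). Diploid accessions pair alleles within or
#' across clades.
#'
#' @param ancestor a [ref_map()] from [build_ancestral_ctdna()].
#' @param config a [sim_config()] object.
#' @return object of class `ctdna_truth`: the configuration, reference map,
#'   per-accession haplotype records, and machine-readable truth tables
#'   (`indels`, `markers`, `homoplasies`, `subs` per allele).
#' @export
evolve_population <- function(ancestor, config) {
  if (config$n_accessions < 1) stop("degenerate config: zero accessions")
  set.seed(derive_seed(config$seed, 2L))
  refc <- seq_chars(ancestor$sequence)
  n <- length(refc)
  mu <- config$substitution_rate
  age <- config$insertion_age
  d_total <- mu * age * if (config$dating_convention == "two_sided") 2 else 1
  p_copy <- d_total / 2

  li <- feature_interval(ancestor, "left_ir")
  ri <- feature_interval(ancestor, "right_ir")

  ## lineage substitution loads (per copy, applied genome-wide below)
  lin_clade <- config$clade_divergence / 2
  lin_tip <- mean(config$allele_divergence_range)
  p_trunk <- max(0, p_copy - lin_clade - lin_tip)

  ## trunk repeat divergence, shared by every lineage; the post-trunk locus
  ## is the working reference of the run (a present-day sequence with
  ## diverged repeat copies, against which reads map uniquely)
  sec <- .ir_flip(refc, ancestor, p_trunk)
  work_ref <- ref_map(paste(sec, collapse = ""), ancestor$features,
                      flank_len = ancestor$flank_len)
  secc <- sec

  ctdna_iv <- feature_interval(ancestor, "ctdna")
  spectrum <- config$indel_spectrum
  min_sep <- config$min_event_separation
  guard <- config$sub_guard

  ## clade ancestors: marker indels first, then guarded substitutions;
  ## markers of the two clades respect mutual separation so a homoplasy can
  ## never place two events too close on one allele
  clades <- list()
  all_marker_ops <- list()
  for (cl in c("A", "B")) {
    marker_ops <- list()
    for (i in seq_len(config$n_clade_markers)) {
      op <- draw_indel(secc, ctdna_iv, spectrum,
                       c(all_marker_ops, marker_ops), min_sep)
      if (!is.null(op)) marker_ops[[length(marker_ops) + 1L]] <- op
    }
    all_marker_ops <- c(all_marker_ops, marker_ops)
    forbidden <- unique(unlist(lapply(c(all_marker_ops), .op_guard, guard = guard)))
    nsub <- rbinom(1L, n, lin_clade)
    sub_pos <- .guarded_positions(nsub, n, forbidden)
    chars <- mutate_bases(sec, sub_pos)
    clades[[cl]] <- list(chars = chars, markers = marker_ops, sub_pos = sub_pos)
  }

  marker_frames <- Filter(function(d) !is.null(d) && nrow(d) > 0,
    lapply(c("A", "B"), function(cl) {
      df <- ops_to_df(clades[[cl]]$markers)
      if (nrow(df) == 0) return(NULL)
      df$clade <- cl
      ## marker names follow the catalog convention (plant inserts are "ins")
      df$marker <- paste0(sub("plant_insert", "ins", df$type), df$pos)
      df
    }))
  markers_df <- if (length(marker_frames)) {
    do.call(rbind, marker_frames)
  } else {
    cbind(ops_to_df(list()),
          data.frame(clade = character(0), marker = character(0)))
  }

  ## plan accessions
  n_acc <- config$n_accessions
  acc_ids <- sprintf("acc%02d", seq_len(n_acc))
  rearranged <- runif(n_acc) < config$p_rearranged_lineage
  het <- runif(n_acc) < config$p_heterozygous
  cross <- het & (runif(n_acc) < config$p_cross_clade)

  ## plan homoplasies: clade marker granted to one allele of the other clade
  homoplasy_plan <- list()
  if (config$n_homoplasy > 0 && !is.null(markers_df) && nrow(markers_df) > 0) {
    for (i in seq_len(config$n_homoplasy)) {
      mrow <- markers_df[sample.int(nrow(markers_df), 1L), ]
      homoplasy_plan[[i]] <- list(marker = mrow$marker, from_clade = mrow$clade,
                                  op = list(pos = mrow$pos, type = mrow$type,
                                            seq = mrow$seq,
                                            direct_repeat = mrow$direct_repeat,
                                            copies = mrow$copies))
    }
  }

  build_allele <- function(allele_id, clade, extra_ops = list()) {
    base <- clades[[clade]]$chars
    delta <- runif(1L, config$allele_divergence_range[1],
                   config$allele_divergence_range[2])
    n_indel <- rpois(1L, config$indels_per_allele)
    ops <- c(clades[[clade]]$markers, extra_ops)
    for (i in seq_len(n_indel)) {
      op <- draw_indel(secc, ctdna_iv, spectrum, ops, min_sep)
      if (!is.null(op)) ops[[length(ops) + 1L]] <- op
    }
    forbidden <- unique(unlist(lapply(ops, .op_guard, guard = guard)))
    forbidden <- forbidden[forbidden >= 1L & forbidden <= n]
    nsub <- rbinom(1L, n, delta)
    sub_pos <- .guarded_positions(nsub, n, forbidden)
    chars <- mutate_bases(base, sub_pos)
    ## clade-level substitutions inside an op's guard zone would change the
    ## op's left-alignment context; revert them to the working reference
    chars[forbidden] <- secc[forbidden]
    seq <- paste(apply_ops(chars, ops), collapse = "")
    subs <- which(chars != secc)
    list(
      allele_id = allele_id, clade = clade, seq = seq,
      ops = ops, structural_class = "standard",
      subs = data.frame(pos = subs, ref = secc[subs], alt = chars[subs],
                        stringsAsFactors = FALSE)
    )
  }

  ## rearranged lineage: its repeat copies carry the same total load as any
  ## other lineage (the clock ticks along every lineage); the load beyond the
  ## trunk and the tips is shared by the accession's two alleles
  rear_extra <- max(0, p_copy - p_trunk - 0.01)
  build_rearranged <- function(allele_id, rear_base) {
    delta <- 0.01
    forbidden <- integer(0)
    nsub <- rbinom(1L, n, delta)
    chars <- mutate_bases(rear_base, .guarded_positions(nsub, n, forbidden))
    subs <- which(chars != secc)
    subs_df <- data.frame(pos = subs, ref = secc[subs], alt = chars[subs],
                          stringsAsFactors = FALSE)
    ## invert the unique center between the repeats, then two deletions
    c_lo <- li["end"] + 1L
    c_hi <- ri["start"] - 1L
    center <- paste(chars[c_lo:c_hi], collapse = "")
    inv <- seq_chars(revcomp(center))
    del1 <- 250L; del2 <- 180L
    inv <- inv[-(seq_len(del1))]
    inv <- inv[-((length(inv) - del2 + 1L):length(inv))]
    out <- c(chars[1:(c_lo - 1L)], inv, chars[(c_hi + 1L):n])
    list(
      allele_id = allele_id, clade = "O",
      seq = paste(out, collapse = ""),
      ops = list(), structural_class = "inverted_center",
      subs = subs_df,
      inversion = c(start = unname(c_lo), end = unname(c_hi)),
      breakpoint_deletions = c(del1 = del1, del2 = del2)
    )
  }

  ## homoplasy targets assigned after accession plan: collect candidate
  ## allele slots per clade
  accessions <- vector("list", n_acc)
  slot_clades <- list()
  for (i in seq_len(n_acc)) {
    id <- acc_ids[i]
    if (rearranged[i]) {
      accessions[[i]] <- list(
        accession = id, index = i, structural_class = "inverted_center",
        heterozygous = het[i], cross_clade = FALSE, clades = c("O", "O")
      )
    } else if (het[i]) {
      cls <- if (cross[i]) c("A", "B") else rep(sample(c("A", "B"), 1L), 2L)
      accessions[[i]] <- list(
        accession = id, index = i, structural_class = "standard",
        heterozygous = TRUE, cross_clade = cross[i], clades = cls
      )
    } else {
      cls <- sample(c("A", "B"), 1L)
      accessions[[i]] <- list(
        accession = id, index = i, structural_class = "standard",
        heterozygous = FALSE, cross_clade = FALSE, clades = c(cls, cls)
      )
    }
  }

  ## map homoplasies to concrete alleles (first haplotype of a random
  ## accession whose clade is opposite the marker's home clade)
  homo_df <- data.frame(marker = character(0), allele_id = character(0),
                        stringsAsFactors = FALSE)
  homo_by_allele <- list()
  for (h in homoplasy_plan) {
    other <- setdiff(c("A", "B"), h$from_clade)
    cand <- character(0)
    for (a in accessions) {
      if (a$structural_class != "standard") next
      for (k in 1:2) {
        aid <- paste0(a$accession, "_", k)
        if (a$clades[k] == other && !(aid %in% names(homo_by_allele)) &&
            !(a$heterozygous == FALSE && k == 2L)) {
          cand <- c(cand, aid)
        }
      }
    }
    if (length(cand) == 0) next
    pick <- sample(cand, 1L)
    homo_by_allele[[pick]] <- c(homo_by_allele[[pick]], list(h$op))
    homo_df <- rbind(homo_df, data.frame(marker = h$marker, allele_id = pick,
                                         stringsAsFactors = FALSE))
  }

  ## build haplotypes
  indel_rows <- list()
  for (i in seq_len(n_acc)) {
    a <- accessions[[i]]
    haps <- list()
    if (a$structural_class == "inverted_center") {
      rear_base <- .ir_flip(sec, ancestor, rear_extra)
      h1 <- build_rearranged(paste0(a$accession, "_1"), rear_base)
      if (a$heterozygous) {
        h2 <- build_rearranged(paste0(a$accession, "_2"), rear_base)
      } else {
        h2 <- h1; h2$allele_id <- paste0(a$accession, "_1")
      }
      haps <- list(h1, h2)
    } else if (a$heterozygous) {
      for (k in 1:2) {
        aid <- paste0(a$accession, "_", k)
        extra <- if (!is.null(homo_by_allele[[aid]])) homo_by_allele[[aid]] else list()
        haps[[k]] <- build_allele(aid, a$clades[k], extra)
      }
      if (identical(haps[[1]]$seq, haps[[2]]$seq)) {
        a$heterozygous <- FALSE       # degenerate draw: identical haplotypes
        haps[[2]] <- haps[[1]]
      }
    } else {
      aid <- paste0(a$accession, "_1")
      extra <- if (!is.null(homo_by_allele[[aid]])) homo_by_allele[[aid]] else list()
      h1 <- build_allele(aid, a$clades[1], extra)
      haps <- list(h1, h1)
    }
    a$haplotypes <- haps
    accessions[[i]] <- a
    seen <- character(0)
    for (h in haps) {
      if (h$allele_id %in% seen) next
      seen <- c(seen, h$allele_id)
      df <- ops_to_df(h$ops, h$allele_id)
      if (nrow(df)) indel_rows[[length(indel_rows) + 1L]] <- df
    }
  }

  indels <- if (length(indel_rows)) do.call(rbind, indel_rows) else ops_to_df(list())
  out <- list(
    config = config, reference = work_ref, ancestor = ancestor,
    accessions = accessions,
    indels = indels, markers = markers_df, homoplasies = homo_df,
    repeat_load_per_copy = p_copy, trunk_load_per_copy = p_trunk
  )
  class(out) <- "ctdna_truth"
  out
}

#' @export
print.ctdna_truth <- function(x, ...) {
  n_het <- sum(vapply(x$accessions, function(a) isTRUE(a$heterozygous), logical(1)))
  cat("simulated cT-DNA population:", length(x$accessions), "accessions (",
      n_het, "heterozygous ),", nrow(x$indels), "injected indel records\n")
  invisible(x)
}

#' Simulate short reads from one accession's haplotypes
#'
#' Uniform-start single-end reads of `read_length` nt from both haplotypes
#' (both strands), with per-base substitution errors at `read_error_rate`.
#' Read names carry no information about the haplotype of origin; the origin
#' table is returned separately as ground truth.
#'
#' @param accession one element of `ctdna_truth$accessions` (or any list with
#'   `accession`, `index` and `haplotypes`, each haplotype carrying `seq` and
#'   `allele_id`).
#' @param config a [sim_config()] object.
#' @param n_reads optional total read count for the accession (split over the
#'   two haplotypes), overriding the coverage-based count.
#' @return list with `reads` (data.frame id, seq) and `origins` (data.frame
#'   id, allele_id, hap, start, strand).
#' @export
generate_reads <- function(accession, config, n_reads = NULL) {
  set.seed(derive_seed(config$seed, 1000L + accession$index))
  rl <- config$read_length
  out_reads <- list(); out_orig <- list()
  counter <- 0L
  for (k in seq_along(accession$haplotypes)) {
    h <- accession$haplotypes[[k]]
    len <- nchar(h$seq)
    if (rl > len) stop("read_length exceeds allele length")
    nr <- if (is.null(n_reads)) {
      max(0L, as.integer(round(config$coverage * len / rl)))
    } else {
      as.integer(round(n_reads / length(accession$haplotypes)))
    }
    if (nr == 0L) next
    ## starts may overhang either end (the locus sits in chromosomal context;
    ## recovered reads are trimmed to the analyzed window)
    starts <- sample.int(len + rl - 1L, nr, replace = TRUE) - rl + 1L
    ends <- pmin(len, starts + rl - 1L)
    starts <- pmax(1L, starts)
    strands <- sample(c("+", "-"), nr, replace = TRUE)
    seqs <- substring(h$seq, starts, ends)
    long_enough <- nchar(seqs) >= 30L
    starts <- starts[long_enough]; strands <- strands[long_enough]
    seqs <- seqs[long_enough]
    nr <- length(seqs)
    if (nr == 0L) next
    flip <- strands == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    if (config$read_error_rate > 0) {
      for (j in seq_len(nr)) {
        lj <- nchar(seqs[j])
        nerr <- rbinom(1L, lj, config$read_error_rate)
        if (nerr > 0) {
          ch <- seq_chars(seqs[j])
          ch <- mutate_bases(ch, sample.int(lj, nerr))
          seqs[j] <- paste(ch, collapse = "")
        }
      }
    }
    ids <- sprintf("%s_r%05d", accession$accession, counter + seq_len(nr))
    counter <- counter + nr
    out_reads[[k]] <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
    out_orig[[k]] <- data.frame(
      id = ids, allele_id = h$allele_id, hap = k,
      start = starts, strand = strands, stringsAsFactors = FALSE
    )
  }
  list(
    reads = do.call(rbind, out_reads),
    origins = do.call(rbind, out_orig)
  )
}

#' Simulate a population and optionally write it to disk
#'
#' Convenience wrapper: builds the ancestral locus, evolves the population,
#' and (if `out_dir` is given) writes the reference FASTA + feature table,
#' per-accession allele FASTA and read FASTQ files, truth TSVs, and a JSON
#' echo of the configuration. Outputs are byte-identical for identical
#' configurations.
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional output directory.
#' @return a `ctdna_truth` object (invisibly if writing).
#' @export
simulate_population <- function(config, out_dir = NULL) {
  ancestor <- build_ancestral_ctdna(config)
  truth <- evolve_population(ancestor, config)
  if (is.null(out_dir)) return(truth)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_reference(ancestor, file.path(out_dir, "reference.fasta"),
                  file.path(out_dir, "reference_features.tsv"))
  alleles <- list()
  origins <- list()
  for (a in truth$accessions) {
    rr <- generate_reads(a, config)
    write_fastq(rr$reads, file.path(out_dir, paste0(a$accession, ".fastq")))
    origins[[a$accession]] <- rr$origins
    for (h in a$haplotypes) alleles[[h$allele_id]] <- h$seq
  }
  write_fasta(unlist(alleles), file.path(out_dir, "true_alleles.fasta"))
  write.table(truth$indels, file.path(out_dir, "truth_indels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, origins), file.path(out_dir, "truth_read_origins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$indel_spectrum <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
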