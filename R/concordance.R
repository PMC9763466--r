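## ---- reference-anchored multiple alignment ----------------------------------

#' Multiple alignment of phased alleles
#'
#' Reference-anchored multiple alignment: every allele is aligned globally to
#' the reference, rows are stacked on reference columns ('-' where the
#' reference base is deleted in an allele), and insertion blocks are added as
#' extra columns keyed by reference position (padded with '-' in alleles that
#' lack them). Columns whose gap fraction exceeds `gap_threshold` are then
#' dropped — the deterministic counterpart of removing indel columns by hand
#' before tree building.
#'
#' @param alleles named character vector of allele sequences, or list of
#'   `phased_allele` objects.
#' @param map a [ref_map()] object.
#' @param gap_threshold maximum tolerated gap fraction per column.
#' @param cache optional [alignment_cache()].
#' @return object of class `ctdna_msa`: character matrix (alleles x columns)
#'   plus the reference position of each retained column (`NA` for insertion
#'   columns).
#' @export
align_alleles <- function(alleles, map, gap_threshold = 0.2, cache = NULL) {
  if (is.list(alleles) && all(vapply(alleles, inherits, logical(1), "phased_allele"))) {
    alleles <- setNames(
      vapply(alleles, function(a) a$sequence, character(1)),
      vapply(alleles, function(a) a$allele_id, character(1))
    )
  }
  if (length(alleles) < 3) stop("need at least 3 alleles to align")
  ids <- names(alleles)
  if (is.null(ids)) stop("alleles must be named")
  ref <- map$sequence
  n <- nchar(ref)
  nal <- length(alleles)

  base_mat <- matrix("-", nrow = nal, ncol = n, dimnames = list(ids, NULL))
  ins_store <- vector("list", nal)
  for (i in seq_len(nal)) {
    a <- cached_align(cache, ids[i], alleles[[i]], ref)
    q <- a$q; r <- a$r
    rpos <- cumsum(r != "-")
    matched <- r != "-"
    base_mat[i, rpos[matched]] <- q[matched]
    ## collect insertion strings keyed by preceding reference position
    gaps <- which(r == "-")
    if (length(gaps)) {
      runs <- split(gaps, cumsum(c(1L, diff(gaps) != 1L)))
      ins <- lapply(runs, function(ix) {
        list(pos = if (rpos[ix[1]] == 0L) 0L else rpos[ix[1]],
             seq = paste(q[ix], collapse = ""))
      })
      ins_store[[i]] <- ins
    }
  }

  ## insertion blocks shared across alleles
  ins_pos <- sort(unique(unlist(lapply(ins_store, function(l)
    vapply(l, function(x) x$pos, integer(1))))))
  ins_cols <- list()
  for (p in ins_pos) {
    seqs <- vapply(seq_len(nal), function(i) {
      l <- ins_store[[i]]
      if (is.null(l)) return("")
      hit <- which(vapply(l, function(x) x$pos, integer(1)) == p)
      if (length(hit)) l[[hit[1]]]$seq else ""
    }, character(1))
    w <- max(nchar(seqs))
    block <- matrix("-", nrow = nal, ncol = w)
    for (i in seq_len(nal)) {
      if (nchar(seqs[i])) {
        block[i, seq_len(nchar(seqs[i]))] <- seq_chars(seqs[i])
      }
    }
    ins_cols[[as.character(p)]] <- block
  }

  ## interleave: reference columns with insertion blocks after their position
  if (length(ins_cols)) {
    pieces <- list(); col_ref <- list()
    last <- 0L
    for (p in ins_pos) {
      if (p >= last + 1L) {
        pieces[[length(pieces) + 1L]] <- base_mat[, (last + 1L):p, drop = FALSE]
        col_ref[[length(col_ref) + 1L]] <- (last + 1L):p
      }
      blk <- ins_cols[[as.character(p)]]
      pieces[[length(pieces) + 1L]] <- blk
      col_ref[[length(col_ref) + 1L]] <- rep(NA_integer_, ncol(blk))
      last <- p
    }
    if (last < n) {
      pieces[[length(pieces) + 1L]] <- base_mat[, (last + 1L):n, drop = FALSE]
      col_ref[[length(col_ref) + 1L]] <- (last + 1L):n
    }
    mat <- do.call(cbind, pieces)
    ref_col <- unlist(col_ref)
  } else {
    mat <- base_mat
    ref_col <- seq_len(n)
  }

  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= gap_threshold
  out <- list(matrix = mat[, keep, drop = FALSE], ref_col = ref_col[keep])
  class(out) <- "ctdna_msa"
  out
}

#' @export
print.ctdna_msa <- function(x, ...) {
  cat("multiple alignment:", nrow(x$matrix), "alleles x",
      ncol(x$matrix), "columns\n")
  invisible(x)
}

## ---- tree building -----------------------------------------------------------

#' Build the allele tree
#'
#' Neighbor-joining on Jukes-Cantor distances computed from the multiple
#' alignment, with nonparametric bootstrap support, rooted on the outgroup
#' and ladderized for a canonical representation. (Neighbor joining replaces
#' a maximum-likelihood engine for desk-scale determinism; the Newick export
#' lets users re-estimate with an external ML tool.)
#'
#' @param msa a `ctdna_msa` from [align_alleles()].
#' @param outgroup allele id used to root the tree.
#' @param n_bootstrap bootstrap replicates (0 to skip support values).
#' @param seed RNG seed for the bootstrap resampling.
#' @return object of class `allele_tree`: `phylo` (rooted, ladderized, with
#'   node labels = bootstrap percentages) and `outgroup`.
#' @export
build_tree <- function(msa, outgroup, n_bootstrap = 200L, seed = 1L) {
  mat <- msa$matrix
  if (!outgroup %in% rownames(mat)) stop("outgroup not present in alignment")
  bin <- ape::as.DNAbin(tolower(mat))
  make_tree <- function(x) {
    d <- ape::dist.dna(x, model = "JC69", pairwise.deletion = TRUE)
    ape::root(ape::nj(d), outgroup, resolve.root = TRUE)
  }
  tree <- make_tree(bin)
  if (n_bootstrap > 0) {
    set.seed(seed)
    bp <- ape::boot.phylo(tree, bin, make_tree, B = n_bootstrap,
                          rooted = TRUE, quiet = TRUE)
    tree$node.label <- round(100 * bp / n_bootstrap)
  }
  tree <- ape::ladderize(tree)
  out <- list(phylo = tree, outgroup = outgroup)
  class(out) <- "allele_tree"
  out
}

#' @export
print.allele_tree <- function(x, ...) {
  cat("allele tree:", length(x$phylo$tip.label), "leaves, outgroup",
      x$outgroup, "\n")
  invisible(x)
}

#' Write the tree as Newick
#'
#' @param tree an `allele_tree`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

clade_leaves <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

## ---- group assignment ---------------------------------------------------------

#' Assign principal groups and marker-based subgroups
#'
#' After removing the outgroup, the two children of the ingroup root define
#' the two principal groups. The group richer in carriers of the most
#' frequent marker is called A (ties broken by the lexicographically smallest
#' leaf). Each marker is then tested: its home group is the majority group of
#' its carriers; carriers whose home-group carriers form a monophyletic clade
#' define a subgroup (A1, A2, ... / B1, B2, ..., markers ordered by
#' frequency); carriers found in the other group are reported as exceptions
#' (marker-topology discordances).
#'
#' @param tree an `allele_tree` from [build_tree()].
#' @param markers logical matrix (alleles x markers).
#' @param extra_outgroup further allele ids kept outside the two principal
#'   groups (e.g. additional early-diverged rearranged alleles); they are
#'   labeled `O` like the rooting outgroup.
#' @return object of class `concordance_report`: `groups` (named character
#'   vector A/B/O per allele), `subgroups`, `markers`, `exceptions`
#'   (data.frame marker/allele_id/group), `tree`.
#' @export
assign_groups <- function(tree, markers, extra_outgroup = character(0)) {
  phy <- tree$phylo
  leaves <- phy$tip.label
  markers <- markers[intersect(rownames(markers), leaves), , drop = FALSE]
  out_ids <- union(tree$outgroup, intersect(extra_outgroup, leaves))
  ingroup <- setdiff(leaves, out_ids)
  ing <- ape::drop.tip(phy, out_ids)
  ntip <- length(ing$tip.label)
  root <- ntip + 1L
  kids <- ing$edge[ing$edge[, 1] == root, 2]
  clades <- lapply(kids, function(k) clade_leaves(ing, k))
  if (length(clades) > 2) {
    ## polytomy at the root: largest clade versus the rest
    sizes <- vapply(clades, length, integer(1))
    big <- which.max(sizes)
    clades <- list(clades[[big]], unlist(clades[-big]))
  }
  groups <- setNames(rep("O", length(leaves)), leaves)
  cl1 <- clades[[1]]; cl2 <- clades[[2]]

  marker_freq <- colSums(markers)
  label1 <- "A"
  if (length(marker_freq) && max(marker_freq) > 0) {
    m_star <- names(sort(marker_freq, decreasing = TRUE))[1]
    carriers <- rownames(markers)[markers[, m_star]]
    f1 <- mean(cl1 %in% carriers); f2 <- mean(cl2 %in% carriers)
    if (f2 > f1) label1 <- "B"
    else if (f1 == f2 && min(cl2) < min(cl1)) label1 <- "B"
  } else if (min(cl2) < min(cl1)) {
    label1 <- "B"
  }
  groups[cl1] <- label1
  groups[cl2] <- setdiff(c("A", "B"), label1)

  ## subgroups and exceptions
  subgroups <- groups
  exceptions <- data.frame(marker = character(0), allele_id = character(0),
                           group = character(0), stringsAsFactors = FALSE)
  counters <- c(A = 0L, B = 0L)
  for (m in names(sort(marker_freq, decreasing = TRUE))) {
    carriers <- rownames(markers)[markers[, m]]
    carriers <- intersect(carriers, ingroup)
    if (length(carriers) == 0) next
    gA <- sum(groups[carriers] == "A")
    gB <- sum(groups[carriers] == "B")
    home <- if (gA >= gB) "A" else "B"
    stray <- carriers[groups[carriers] != home & groups[carriers] != "O"]
    if (length(stray)) {
      exceptions <- rbind(exceptions, data.frame(
        marker = m, allele_id = stray, group = unname(groups[stray]),
        stringsAsFactors = FALSE
      ))
    }
    home_carriers <- setdiff(carriers, stray)
    if (length(home_carriers) >= 2 &&
        ape::is.monophyletic(ing, home_carriers)) {
      counters[home] <- counters[home] + 1L
      lab <- paste0(home, counters[home])
      plain <- subgroups[home_carriers] %in% c("A", "B")
      subgroups[home_carriers[plain]] <- lab
    }
  }

  out <- list(
    groups = groups, subgroups = subgroups, markers = markers,
    exceptions = exceptions, tree = tree
  )
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance report:", sum(x$groups == "A"), "alleles in A,",
      sum(x$groups == "B"), "in B,", nrow(x$exceptions),
      "marker-topology exceptions\n")
  invisible(x)
}

#' Marker presence matrix from an indel catalog
#'
#' Catalog rows carried by at least `min_count` alleles become markers, named
#' `<type><pos>` (e.g. `del441`).
#'
#' @param catalog data.frame from [aggregate_catalog()].
#' @param allele_ids all allele ids (matrix rows).
#' @param min_count minimum carrier count for a row to be used as a marker.
#' @return logical matrix (alleles x markers).
#' @export
markers_from_catalog <- function(catalog, allele_ids, min_count = 3L) {
  sel <- catalog[catalog$x >= min_count, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(matrix(logical(0), nrow = length(allele_ids), ncol = 0,
                  dimnames = list(allele_ids, NULL)))
  }
  mnames <- paste0(sub("plant_insert", "ins", sel$type), sel$pos)
  m <- matrix(FALSE, nrow = length(allele_ids), ncol = nrow(sel),
              dimnames = list(allele_ids, mnames))
  for (j in seq_len(nrow(sel))) {
    carriers <- strsplit(sel$alleles[j], ",", fixed = TRUE)[[1]]
    m[intersect(carriers, allele_ids), j] <- TRUE
  }
  m
}

#' Allele-pair group spans
#'
#' For every accession with two distinct alleles in the report, the group
#' labels of the two alleles and whether the pair spans both principal
#' groups.
#'
#' @param report a `concordance_report`.
#' @param phasing data.frame with columns `accession`, `allele_id` (two rows
#'   per paired accession), or a list of `phasing_result` objects.
#' @return list with `table` (accession, group1, group2, cross) and summary
#'   counts `n_pairs`, `n_cross`, `cross_fraction`.
#' @export
pair_spans <- function(report, phasing) {
  if (is.list(phasing) && all(vapply(phasing, inherits, logical(1), "phasing_result"))) {
    rows <- lapply(phasing, function(p) {
      if (p$status != "paired") return(NULL)
      data.frame(
        accession = p$accession,
        allele_id = vapply(p$alleles, function(a) a$allele_id, character(1)),
        stringsAsFactors = FALSE
      )
    })
    phasing <- do.call(rbind, rows)
  }
  if (is.null(phasing) || nrow(phasing) == 0) {
    return(list(
      table = data.frame(accession = character(0), group1 = character(0),
                         group2 = character(0), cross = logical(0)),
      n_pairs = 0L, n_cross = 0L, cross_fraction = NA_real_
    ))
  }
  out <- list()
  for (acc in unique(phasing$accession)) {
    ids <- phasing$allele_id[phasing$accession == acc]
    ids <- ids[ids %in% names(report$groups)]
    if (length(ids) != 2) next
    g <- unname(report$groups[ids])
    out[[acc]] <- data.frame(
      accession = acc, group1 = g[1], group2 = g[2],
      cross = g[1] != g[2] & !"O" %in% g, stringsAsFactors = FALSE
    )
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(accession = character(0), group1 = character(0),
               group2 = character(0), cross = logical(0))
  rownames(tab) <- NULL
  list(
    table = tab,
    n_pairs = nrow(tab),
    n_cross = sum(tab$cross),
    cross_fraction = if (nrow(tab)) sum(tab$cross) / nrow(tab) else NA_real_
  )
}
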