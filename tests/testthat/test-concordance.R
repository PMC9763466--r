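## small allele set derived from the diverged reference: two clades marked by
## private substitution loads plus a marker deletion in clade A
make_clades <- function(map, n_per_clade = 4, seed = 5) {
  set.seed(seed)
  ref <- map$sequence
  refc <- strsplit(ref, "")[[1]]
  mutate_from <- function(chars, n) {
    paste(ctdnatools:::mutate_bases(chars, sample(length(chars), n)),
          collapse = "")
  }
  cladeA <- ctdnatools:::mutate_bases(refc, sample(length(refc), 120))
  cladeB <- ctdnatools:::mutate_bases(refc, sample(length(refc), 120))
  del_after <- 441L; del_len <- 7L
  alleles <- list()
  for (i in seq_len(n_per_clade)) {
    sa <- mutate_from(cladeA, 25)
    ## clade A carries a marker deletion
    sa <- paste0(substr(sa, 1, del_after),
                 substr(sa, del_after + del_len + 1L, nchar(sa)))
    alleles[[paste0("a", i, "_1")]] <- sa
    alleles[[paste0("b", i, "_1")]] <- mutate_from(cladeB, 25)
  }
  ## outgroup: far from both clades
  alleles[["og_1"]] <- mutate_from(refc, 400)
  unlist(alleles)
}

test_that("identical sequences give a gap-free alignment", {
  map <- diverged_map()
  seqs <- setNames(rep(substr(map$sequence, 1, 800), 4), paste0("s", 1:4))
  small_ft <- data.frame(name = c("ctdna", "left_ir", "right_ir"),
                         start = c(1L, 1L, 700L), end = c(800L, 100L, 800L))
  m <- ref_map(substr(map$sequence, 1, 800), small_ft)
  msa <- align_alleles(seqs, m)
  expect_false(any(msa$matrix == "-"))
  expect_equal(ncol(msa$matrix), 800L)
})

test_that("a private insertion block is dropped at the gap threshold", {
  map <- diverged_map()
  ref <- substr(map$sequence, 1, 1000)
  small_ft <- data.frame(name = c("ctdna", "left_ir", "right_ir"),
                         start = c(1L, 1L, 900L), end = c(1000L, 100L, 1000L))
  m <- ref_map(ref, small_ft)
  set.seed(2)
  withins <- paste0(substr(ref, 1, 500), random_dna(30), substr(ref, 501, 1000))
  seqs <- c(s1 = ref, s2 = ref, s3 = ref, s4 = withins)
  msa <- align_alleles(seqs, m)
  ## the insert columns are gapped in 3 of 4 alleles and removed
  expect_equal(ncol(msa$matrix), 1000L)
  expect_false(any(msa$matrix == "-"))
})

test_that("alignment-based pairwise identities track the truth", {
  truth <- demo_truth()
  alleles <- truth_alleles(truth, include_inverted = FALSE)[1:6]
  msa <- align_alleles(alleles, truth$reference)
  mat <- msa$matrix
  ids <- names(alleles)
  for (i in 1:2) for (j in 3:4) {
    al <- align_pair(alleles[[i]], alleles[[j]])
    truth_id <- sum(al$q == al$r & al$q != "-") /
      sum(al$q != "-" & al$r != "-")
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    msa_id <- mean(mat[i, ok] == mat[j, ok])
    expect_lt(abs(msa_id - truth_id), 0.005)
  }
})

test_that("trees recover planted clades and rooting is deterministic", {
  map <- diverged_map()
  alleles <- make_clades(map)
  msa <- align_alleles(alleles, map)
  tree <- build_tree(msa, outgroup = "og_1", n_bootstrap = 50, seed = 2)
  a_ids <- grep("^a", names(alleles), value = TRUE)
  b_ids <- grep("^b", names(alleles), value = TRUE)
  expect_true(ape::is.monophyletic(tree$phylo, a_ids))
  expect_true(ape::is.monophyletic(tree$phylo, b_ids))

  ## permuting the input order leaves the topology unchanged
  perm <- sample(length(alleles))
  msa2 <- align_alleles(alleles[perm], map)
  tree2 <- build_tree(msa2, outgroup = "og_1", n_bootstrap = 0)
  expect_equal(ape::dist.topo(ape::unroot(tree$phylo),
                              ape::unroot(tree2$phylo))[1], 0)

  ## two clusters of near-identical sequences get full support
  expect_true(all(as.numeric(tree$phylo$node.label) >= 0, na.rm = TRUE))
})

test_that("groups, subgroups, and exceptions follow the markers", {
  map <- diverged_map()
  alleles <- make_clades(map)
  msa <- align_alleles(alleles, map)
  tree <- build_tree(msa, outgroup = "og_1", n_bootstrap = 0)
  a_ids <- grep("^a", names(alleles), value = TRUE)
  b_ids <- grep("^b", names(alleles), value = TRUE)
  markers <- matrix(FALSE, nrow = length(alleles), ncol = 1,
                    dimnames = list(names(alleles), "del441"))
  markers[a_ids, "del441"] <- TRUE
  rep0 <- assign_groups(tree, markers)
  ## the marker-rich clade is A
  expect_true(all(rep0$groups[a_ids] == "A"))
  expect_true(all(rep0$groups[b_ids] == "B"))
  expect_equal(nrow(rep0$exceptions), 0L)
  ## alleles without markers in a pure clade carry no exception
  ## inject one homoplasy: grant the marker to one B allele
  markers2 <- markers
  markers2[b_ids[1], "del441"] <- TRUE
  rep1 <- assign_groups(tree, markers2)
  expect_equal(rep1$exceptions$allele_id, b_ids[1])
  expect_equal(rep1$exceptions$marker, "del441")
})

test_that("pair spans count cross-group pairs", {
  map <- diverged_map()
  alleles <- make_clades(map)
  msa <- align_alleles(alleles, map)
  tree <- build_tree(msa, outgroup = "og_1", n_bootstrap = 0)
  markers <- matrix(FALSE, nrow = length(alleles), ncol = 1,
                    dimnames = list(names(alleles), "del441"))
  markers[grep("^a", names(alleles)), 1] <- TRUE
  rep0 <- assign_groups(tree, markers)
  phasing <- data.frame(
    accession = c("x", "x", "y", "y"),
    allele_id = c("a1_1", "b1_1", "a2_1", "a3_1")
  )
  sp <- pair_spans(rep0, phasing)
  expect_equal(sp$n_pairs, 2L)
  expect_equal(sp$n_cross, 1L)
  expect_equal(sp$cross_fraction, 0.5)
  ## homozygous-only input yields no pair rows
  sp0 <- pair_spans(rep0, data.frame(accession = "z", allele_id = "a1_1"))
  expect_equal(sp0$n_pairs, 0L)
})

test_that("marker matrices derive from catalog carrier lists", {
  catalog <- data.frame(
    pos = c(441L, 1946L), type = c("del", "plant_insert"),
    seq = c("TTTGTAG", "AATCGCXXXX"), len = c(7L, 10L),
    direct_repeat = c("", "AATCGC"), copies = 1L,
    x = c(3L, 1L), alleles = c("p_1,q_1,r_1", "p_1"),
    stringsAsFactors = FALSE
  )
  m <- markers_from_catalog(catalog, c("p_1", "q_1", "r_1", "s_1"),
                            min_count = 3)
  expect_equal(colnames(m), "del441")
  expect_equal(unname(m[, "del441"]), c(TRUE, TRUE, TRUE, FALSE))
})
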