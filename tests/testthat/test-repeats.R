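test_that("the undiverged ancestor has 100% repeat identity", {
  map <- ancestor_map()
  rp <- extract_repeats(map$sequence, map)
  expect_equal(rp$status, "ok")
  expect_equal(rp$identity, 100)
  expect_equal(rp$divergence, 0)
})

test_that("identity counts mismatching columns over the aligned span", {
  ## column-count oracle: exactly 95 mismatches over 948 columns, no gaps
  set.seed(12)
  left <- random_dna(948)
  ch <- strsplit(left, "")[[1]]
  mm <- sample(948, 95)
  ch2 <- ctdnatools:::mutate_bases(ch, mm)
  right_rc <- paste(ch2, collapse = "")
  a <- align_pair(left, right_rc)
  idn <- ctdnatools:::aligned_identity(a$q, a$r)
  expect_equal(idn$identity, 100 * (948 - 95) / 948, tolerance = 1e-10)
  expect_equal(round(idn$identity, 2), 89.98)
})

test_that("repeat extraction is invariant under reverse complement", {
  truth <- demo_truth()
  map <- truth$reference
  allele <- truth$accessions[[1]]$haplotypes[[1]]$seq
  rp1 <- extract_repeats(allele, map)
  rp2 <- extract_repeats(revcomp(allele), map)
  expect_equal(rp1$identity, rp2$identity, tolerance = 1e-6)
  ## identity is symmetric in the two copies and 100% for a copy with itself
  self <- align_pair(rp1$left_seq, rp1$left_seq)
  expect_equal(ctdnatools:::aligned_identity(self$q, self$r)$identity, 100)
})

test_that("simulated repeat divergence matches the binomial expectation", {
  ## oracle, independent of the evolver: each repeat column of each copy is
  ## substituted with probability p; columns differ with probability
  ## 2 p (1-p) + (2/3) p^2
  cfg <- sim_config(seed = 7, n_accessions = 5, clade_divergence = 0,
                    allele_divergence_range = c(0, 0), indels_per_allele = 0,
                    n_clade_markers = 0, p_rearranged_lineage = 0)
  truth <- simulate_population(cfg)
  p <- cfg$substitution_rate * cfg$insertion_age / 2
  q <- 2 * p * (1 - p) + (2 / 3) * p^2
  map <- truth$ancestor
  divs <- vapply(truth$accessions, function(a)
    extract_repeats(a$haplotypes[[1]]$seq, map)$divergence, numeric(1))
  se <- sqrt(q * (1 - q) / 948)
  expect_lt(abs(mean(divs) - q), 3 * se)
  ## per-allele identities are tightly clustered
  expect_lt(sd(100 * (1 - divs)), 2)
})

test_that("repeat divergence grows monotonically with insertion age", {
  ages <- c(2e6, 8e6, 15e6)
  mean_div <- vapply(ages, function(T) {
    divs <- vapply(1:6, function(s) {
      cfg <- sim_config(seed = 100 + s, n_accessions = 1, insertion_age = T,
                        clade_divergence = 0, allele_divergence_range = c(0, 0),
                        indels_per_allele = 0, n_clade_markers = 0,
                        p_rearranged_lineage = 0)
      truth <- simulate_population(cfg)
      extract_repeats(truth$accessions[[1]]$haplotypes[[1]]$seq,
                      truth$ancestor)$divergence
    }, numeric(1))
    mean(divs)
  }, numeric(1))
  expect_true(all(diff(mean_div) > 0))
})

test_that("structure classification separates standard from inverted-center", {
  map <- ancestor_map()
  expect_equal(classify_structure(map$sequence, map)$class, "standard")

  cfg <- sim_config(seed = 13, n_accessions = 3, p_rearranged_lineage = 1)
  truth <- simulate_population(cfg)
  h <- truth$accessions[[1]]$haplotypes[[1]]
  expect_equal(h$structural_class, "inverted_center")
  sc <- classify_structure(h$seq, truth$reference)
  expect_equal(sc$class, "inverted_center")
  ## the two breakpoint deletions are recovered near the repeat boundaries
  expect_equal(nrow(sc$breakpoint_deletions), 2L)
  expect_equal(sort(sc$breakpoint_deletions$len),
               sort(unname(h$breakpoint_deletions)), tolerance = 0.1)
})

test_that("short central segments are unresolved", {
  ft <- data.frame(
    name = c("ctdna", "left_ir", "right_ir"),
    start = c(1L, 1L, 161L), end = c(260L, 100L, 260L)
  )
  set.seed(3)
  ir <- random_dna(100)
  center <- random_dna(60)
  seqn <- paste0(ir, center, revcomp(ir))
  m <- ref_map(seqn, ft)
  expect_equal(classify_structure(seqn, m)$class, "unresolved")
})

test_that("gene disruptions are detected with printed-style contexts", {
  ## build a small locus with one plus-strand gene and plant a premature TGA
  ## such that the 12-nt context ends with the stop codon
  set.seed(21)
  n <- 3000L
  chars <- strsplit(random_dna(n), "")[[1]]
  chars <- ctdnatools:::write_orf(chars, 642L, 1840L)
  ref <- paste(chars, collapse = "")
  ft <- data.frame(
    name = c("ctdna", "left_ir", "acs", "right_ir"),
    start = c(1L, 1L, 642L, 2801L), end = c(3000L, 120L, 1840L, 2920L)
  )
  m <- ref_map(ref, ft)
  ## intact gene: no events
  expect_equal(nrow(scan_gene_disruptions(ref, m)), 0L)

  ## premature stop with the printed 12-nt context ATCGCGAAATGA
  ach <- chars
  ach[1545:1556] <- strsplit("ATCGCGAAATGA", "")[[1]]
  stopifnot((1554 - 642) %% 3 == 0)   # TGA in frame at 1554..1556
  allele <- paste(ach, collapse = "")
  ev <- scan_gene_disruptions(allele, m)
  stops <- ev[ev$kind == "premature_stop", ]
  expect_true(any(stops$context == "ATCGCGAAATGA"))
  expect_true(1554 %in% stops$pos)

  ## a 1-nt insertion causes a frameshift
  ins_allele <- paste0(substr(ref, 1, 1000), "G", substr(ref, 1001, n))
  ev2 <- scan_gene_disruptions(ins_allele, m)
  expect_true(any(ev2$kind == "frameshift" & ev2$gene == "acs"))

  ## removing most of the gene is a truncation
  tr_allele <- paste0(substr(ref, 1, 640), substr(ref, 1701, n))
  ev3 <- scan_gene_disruptions(tr_allele, m)
  expect_true(any(ev3$kind == "truncation" & ev3$gene == "acs"))
})
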