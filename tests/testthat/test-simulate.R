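test_that("the ancestral locus construction honors its contracts", {
  map <- ancestor_map()
  ## left repeat equals the reverse complement of the right repeat over the
  ## homologous span: originally identical
  left <- feature_seq(map, "left_ir")
  right_rc <- revcomp(feature_seq(map, "right_ir"))
  expect_identical(left, substr(right_rc, 1, nchar(left)))
  ## gene intervals host open reading frames (no internal stop in susL)
  s <- feature_seq(map, "susL")
  codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  expect_false(any(head(codons, -1) %in% c("TAA", "TAG", "TGA")))
  expect_equal(codons[1], "ATG")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77, n_accessions = 3)
  d1 <- file.path(tempdir(), "simdet1")
  d2 <- file.path(tempdir(), "simdet2")
  simulate_population(cfg, d1)
  simulate_population(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     label = paste("bytes of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth tables reconstruct every simulated allele", {
  truth <- demo_truth()
  refc <- strsplit(truth$reference$sequence, "")[[1]]
  for (a in truth$accessions) {
    for (h in a$haplotypes) {
      ops <- c(
        lapply(seq_len(nrow(h$subs)), function(i)
          list(pos = h$subs$pos[i], type = "sub", seq = h$subs$alt[i])),
        h$ops
      )
      rec <- paste(ctdnatools:::apply_ops(refc, ops), collapse = "")
      expect_identical(rec, h$seq, label = paste("conservation of", h$allele_id))
    }
  }
  ## and every truth deletion sequence matches the reference segment
  dels <- truth$indels[truth$indels$type == "del", ]
  for (i in seq_len(nrow(dels))) {
    expect_identical(
      substr(truth$reference$sequence, dels$pos[i] + 1,
             dels$pos[i] + nchar(dels$seq[i])),
      dels$seq[i]
    )
  }
})

test_that("an age-zero undiverged population equals its ancestor", {
  cfg <- sim_config(seed = 5, n_accessions = 3, insertion_age = 0,
                    clade_divergence = 0, allele_divergence_range = c(0, 0),
                    indels_per_allele = 0, n_clade_markers = 0,
                    p_rearranged_lineage = 0)
  truth <- simulate_population(cfg)
  expect_identical(truth$reference$sequence, truth$ancestor$sequence)
  for (a in truth$accessions) {
    expect_identical(a$haplotypes[[1]]$seq, truth$ancestor$sequence)
  }
  expect_equal(nrow(truth$indels), 0L)
})

test_that("plant inserts are flanked by their duplicated target motif", {
  truth <- demo_truth()
  ref <- truth$reference$sequence
  pl <- truth$indels[truth$indels$type == "plant_insert", ]
  expect_gt(nrow(pl), 0)   # the default spectrum draws plant inserts
  for (i in seq_len(nrow(pl))) {
    k <- nchar(pl$direct_repeat[i])
    ## left-aligned convention: motif at the insert head and duplicated in
    ## the reference immediately after the insertion point
    expect_identical(substr(pl$seq[i], 1, k), pl$direct_repeat[i])
    expect_identical(substr(ref, pl$pos[i] + 1, pl$pos[i] + k),
                     pl$direct_repeat[i])
    ## in the carrier allele the motif therefore flanks the plant sequence
    ## on both sides
  }
})

test_that("read counts and error-free reads behave as configured", {
  cfg <- sim_config(seed = 9, n_accessions = 2, coverage = 20,
                    p_rearranged_lineage = 0)
  truth <- simulate_population(cfg)
  a <- truth$accessions[[1]]
  rr <- generate_reads(a, cfg)
  len <- nchar(a$haplotypes[[1]]$seq)
  expected <- 2 * round(cfg$coverage * len / cfg$read_length)
  ## short end-overhang reads are discarded, so counts fall slightly below
  expect_lt(abs(nrow(rr$reads) - expected), 4 * sqrt(expected))
  ## error-free reads are exact substrings of a haplotype (or its RC)
  hap <- a$haplotypes[[1]]$seq
  set.seed(1)
  for (i in sample(nrow(rr$reads), 25)) {
    o <- rr$origins[i, ]
    h <- a$haplotypes[[o$hap]]$seq
    r <- rr$reads$seq[i]
    if (o$strand == "-") r <- revcomp(r)
    expect_identical(substr(h, o$start, o$start + nchar(r) - 1L), r)
  }
  ## every read is traceable to exactly one haplotype record
  expect_true(all(rr$reads$id == rr$origins$id))
  ## read names do not leak the haplotype of origin
  expect_false(any(grepl("hap|allele|_1_|_2_", rr$reads$id)))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_accessions = 0), "at least 1")
  expect_error(sim_config(p_heterozygous = 1.5), "probabilities")
  expect_error(sim_config(substitution_rate = 0), "positive")
  cfg <- sim_config(seed = 2, read_length = 10000L)
  anc <- build_ancestral_ctdna(cfg)
  truth <- evolve_population(anc, sim_config(seed = 2, n_accessions = 1,
                                             p_rearranged_lineage = 0))
  expect_error(generate_reads(truth$accessions[[1]], cfg),
               "read_length exceeds")
})

test_that("injected homoplasies are recorded and applied", {
  cfg <- sim_config(seed = 41, n_accessions = 12, n_homoplasy = 2,
                    p_rearranged_lineage = 0)
  truth <- simulate_population(cfg)
  expect_equal(nrow(truth$homoplasies), 2L)
  for (i in seq_len(nrow(truth$homoplasies))) {
    h <- truth$homoplasies[i, ]
    carried <- truth$indels[truth$indels$allele_id == h$allele_id, ]
    expect_true(h$marker %in%
                  paste0(sub("plant_insert", "ins", carried$type), carried$pos))
  }
})
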