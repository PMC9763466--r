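## the published 32-mer lost from the susL region of most alleles
SUSL_32MER <- "GCGGTGGAAAGTCTAATCACGAGTTGGTCGAG"

insert_after <- function(seq, pos, ins) {
  paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1, nchar(seq)))
}

delete_after <- function(seq, pos, len) {
  paste0(substr(seq, 1, pos), substr(seq, pos + len + 1, nchar(seq)))
}

test_that("a single insertion yields exactly one left-aligned catalog row", {
  map <- diverged_map()
  allele <- insert_after(map$sequence, 3182L, SUSL_32MER)
  ev <- call_indels(allele, map, min_len = 3)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "ins")
  expect_equal(ev$len, 32L)
  expect_equal(ev$pos, 3182L)
  expect_equal(ev$seq, SUSL_32MER)
})

test_that("an allele identical to the reference has an empty catalog", {
  map <- diverged_map()
  ev <- call_indels(map$sequence, map)
  expect_equal(nrow(ev), 0L)
})

test_that("deletions are reported at the 5'-most equivalent placement", {
  map <- diverged_map()
  ref <- map$sequence
  ## pick a deletion inside a homopolymer so placement is ambiguous
  run <- regexpr("(A{4,})", ref)
  pos <- as.integer(run)             # first base of the homopolymer
  allele <- delete_after(ref, pos + 1L, 3L)    # delete 3 bases mid-run
  ev <- call_indels(allele, map)
  expect_equal(nrow(ev), 1L)
  ## brute-force oracle: minimum over all equivalent placements
  eq <- equivalent_del_positions(ref, pos + 1L, 3L)
  expect_equal(ev$pos, min(eq))
})

test_that("deletion calls round-trip against the reference", {
  map <- diverged_map()
  ref <- map$sequence
  set.seed(5)
  for (i in 1:5) {
    pos <- sample(500:5000, 1)
    len <- sample(3:40, 1)
    allele <- delete_after(ref, pos, len)
    ev <- call_indels(allele, map)
    expect_equal(nrow(ev), 1L)
    ## reported sequence equals the reference segment after the position
    expect_equal(ev$seq, substr(ref, ev$pos + 1, ev$pos + ev$len))
    ## re-inserting the deleted segment reconstructs the reference
    expect_identical(insert_after(allele, ev$pos, ev$seq), ref)
  }
})

test_that("left-alignment is idempotent", {
  map <- diverged_map()
  refc <- strsplit(map$sequence, "")[[1]]
  la1 <- left_align_indel(refc, 3182L, "ins", SUSL_32MER)
  la2 <- left_align_indel(refc, la1$pos, "ins", la1$seq)
  expect_identical(la1, la2)
})

test_that("plant inserts are recognized by their duplicated target motif", {
  map <- diverged_map()
  ref <- map$sequence
  pos <- 1946L
  motif <- substr(ref, pos - 5L, pos)     # 6-mer target, duplicated on insert
  set.seed(9)
  ## screen the plant sequence so the duplicated motif cannot extend by
  ## chance (same hygiene as the population generator)
  repeat {
    plant <- random_dna(30)
    if (substr(plant, 1, 1) != substr(ref, pos + 1L, pos + 1L) &&
        substr(plant, 30, 30) != substr(ref, pos - 6L, pos - 6L)) break
  }
  allele <- insert_after(ref, pos, paste0(plant, motif))
  ev <- call_indels(allele, map)
  expect_equal(nrow(ev), 1L)
  ev2 <- classify_plant_insert(ev[1, ], map)
  expect_equal(ev2$type, "plant_insert")
  expect_equal(ev2$direct_repeat, motif)
})

test_that("insertions without flanking duplication stay plain insertions", {
  map <- diverged_map()
  ref <- map$sequence
  ins <- "GGTTCCAAGGTTCA"
  pos <- 2500L
  ## make sure the fixture really has no >=3 nt duplication at the flanks
  stopifnot(substr(ins, 1, 3) != substr(ref, pos + 1, pos + 3),
            substr(ins, 12, 14) != substr(ref, pos - 2, pos))
  ev <- make_ins_event(pos, ins)
  expect_equal(classify_plant_insert(ev, map)$type, "ins")
})

test_that("tandem duplications of local sequence are re-typed", {
  map <- diverged_map()
  ref <- map$sequence
  pos <- 2337L
  unit <- substr(ref, pos - 19L, pos)     # the 20-mer ending at pos
  allele1 <- insert_after(ref, pos, unit)
  ev1 <- call_indels(allele1, map)
  expect_equal(nrow(ev1), 1L)
  ev1 <- detect_tandem_duplication(ev1[1, ], map)
  expect_equal(ev1$type, "dupl")
  expect_equal(ev1$copies, 1L)
  ## double-length tandem: string-periodicity oracle gives copy number 2
  allele2 <- insert_after(ref, pos, strrep(unit, 2))
  ev2 <- call_indels(allele2, map)
  ev2 <- detect_tandem_duplication(ev2[1, ], map)
  expect_equal(ev2$type, "dupl")
  expect_equal(ev2$copies, 2L)
  ## a non-matching insert is unchanged
  ev3 <- make_ins_event(2500L, "TTGACCAGTTGACCAG")
  expect_equal(detect_tandem_duplication(ev3, map)$type, "ins")
})

test_that("catalog aggregation counts carrying alleles", {
  map <- diverged_map()
  ref <- map$sequence
  a1 <- delete_after(ref, 441L, 7L)
  a2 <- delete_after(ref, 441L, 7L)
  a3 <- delete_after(ref, 2552L, 10L)
  evs <- rbind(
    transform(call_indels(a1, map), allele_id = "x_1"),
    transform(call_indels(a2, map), allele_id = "x_2"),
    transform(call_indels(a3, map), allele_id = "y_1")
  )
  cat <- aggregate_catalog(evs)
  expect_equal(nrow(cat), 2L)
  shared <- cat[cat$x == 2L, ]
  expect_equal(shared$alleles, "x_1,x_2")
  ## overlapping but distinct deletions remain separate rows
  b1 <- delete_after(ref, 2779L, 11L)
  b2 <- delete_after(ref, 2779L, 5L)
  evs2 <- rbind(
    transform(call_indels(b1, map), allele_id = "p"),
    transform(call_indels(b2, map), allele_id = "q")
  )
  cat2 <- aggregate_catalog(evs2)
  expect_equal(nrow(cat2), 2L)
})

test_that("simulator-injected indels are recovered exactly", {
  truth <- demo_truth()
  map <- truth$reference
  alleles <- truth_alleles(truth, include_inverted = FALSE)
  recovered <- list()
  cache <- alignment_cache()
  for (id in names(alleles)) {
    al <- structure(list(sequence = alleles[[id]], allele_id = id),
                    class = "phased_allele")
    ev <- call_indels(al, map, cache = cache)
    if (nrow(ev)) { ev$allele_id <- id; recovered[[id]] <- ev }
  }
  rec <- do.call(rbind, recovered)
  tru <- truth$indels
  ## every injected event is recovered with exact position, length, sequence
  key_rec <- sort(paste(rec$allele_id, rec$pos, rec$seq))
  key_tru <- sort(paste(tru$allele_id, tru$pos, tru$seq))
  expect_identical(key_rec, key_tru)
  ## and classification recovers the injected type and direct repeat
  rec <- classify_insertions(rec, map)
  m <- merge(rec, tru, by = c("allele_id", "pos"))
  expect_true(all(m$type.x == m$type.y))
  expect_true(all(m$direct_repeat.x == m$direct_repeat.y))
  ## catalog totals match injection counts
  cat <- aggregate_catalog(rec)
  expect_equal(sum(cat$x), nrow(tru))
})

test_that("hypervariable regions emerge from the published catalog positions", {
  ## positions of the published indel table are the input here
  pos <- c(239, 255, 258, 438, 440, 441, 442, 444, 446, 449, 449, 449, 626,
           640, 1012, 1277, 1508, 1712, 1790, 1928, 1946, 2001, 2146, 2146,
           2152, 2337, 2553, 2644, 2744, 2748, 2767, 2768, 2769, 2769, 2770,
           2772, 2774, 2779, 2779, 2781, 2781, 2824, 3085, 3182, 3383, 3471,
           3525, 3574, 3664, 3687, 3736, 3789, 3905, 3962, 3962, 3962, 3962,
           3962, 3962, 3969, 4183, 4440, 5238, 5347)
  catalog <- data.frame(pos = pos)
  regions <- report_hypervariable_regions(catalog, window = 15, min_events = 5)
  expect_equal(nrow(regions), 2L)
  expect_equal(regions$start, c(438L, 2767L))
  expect_equal(regions$end, c(449L, 2781L))
  ## uniform sparse events yield nothing
  sparse <- data.frame(pos = seq(100L, 5000L, by = 100L))
  expect_equal(nrow(report_hypervariable_regions(sparse)), 0L)
})

test_that("region BED export uses 0-based half-open intervals", {
  regions <- data.frame(start = 438L, end = 449L, n_positions = 7L)
  path <- tempfile(fileext = ".bed")
  write_regions_bed(regions, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 437L)
  expect_equal(bed$V3, 449L)
})
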