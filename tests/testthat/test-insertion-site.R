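## published motifs of the insert-A analysis
TIR_MOTIF <- "TGCAACTAAG"
TSD_MOTIF <- "GTCCAGCT"

## build an insert with the published terminal inverted repeat: motif at the
## 5' end, its reverse complement at the 3' end, screened random interior
make_tir_insert <- function(interior_len = 280L, motif = TIR_MOTIF) {
  repeat {
    interior <- random_dna(interior_len)
    ins <- paste0(motif, interior, revcomp(motif))
    probe <- detect_terminal_ir(
      data.frame(start = 1L, end = nchar(ins)), ins,
      min_len = 5, max_mismatch = 0
    )
    if (probe$terminal_ir_len == nchar(motif)) return(ins)
  }
}

test_that("empty-vs-filled comparison recovers a planted insertion exactly", {
  set.seed(101)
  a <- random_dna(1200)
  b <- random_dna(900)
  ins <- random_dna(400)
  empty <- paste0(a, b)
  filled <- paste0(a, ins, b)
  calls <- align_empty_vs_filled(empty, filled)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "filled_only")
  expect_equal(calls$start, 1201L)
  expect_equal(calls$end, 1600L)
  ## identical sequences produce no calls
  expect_equal(nrow(align_empty_vs_filled(empty, empty)), 0L)
})

test_that("the published empty/filled geometry is recovered", {
  ## geometry of the insertion-site figure: common 1219, insert A (1042, with
  ## terminal IR + TSD) in the empty-site genome, 88-nt spacer, the 5286-nt
  ## cT-DNA plus an 872-nt ligated plant sequence in the filled genome, a
  ## 73-nt segment lost in the filled lineage, common tail
  set.seed(202)
  insertA_core <- make_tir_insert(1042L - 2L * nchar(TIR_MOTIF))
  ## screen the neighboring pieces so the planted 8-mer target duplication is
  ## maximal (no chance extension into the insert)
  core_first <- substr(insertA_core, 1, 1)
  core_last <- substr(insertA_core, 1042, 1042)
  repeat {
    common1 <- random_dna(1219)
    if (substr(common1, 1219, 1219) != core_last) break
  }
  repeat {
    spacer88 <- random_dna(88)
    if (substr(spacer88, 1, 1) != core_first) break
  }
  ctdna <- random_dna(5286)
  insertB <- random_dna(872)
  lost73 <- random_dna(73)
  common2 <- random_dna(250)
  common3 <- random_dna(930)
  target <- TSD_MOTIF

  empty <- paste0(common1, target, insertA_core, target, spacer88,
                  common2, lost73, common3)
  filled <- paste0(common1, target, spacer88, ctdna, insertB,
                   common2, common3)
  calls <- align_empty_vs_filled(empty, filled)

  emp <- calls[calls$kind == "empty_only", ]
  fil <- calls[calls$kind == "filled_only", ]
  ## insert A and the 73-nt segment on the empty side; cT-DNA + ligated
  ## plant DNA on the filled side
  expect_equal(sort(emp$length), c(73L, 1042L + nchar(TSD_MOTIF)))
  expect_equal(fil$length, 5286L + 872L)

  ## TSD detection trims the duplicated target copy and reports the motif
  ia <- emp[which.max(emp$length), ]
  ia <- detect_tsd(ia, empty)
  expect_equal(ia$tsd, TSD_MOTIF)
  expect_equal(ia$length, 1042L)

  ## terminal inverted repeat of insert A
  ia <- detect_terminal_ir(ia, empty, min_len = 5, max_mismatch = 0)
  expect_equal(ia$terminal_ir_len, 10L)
  expect_equal(ia$terminal_ir_seq, TIR_MOTIF)
})

test_that("terminal IR detection matches a brute-force scan", {
  set.seed(33)
  ins <- make_tir_insert(280L)
  call <- data.frame(start = 1L, end = nchar(ins))
  out <- detect_terminal_ir(call, ins, min_len = 5, max_mismatch = 0)
  expect_equal(out$terminal_ir_len, 10L)
  expect_equal(out$terminal_ir_seq, TIR_MOTIF)

  ## invariance under reverse complement of the insert
  rc <- revcomp(ins)
  out_rc <- detect_terminal_ir(data.frame(start = 1L, end = nchar(rc)), rc,
                               min_len = 5, max_mismatch = 0)
  expect_equal(out_rc$terminal_ir_len, out$terminal_ir_len)

  ## no terminal complementarity: length 0
  repeat {
    plain <- random_dna(200)
    probe <- detect_terminal_ir(data.frame(start = 1L, end = 200L), plain,
                                min_len = 5, max_mismatch = 0)
    break
  }
  expect_equal(probe$terminal_ir_len, 0L)
})

test_that("a mismatch inside the terminal IR is tolerated only when allowed", {
  set.seed(44)
  arm <- random_dna(25)
  interior <- random_dna(150)
  ins <- paste0(arm, interior, revcomp(arm))
  ## plant one mismatch at arm position 12
  ch <- strsplit(ins, "")[[1]]
  ch[12] <- setdiff(c("A", "C", "G", "T"), ch[12])[1]
  ins_mm <- paste(ch, collapse = "")
  call <- data.frame(start = 1L, end = nchar(ins_mm))
  tol <- detect_terminal_ir(call, ins_mm, min_len = 5, max_mismatch = 1)
  expect_equal(tol$terminal_ir_len, 25L)
  strict <- detect_terminal_ir(call, ins_mm, min_len = 5, max_mismatch = 0)
  expect_equal(strict$terminal_ir_len, 11L)   # longest exact core
})

test_that("the longest duplicated flank motif wins", {
  set.seed(55)
  a <- random_dna(600)
  b <- random_dna(600)
  motif8 <- "GATCCTGA"
  ## screen the random pieces so the planted 8-mer is the maximal duplication
  repeat {
    ins <- random_dna(120)
    if (substr(ins, 120, 120) != substr(a, 600, 600) &&
        substr(ins, 1, 1) != substr(b, 1, 1)) break
  }
  ## the 8-mer contains a 4-mer duplication as its suffix; the 8-mer wins
  filled <- paste0(a, motif8, ins, motif8, b)
  empty <- paste0(a, motif8, b)
  calls <- align_empty_vs_filled(empty, filled)
  expect_equal(nrow(calls), 1L)
  out <- detect_tsd(calls[1, ], filled)
  expect_equal(out$tsd, motif8)
  expect_equal(out$length, 120L)
  ## with unrelated flanks no TSD is reported
  plain <- detect_tsd(data.frame(start = 700L, end = 800L), paste0(a, b))
  expect_equal(plain$tsd_len, 0L)
})

test_that("deleting filled-only calls reconstructs the empty sequence", {
  set.seed(66)
  a <- random_dna(800); b <- random_dna(700); c <- random_dna(900)
  i1 <- random_dna(150); i2 <- random_dna(300)
  empty <- paste0(a, b, c)
  filled <- paste0(a, i1, b, i2, c)
  calls <- align_empty_vs_filled(empty, filled)
  fil <- calls[calls$kind == "filled_only", ]
  fil <- fil[order(-fil$start), ]
  rec <- filled
  for (i in seq_len(nrow(fil))) {
    rec <- paste0(substr(rec, 1, fil$start[i] - 1L),
                  substr(rec, fil$end[i] + 1L, nchar(rec)))
  }
  expect_identical(rec, empty)
})

test_that("insert presence is screened across other sequences", {
  set.seed(77)
  a <- random_dna(500); b <- random_dna(500)
  ins <- random_dna(200)
  filled <- paste0(a, ins, b)
  call <- data.frame(start = 501L, end = 700L)
  others <- c(carrier = paste0(random_dna(100), ins, random_dna(50)),
              free = random_dna(400))
  pres <- insert_presence(call, filled, others)
  expect_true(pres[["carrier"]])
  expect_false(pres[["free"]])
})
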