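## shared fixtures; expensive objects are memoized on disk for the duration
## of the test session (tempdir is per-process)

cache_rds <- function(key, expr) {
  path <- file.path(tempdir(), paste0("ctdnatools-test-", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- force(expr)
  saveRDS(val, path)
  val
}

## ancestral locus under the default configuration (identical repeats)
ancestor_map <- function() {
  cache_rds("ancestor", build_ancestral_ctdna(sim_config(seed = 1)))
}

## present-day-like mapping reference: repeats diverged to ~9.7%
diverged_map <- function() {
  cache_rds("diverged", apply_repeat_divergence(ancestor_map(), 0.097, seed = 7))
}

## a small evolved population with truth tables
demo_truth <- function() {
  cache_rds("truth", {
    cfg <- sim_config(seed = 11, n_accessions = 10, p_rearranged_lineage = 0)
    simulate_population(cfg)
  })
}

## flatten unique haplotypes of a truth object: named character vector
truth_alleles <- function(truth, include_inverted = TRUE) {
  out <- character(0)
  for (a in truth$accessions) {
    if (!include_inverted && a$structural_class != "standard") next
    for (h in a$haplotypes) out[h$allele_id] <- h$seq
  }
  out
}

## build a one-row insertion event as call_indels would report it
make_ins_event <- function(pos, seq, allele_id = "x") {
  data.frame(
    allele_id = allele_id, pos = as.integer(pos), type = "ins", seq = seq,
    len = nchar(seq), direct_repeat = "", copies = 1L,
    compound = FALSE, partial = FALSE, stringsAsFactors = FALSE
  )
}

## brute-force oracle: all equivalent placements of a deletion in `ref`,
## returned as the set of possible "last base before event" positions
equivalent_del_positions <- function(ref, pos, len) {
  ch <- strsplit(ref, "")[[1]]
  res <- integer(0)
  without <- function(p) paste(ch[-((p + 1):(p + len))], collapse = "")
  target <- without(pos)
  for (p in 0:(nchar(ref) - len)) {
    if (identical(without(p), target)) res <- c(res, p)
  }
  res
}
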