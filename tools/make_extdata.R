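## Regenerates the bundled synthetic reference locus (inst/extdata).
## The sequence is synthetic: ancestral locus geometry per the published
## coordinates, with the two inverted repeats diverged to ~10% as in a
## present-day reference sequence. Run from the package root:
##   Rscript tools/make_extdata.R
pkgload::load_all(".", quiet = TRUE)

map <- apply_repeat_divergence(
  build_ancestral_ctdna(sim_config(seed = 424242L)),
  divergence = 0.097, seed = 424242L
)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_reference(map,
                "inst/extdata/synthetic_reference.fasta",
                "inst/extdata/synthetic_reference_features.tsv")
rp <- extract_repeats(map$sequence, map)
cat(sprintf("bundled reference: %d nt, repeat identity %.2f%%\n",
            nchar(map$sequence), rp$identity))
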