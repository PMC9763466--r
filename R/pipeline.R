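#' Pipeline configuration
#'
#' Bundles the simulation settings and analysis thresholds of one
#' reproducible run. Unknown keys are rejected; the configuration is echoed
#' verbatim (as JSON) into the run directory.
#'
#' @param sim a [sim_config()] object (the simulated input).
#' @param input `"reads"` (simulate reads, then recruit + phase) or
#'   `"alleles"` (analyze the simulated haplotype sequences directly, the
#'   pre-assembled-alleles input mode).
#' @param min_coverage phasing coverage gate, see [phase_alleles()].
#' @param min_identity,min_overlap recruitment thresholds, see
#'   [recruit_reads()].
#' @param n_bootstrap bootstrap replicates for [build_tree()].
#' @param marker_min_count catalog carrier count for marker status.
#' @param gap_threshold gap-column threshold for [align_alleles()].
#' @param catalog_min_len minimum indel length cataloged.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input = c("reads", "alleles"),
                            min_coverage = 10, min_identity = 0.8,
                            min_overlap = 50L, n_bootstrap = 100L,
                            marker_min_count = 3L, gap_threshold = 0.2,
                            catalog_min_len = 3L) {
  input <- match.arg(input)
  cfg <- list(
    sim = sim, input = input, min_coverage = min_coverage,
    min_identity = min_identity, min_overlap = min_overlap,
    n_bootstrap = as.integer(n_bootstrap),
    marker_min_count = as.integer(marker_min_count),
    gap_threshold = gap_threshold, catalog_min_len = as.integer(catalog_min_len)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> phase -> repeat/dating/structure/gene-scan ->
#' indel catalog -> tree/groups/pair-spans as one seeded, reproducible run,
#' writing every report into `out_dir`. Identical configurations produce
#' byte-identical run directories. A stage failure aborts with a
#' stage-tagged message; outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir run directory (created if absent).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## echo configuration
  cfg_echo <- config
  cfg_echo$sim$indel_spectrum <- NULL
  jsonlite::write_json(unclass(cfg_echo), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  ## stage: simulate
  truth <- stage("simulate", simulate_population(config$sim,
                                                 file.path(out_dir, "sim")))
  map <- truth$reference

  ## stage: phase (or collect pre-assembled alleles)
  alleles <- list()      # named list id -> sequence
  statuses <- list()     # per accession
  pair_rows <- list()
  if (config$input == "reads") {
    stage("phase", {
      for (a in truth$accessions) {
        rr <- generate_reads(a, config$sim)
        pr <- phase_accession(rr$reads, map, accession = a$accession,
                              min_identity = config$min_identity,
                              min_overlap = config$min_overlap,
                              min_coverage = config$min_coverage)
        statuses[[a$accession]] <- pr
        for (al in pr$alleles) alleles[[al$allele_id]] <- al$sequence
        if (pr$status == "paired") {
          pair_rows[[a$accession]] <- data.frame(
            accession = a$accession,
            allele_id = vapply(pr$alleles, function(x) x$allele_id, character(1)),
            stringsAsFactors = FALSE
          )
        }
      }
    })
  } else {
    stage("phase", {
      for (a in truth$accessions) {
        if (a$heterozygous) {
          for (h in a$haplotypes) alleles[[h$allele_id]] <- h$seq
          statuses[[a$accession]] <- list(status = "paired")
          pair_rows[[a$accession]] <- data.frame(
            accession = a$accession,
            allele_id = vapply(a$haplotypes, function(h) h$allele_id, character(1)),
            stringsAsFactors = FALSE
          )
        } else {
          id <- paste0(a$accession, "_un")
          alleles[[id]] <- a$haplotypes[[1]]$seq
          statuses[[a$accession]] <- list(status = "unique")
        }
      }
    })
  }
  status_vec <- vapply(statuses, function(s) s$status, character(1))
  phasing_tab <- data.frame(
    accession = names(statuses), status = unname(status_vec),
    stringsAsFactors = FALSE
  )
  .write_tsv(phasing_tab, file.path(out_dir, "phasing.tsv"))
  if (length(alleles)) {
    write_fasta(unlist(alleles), file.path(out_dir, "phased_alleles.fasta"))
  }

  cache <- alignment_cache()
  ids <- names(alleles)
  ## wrap sequences so downstream stages share cached alignments per allele
  wrapped <- lapply(ids, function(id) {
    structure(list(sequence = alleles[[id]], allele_id = id),
              class = "phased_allele")
  })
  names(wrapped) <- ids

  ## stage: repeats + dating
  rep_rows <- list(); age_rows <- list()
  stage("repeats", {
    for (id in ids) {
      rp <- extract_repeats(wrapped[[id]], map, cache = cache)
      rp$allele_id <- id
      rep_rows[[id]] <- data.frame(
        allele_id = id, status = rp$status,
        identity = rp$identity, divergence = rp$divergence,
        aligned_cols = rp$aligned_cols, stringsAsFactors = FALSE
      )
      if (rp$status == "ok") {
        dr <- date_insertion(rp, rate = config$sim$substitution_rate,
                             convention = config$sim$dating_convention)
        age_rows[[id]] <- data.frame(
          allele_id = id, age_years = dr$age,
          age_lo = dr$age_ci[1], age_hi = dr$age_ci[2],
          stringsAsFactors = FALSE
        )
      }
    }
  })
  repeats_tab <- do.call(rbind, rep_rows)
  dating_tab <- do.call(rbind, age_rows)
  if (!is.null(repeats_tab)) .write_tsv(repeats_tab, file.path(out_dir, "repeats.tsv"))
  if (!is.null(dating_tab)) .write_tsv(dating_tab, file.path(out_dir, "dating.tsv"))

  ## stage: structure classification
  struct_rows <- list()
  stage("structure", {
    for (id in ids) {
      sc <- classify_structure(wrapped[[id]], map)
      struct_rows[[id]] <- data.frame(
        allele_id = id, class = sc$class, evidence = sc$evidence,
        stringsAsFactors = FALSE
      )
    }
  })
  struct_tab <- do.call(rbind, struct_rows)
  if (!is.null(struct_tab)) .write_tsv(struct_tab, file.path(out_dir, "structure.tsv"))
  standard_ids <- struct_tab$allele_id[struct_tab$class == "standard"]
  inverted_ids <- struct_tab$allele_id[struct_tab$class == "inverted_center"]

  ## stage: gene disruptions (standard architecture only; the rearranged
  ## form is not colinear with the annotation)
  stage("disruptions", {
    dis <- lapply(standard_ids, function(id) {
      d <- scan_gene_disruptions(wrapped[[id]], map, cache = cache)
      if (nrow(d)) d$allele_id <- id
      d
    })
    dis <- do.call(rbind, dis)
    if (!is.null(dis)) .write_tsv(dis, file.path(out_dir, "disruptions.tsv"))
  })

  ## stage: indel catalog (standard alleles; see structure.tsv for the rest)
  catalog <- NULL
  stage("indels", {
    evs <- lapply(standard_ids, function(id) {
      e <- call_indels(wrapped[[id]], map, min_len = config$catalog_min_len,
                       cache = cache)
      if (nrow(e)) e$allele_id <- id
      e
    })
    evs <- do.call(rbind, evs)
    if (is.null(evs)) evs <- .empty_events()
    evs <- classify_insertions(evs, map)
    catalog <- aggregate_catalog(evs)
    .write_tsv(catalog, file.path(out_dir, "catalog.tsv"))
    regions <- report_hypervariable_regions(catalog)
    write_regions_bed(regions, file.path(out_dir, "hypervariable.bed"))
  })

  ## stage: tree + concordance
  report <- NULL; spans <- NULL
  if (length(ids) >= 4) {
    stage("tree", {
      tree_seqs <- unlist(alleles)
      ## re-orient inverted-center alleles so the tree alignment is colinear
      for (id in inverted_ids) {
        tree_seqs[[id]] <- standardize_structure(alleles[[id]], map)
      }
      msa <- align_alleles(tree_seqs, map,
                           gap_threshold = config$gap_threshold, cache = NULL)
      outgroup <- if (length(inverted_ids)) inverted_ids[1] else {
        d <- ape::dist.dna(ape::as.DNAbin(tolower(msa$matrix)),
                           model = "JC69", pairwise.deletion = TRUE)
        dm <- as.matrix(d)
        rownames(dm)[which.max(rowMeans(dm, na.rm = TRUE))]
      }
      tree <- build_tree(msa, outgroup, n_bootstrap = config$n_bootstrap,
                         seed = config$sim$seed)
      write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
      mk <- markers_from_catalog(catalog, ids,
                                 min_count = config$marker_min_count)
      report <- assign_groups(tree, mk, extra_outgroup = inverted_ids)
      .write_tsv(
        data.frame(allele_id = names(report$groups),
                   group = unname(report$groups),
                   subgroup = unname(report$subgroups)),
        file.path(out_dir, "groups.tsv")
      )
      if (nrow(report$exceptions)) {
        .write_tsv(report$exceptions, file.path(out_dir, "exceptions.tsv"))
      }
      pairs_df <- do.call(rbind, pair_rows)
      spans <- pair_spans(report, pairs_df)
      .write_tsv(spans$table, file.path(out_dir, "pairs.tsv"))
    })
  }

  n_unique <- sum(status_vec == "unique")
  n_paired <- sum(status_vec == "paired")
  summary <- list(
    n_accessions = length(statuses),
    n_unique = n_unique,
    n_paired = n_paired,
    n_insufficient = sum(status_vec == "insufficient"),
    n_alleles = n_unique + 2L * n_paired,
    mean_repeat_identity = if (!is.null(repeats_tab))
      mean(repeats_tab$identity, na.rm = TRUE) else NA,
    mean_age_years = if (!is.null(dating_tab))
      mean(dating_tab$age_years) else NA,
    dating_convention = config$sim$dating_convention,
    n_inverted_center = length(inverted_ids),
    n_catalog_rows = if (!is.null(catalog)) nrow(catalog) else 0L,
    groups = if (!is.null(report)) as.list(table(report$groups)) else NULL,
    n_exceptions = if (!is.null(report)) nrow(report$exceptions) else NA,
    n_pairs = if (!is.null(spans)) spans$n_pairs else NA,
    n_cross_pairs = if (!is.null(spans)) spans$n_cross else NA
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

#' Re-orient an inverted-center allele to the standard architecture
#'
#' Locates the two inverted repeats on the allele and reverse-complements the
#' unique segment between them, yielding a sequence colinear with the
#' standard form (used for tree alignment of rearranged alleles).
#'
#' @param allele a `phased_allele` or DNA string.
#' @param map a [ref_map()] object.
#' @return DNA string.
#' @export
standardize_structure <- function(allele, map) {
  seq <- allele_seq_of(allele)
  locate <- function(feature) {
    pat <- feature_seq(map, feature)
    aln <- Biostrings::pairwiseAlignment(
      pattern = pat, subject = seq, type = "local",
      substitutionMatrix = .ctdna_submat(), gapOpening = 4, gapExtension = 1
    )
    c(Biostrings::start(Biostrings::subject(aln)),
      Biostrings::end(Biostrings::subject(aln)))
  }
  li <- locate("left_ir")
  ri <- locate("right_ir")
  if (ri[1] <= li[2] + 1L) return(seq)
  center <- substr(seq, li[2] + 1L, ri[1] - 1L)
  paste0(substr(seq, 1L, li[2]), revcomp(center),
         substr(seq, ri[1], nchar(seq)))
}
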