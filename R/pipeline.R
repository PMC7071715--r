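#' Identify and characterize family members in a proteome
#'
#' The identification stage of the pipeline: builds the profile scoring
#' matrix from the seed alignment, scans every protein, maps the best hit
#' per protein onto canonical coordinates, classifies DNA-binding
#' categories and computes protein statistics and the conservation profile.
#'
#' @param proteins Protein data.frame from [read_fasta()].
#' @param seed_aln A [seed_alignment()] of reference domains.
#' @param threshold_bits Domain-calling threshold.
#' @param pseudocount PSSM pseudocount (see [build_pssm()]).
#' @param basic_set Residues counted as basic for classification.
#' @param out_dir Optional output directory for TSV exports.
#' @param verbose Log stage counts via `message()`.
#' @return List with `pssm`, `hits`, `domains`, `categories`,
#'   `category_counts`, `consensus`, `protein_stats`, `log`.
#' @export
run_identify <- function(proteins, seed_aln,
                         threshold_bits = BHLH_DEFAULT_THRESHOLD_BITS,
                         pseudocount = 20, basic_set = c("K", "R", "H"),
                         out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[identify] ", ...)
  pssm <- build_pssm(seed_aln, pseudocount)
  say("scanning ", nrow(proteins), " proteins (threshold ",
      threshold_bits, " bits)")
  hits <- scan_proteome(pssm, proteins, threshold_bits)
  domains <- canonical_domains(hits, proteins)
  say("found ", nrow(domains), " family members")
  if (nrow(domains) > 0L) {
    categories <- classify_domains(domains, basic_set)
    counts <- category_counts(categories)
    consensus <- consensus_profile(domains)
    stats <- protein_stats(proteins[proteins$id %in% rownames(domains), ])
  } else {
    categories <- setNames(character(0), character(0))
    counts <- category_counts(character(0))
    consensus <- NULL
    stats <- protein_stats(proteins[integer(0), ])
  }
  say("categories: ", paste(names(counts), counts, sep = "=",
                            collapse = ", "))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hits_tsv(hits, file.path(out_dir, "domain_hits.tsv"))
    write_category_tsv(categories, file.path(out_dir, "binding_categories.tsv"))
    if (!is.null(consensus)) {
      write_consensus_tsv(consensus, file.path(out_dir, "consensus_profile.tsv"))
    }
    write_protein_stats(stats, file.path(out_dir, "protein_stats.tsv"))
  }
  list(pssm = pssm, hits = hits, domains = domains, categories = categories,
       category_counts = counts, consensus = consensus,
       protein_stats = stats,
       log = list(n_scanned = nrow(proteins), n_found = nrow(domains),
                  counts = counts))
}

#' Run the full pipeline on a simulated (or assembled) study
#'
#' Orchestrates every stage — identification/characterization, ortholog
#' naming, phylogeny with bootstrap and subfamily inheritance, duplication
#' calling, and Fe-deficiency candidate prioritization — and returns a
#' consolidated report. All randomness (bootstrap resampling) is derived
#' from the study's master seed.
#'
#' @param study Study list from [simulate_bhlh_study()], or a manually
#'   assembled list with the same elements.
#' @param out_dir Optional output directory (writes TSVs, Newick tree and
#'   `report.json`).
#' @param params Named list of stage-parameter overrides:
#'   `threshold_bits`, `basic_set`, `base_prefix`, `n_bootstrap`,
#'   `min_block`, `max_gap`, `min_identity`, `tpm_cut`, `alpha`, `margin`.
#' @param verbose Log stage progress.
#' @return Report list (also serialized to JSON when `out_dir` is given).
#' @export
run_full <- function(study, out_dir = NULL, params = list(), verbose = TRUE) {
  p <- list(threshold_bits = BHLH_DEFAULT_THRESHOLD_BITS,
            basic_set = c("K", "R", "H"), base_prefix = "bHLH",
            n_bootstrap = 100L, min_block = 5L, max_gap = 25L,
            min_identity = 40, tpm_cut = study$config$expression$tpm_cut,
            alpha = 0.05, margin = 1)
  bad <- setdiff(names(params), names(p))
  if (length(bad) > 0L) stop("unknown parameter(s): ",
                             paste(bad, collapse = ", "))
  p[names(params)] <- params
  say <- function(...) if (verbose) message("[full] ", ...)

  ident <- run_identify(study$proteome$proteins,
                        study$proteome$seed_alignment,
                        threshold_bits = p$threshold_bits,
                        basic_set = p$basic_set,
                        out_dir = out_dir, verbose = verbose)
  family_ids <- rownames(ident$domains)

  say("naming ", length(family_ids), " candidates against ",
      nrow(study$proteome$references), " references")
  fam_records <- study$proteome$proteins[
    study$proteome$proteins$id %in% family_ids, , drop = FALSE]
  idm <- identity_matrix(fam_records, study$proteome$references)
  naming <- assign_names(idm, base_prefix = p$base_prefix)

  say("phylogeny: NJ with ", p$n_bootstrap, " bootstrap replicates")
  all_domains <- rbind(ident$domains, study$proteome$reference_domains)
  tree <- bootstrap_support(all_domains, n_reps = p$n_bootstrap,
                            seed = study$config$seed + 4L)
  subfam <- assign_subfamilies(tree, study$proteome$truth$reference_labels)

  say("duplication calling")
  ranks <- gene_rank_index(study$layout$models)
  tandem <- find_tandem(family_ids, ranks, study$layout$homologs,
                        min_identity = p$min_identity)
  coll <- find_collinear_blocks(study$layout$homologs, ranks,
                                min_block = p$min_block, max_gap = p$max_gap,
                                family_ids = family_ids,
                                min_identity = p$min_identity)

  say("candidate prioritization")
  expr <- study$expression
  expressed <- expressed_genes(expr$tpm)
  go_set <- go_gene_set(expr$go,
                        study$config$expression$go_term[["term_name"]])
  casc <- cascade(expressed, go_set, expr$tpm, tpm_cut = p$tpm_cut)
  qres <- qpcr_timecourse(study$qpcr$ct, alpha = p$alpha, margin = p$margin)
  keys <- key_candidates(qres)

  conserved50 <- conserved_positions(ident$consensus, 0.5)
  conserved80 <- conserved_positions(ident$consensus, 0.8)
  report <- list(
    n_proteins_scanned = nrow(study$proteome$proteins),
    n_family_found = length(family_ids),
    category_counts = as.list(ident$category_counts),
    n_conserved_50 = nrow(conserved50),
    conserved_50_positions = conserved50$position,
    n_conserved_80 = nrow(conserved80),
    naming = naming,
    subfamilies = as.list(subfam),
    tandem = tandem,
    tandem_gene_count = length(unique(tandem$gene_id)),
    blocks = coll$blocks,
    segmental_gene_count = length(unique(coll$segmental$gene_id)),
    venn_counts = as.list(casc$counts),
    shortlist = casc$shortlist,
    key_candidates = keys,
    pattern_types = as.list(table(qres$per_gene$pattern_type))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(naming, file.path(out_dir, "family_names.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_newick(tree, file.path(out_dir, "family_tree.nwk"))
    write.table(qres$per_timepoint, file.path(out_dir, "qpcr_timecourse.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(coll$blocks, file.path(out_dir, "collinear_blocks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tandem, file.path(out_dir, "tandem_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      report[c("n_proteins_scanned", "n_family_found", "category_counts",
               "n_conserved_50", "n_conserved_80", "tandem_gene_count",
               "segmental_gene_count", "venn_counts", "key_candidates")],
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  say("done")
  invisible(report)
}
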