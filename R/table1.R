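#' Packaged summary table of a real 128-member citrus bHLH family
#'
#' A transcription of the published summary of 128 pummelo bHLH genes: the
#' family name, ORF length (bp, including the stop codon), genome gene id,
#' best Arabidopsis homolog, its common abbreviation (NA when none is in
#' use) and the percent identity to it. It serves as a small real-data
#' fixture for count-based checks of the naming and ORF-arithmetic
#' conventions.
#'
#' @return Data.frame with columns `no`, `gene_name`, `orf_bp`, `gene_id`,
#'   `at_homolog`, `abbr_name`, `identity_pct`.
#' @export
bhlh_table1 <- function() {
  path <- system.file("extdata", "cgbhlh_table1.tsv", package = "bhlhtools",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Chromosome from a citrus-style gene id
#'
#' Gene ids of the form `Cg5g002660` encode the chromosome between `Cg` and
#' `g`; `Un` marks an unanchored (unknown-chromosome) gene.
#'
#' @param gene_id Character vector of gene ids.
#' @return Character vector like `"chr5"` or `"chrUn"`.
#' @export
chromosome_from_gene_id <- function(gene_id) {
  m <- regmatches(gene_id, regexpr("^Cg(\\d+|Un)", gene_id))
  if (any(!nzchar(m)) || length(m) != length(gene_id)) {
    stop("gene id(s) not in Cg<chrom>g... form")
  }
  paste0("chr", sub("^Cg", "", m))
}

#' Summary statistics of the packaged family table
#'
#' Recomputes the headline counts of the fixture: ORF length range and the
#' encoded protein-length range, the number of genes with ORF length in
#' 700-2000 bp, per-chromosome gene counts, and the identity range.
#'
#' @param tbl Table from [bhlh_table1()].
#' @return Named list of summaries.
#' @export
table1_summary <- function(tbl = bhlh_table1()) {
  chrom <- chromosome_from_gene_id(tbl$gene_id)
  counts <- table(chrom)
  named <- grepl("^chr[0-9]+$", names(counts))
  list(
    n_genes = nrow(tbl),
    orf_bp_range = range(tbl$orf_bp),
    aa_range = range(protein_length_from_orf(tbl$orf_bp)),
    n_orf_700_2000 = sum(tbl$orf_bp >= 700 & tbl$orf_bp <= 2000),
    chromosome_counts = counts,
    n_on_named_chromosomes = sum(counts[named]),
    identity_range = range(tbl$identity_pct)
  )
}
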