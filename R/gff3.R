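#' Read gene models from a GFF3 file
#'
#' Parses gene / mRNA / exon / CDS / UTR features (linked through `ID` and
#' `Parent` attributes) into one gene model per gene. Exons from all
#' transcripts of a gene are collated, merged where they overlap, and sorted
#' by ascending start regardless of strand. Coordinates are kept 1-based
#' inclusive, the GFF3 convention.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `id`, `chromosome`, `start`, `end`,
#'   `strand`, `n_exons`, `utr_present`, and a list-column `exons` holding a
#'   two-column data.frame (`start`, `end`) per gene.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 (check that end >= start on every line): ",
                             conditionMessage(e))
  )
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList
  first_parent <- vapply(as.list(parents), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1))

  gene_idx <- which(type == "gene")
  if (length(gene_idx) == 0L) stop("no gene features in ", path)
  gene_ids <- ids[gene_idx]

  # transcript (mRNA) -> gene map; exons point at transcripts
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  tx2gene <- setNames(first_parent[tx_idx], ids[tx_idx])

  resolve_gene <- function(parent, what) {
    if (is.na(parent)) stop(what, " feature without a Parent attribute")
    if (parent %in% gene_ids) return(parent)
    if (parent %in% names(tx2gene)) {
      g <- tx2gene[[parent]]
      if (g %in% gene_ids) return(g)
    }
    stop(what, " with Parent '", parent, "' that maps to no gene feature")
  }

  exon_idx <- which(type == "exon")
  exon_gene <- vapply(first_parent[exon_idx], resolve_gene, character(1),
                      what = "exon")
  utr_idx <- which(type %in% c("five_prime_UTR", "three_prime_UTR"))
  utr_gene <- if (length(utr_idx)) {
    vapply(first_parent[utr_idx], resolve_gene, character(1), what = "UTR")
  } else character(0)

  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))

  exons <- lapply(seq_along(gene_idx), function(k) {
    gid <- gene_ids[k]
    ke <- exon_idx[exon_gene == gid]
    if (length(ke) == 0L) {
      # genes without explicit exon lines span a single exon
      return(data.frame(start = starts[gene_idx[k]], end = ends[gene_idx[k]]))
    }
    ir <- IRanges::reduce(IRanges::IRanges(starts[ke], ends[ke]))
    data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  })

  out <- data.frame(
    id = gene_ids,
    chromosome = chroms[gene_idx],
    start = starts[gene_idx],
    end = ends[gene_idx],
    strand = strands[gene_idx],
    n_exons = vapply(exons, nrow, integer(1)),
    utr_present = gene_ids %in% utr_gene,
    stringsAsFactors = FALSE
  )
  out$exons <- exons
  out
}

#' Write gene models to a GFF3 file
#'
#' Serializes the gene-model data.frame produced by [read_gff3()] (or by the
#' synthetic-genome generator) back to GFF3, emitting gene, mRNA and exon
#' features with `ID`/`Parent` attributes.
#'
#' @param models Gene-model data.frame (see [read_gff3()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(is.data.frame(models),
            all(c("id", "chromosome", "start", "end", "strand") %in% names(models)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    line <- function(type, s, e, attrs) {
      sprintf("%s\tbhlhtools\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chromosome, type, as.integer(s), as.integer(e), g$strand, attrs)
    }
    writeLines(line("gene", g$start, g$end, paste0("ID=", g$id)), con)
    mrna_id <- paste0(g$id, ".t1")
    writeLines(line("mRNA", g$start, g$end,
                    paste0("ID=", mrna_id, ";Parent=", g$id)), con)
    ex <- if ("exons" %in% names(models)) models$exons[[i]] else
      data.frame(start = g$start, end = g$end)
    for (j in seq_len(nrow(ex))) {
      writeLines(line("exon", ex$start[j], ex$end[j],
                      paste0("ID=", mrna_id, ".exon", j, ";Parent=", mrna_id)), con)
    }
  }
  invisible(path)
}
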