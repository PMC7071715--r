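#' Per-chromosome gene rank index
#'
#' Genes are sorted by start position within each chromosome; the rank is
#' the ordinal position (1-based). Coordinate ties fall back to a stable
#' order by gene id.
#'
#' @param models Gene-model data.frame with columns `id`, `chromosome`,
#'   `start` (e.g. from [read_gff3()]).
#' @return Data.frame `id`, `chromosome`, `start`, `rank`.
#' @export
gene_rank_index <- function(models) {
  stopifnot(all(c("id", "chromosome", "start") %in% names(models)))
  out <- do.call(rbind, lapply(split(models, models$chromosome), function(m) {
    m <- m[order(m$start, m$id), c("id", "chromosome", "start")]
    m$rank <- seq_len(nrow(m))
    m
  }))
  rownames(out) <- NULL
  out
}

# Canonicalize a homolog-pair table: unordered pairs, optional identity
# threshold, self-pairs dropped.
.homolog_pairs <- function(homologs, min_identity = NULL) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(homologs)))
  h <- homologs[homologs$gene_a != homologs$gene_b, , drop = FALSE]
  if (!is.null(min_identity) && "identity_pct" %in% names(h)) {
    h <- h[h$identity_pct >= min_identity, , drop = FALSE]
  }
  a <- pmin(h$gene_a, h$gene_b)
  b <- pmax(h$gene_a, h$gene_b)
  unique(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
}

#' Homolog pairs among proteins by global identity
#'
#' Convenience builder of the homology input for duplication calling: all
#' unordered pairs whose global percent identity reaches `min_identity`
#' (default 40, standing in for an alignment-search e-value cutoff).
#'
#' @param proteins Protein data.frame (`id`, `sequence`).
#' @param min_identity Identity threshold in percent.
#' @return Data.frame `gene_a`, `gene_b`, `identity_pct`.
#' @export
homolog_pairs <- function(proteins, min_identity = 40) {
  n <- nrow(proteins)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pid <- global_identity(proteins$sequence[i], proteins$sequence[j])
      if (pid >= min_identity) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = proteins$id[i], gene_b = proteins$id[j],
          identity_pct = pid, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity_pct = numeric(0)))
  }
  do.call(rbind, out)
}

#' Call tandem duplications among family genes
#'
#' Two family genes are tandem-linked when they lie on the same chromosome
#' within `max_gap_genes` rank positions of each other (default 1, i.e.
#' adjacent) and are homologous. Calls are the connected components of the
#' tandem links, so a cluster of three adjacent homologs is one call.
#'
#' @param family_ids Character vector of family gene ids.
#' @param ranks Rank index from [gene_rank_index()].
#' @param homologs Homolog-pair data.frame (`gene_a`, `gene_b`, optionally
#'   `identity_pct`).
#' @param max_gap_genes Maximum intervening rank distance.
#' @param min_identity Optional identity threshold applied to `homologs`.
#' @return Data.frame `gene_id`, `cluster_id`, `type = "TANDEM"`; zero rows
#'   when no cluster exists.
#' @export
find_tandem <- function(family_ids, ranks, homologs, max_gap_genes = 1L,
                        min_identity = NULL) {
  h <- .homolog_pairs(homologs, min_identity)
  fam <- ranks[ranks$id %in% family_ids, , drop = FALSE]
  pos <- setNames(split(fam[, c("chromosome", "rank")], seq_len(nrow(fam))),
                  fam$id)
  keep <- h$gene_a %in% fam$id & h$gene_b %in% fam$id
  h <- h[keep, , drop = FALSE]
  linked <- vapply(seq_len(nrow(h)), function(k) {
    pa <- pos[[h$gene_a[k]]]
    pb <- pos[[h$gene_b[k]]]
    pa$chromosome == pb$chromosome && abs(pa$rank - pb$rank) <= max_gap_genes
  }, logical(1))
  h <- h[linked, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(gene_id = character(0), cluster_id = integer(0),
                      type = character(0)))
  }
  # connected components by union-find over linked genes
  genes <- unique(c(h$gene_a, h$gene_b))
  comp <- setNames(seq_along(genes), genes)
  find <- function(x) {
    while (comp[[x]] != match(x, genes)) x <- genes[comp[[x]]]
    x
  }
  for (k in seq_len(nrow(h))) {
    ra <- find(h$gene_a[k])
    rb <- find(h$gene_b[k])
    if (ra != rb) comp[[ra]] <- match(rb, genes)
  }
  roots <- vapply(genes, find, character(1))
  cluster <- as.integer(factor(roots, levels = unique(roots)))
  out <- data.frame(gene_id = genes, cluster_id = cluster, type = "TANDEM",
                    stringsAsFactors = FALSE)
  out[order(out$cluster_id, out$gene_id), ]
}

# DP chaining of matches (a_rank ascending, b_rank strictly monotone) with a
# per-step rank gap bound on both regions. Returns chains of match indices.
.chain_matches <- function(am, bm, max_gap, decreasing_b = FALSE) {
  n <- length(am)
  if (n == 0L) return(list())
  ord <- order(am, if (decreasing_b) -bm else bm)
  am <- am[ord]; bm <- bm[ord]
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- am[i] - am[j]
      db <- if (decreasing_b) bm[j] - bm[i] else bm[i] - bm[j]
      if (da > 0L && da <= max_gap && db > 0L && db <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  used <- rep(FALSE, n)
  chains <- list()
  for (i in order(-len)) {
    if (used[i]) next
    chain <- integer(0)
    k <- i
    while (!is.na(k) && !used[k]) {
      chain <- c(k, chain)
      used[k] <- TRUE
      k <- prev[k]
    }
    chains[[length(chains) + 1L]] <- ord[chain]
  }
  chains
}

#' Detect collinear (segmental) duplication blocks
#'
#' Simplified collinearity chaining over homolog pairs: matches between two
#' chromosomes are chained by dynamic programming when their gene ranks
#' advance consistently on both regions (antiparallel chains capture
#' inverted blocks); a chain of at least `min_block` pairs with per-step
#' rank gaps of at most `max_gap` is a collinear block. Family genes inside
#' any block are segmental-duplication calls.
#'
#' @param homologs Homolog pairs across all genes (family plus anchors).
#' @param ranks Rank index from [gene_rank_index()].
#' @param min_block Minimum number of collinear pairs per block (default 5).
#' @param max_gap Maximum rank gap between consecutive pairs (default 25).
#' @param antiparallel Also chain inverted (reversed-order) blocks.
#' @param family_ids Optional family gene ids for segmental calls.
#' @param min_identity Optional identity threshold applied to `homologs`.
#' @return List with `blocks` (data.frame `block_id`, `chr_a`, `chr_b`,
#'   `n_pairs`, `orientation`), `pairs` (`block_id`, `gene_a`, `gene_b`) and
#'   `segmental` (data.frame `gene_id`, `type = "SEGMENTAL"`, `block_id`).
#' @export
find_collinear_blocks <- function(homologs, ranks, min_block = 5L,
                                  max_gap = 25L, antiparallel = TRUE,
                                  family_ids = character(0),
                                  min_identity = NULL) {
  h <- .homolog_pairs(homologs, min_identity)
  idx <- setNames(seq_len(nrow(ranks)), ranks$id)
  known <- h$gene_a %in% names(idx) & h$gene_b %in% names(idx)
  h <- h[known, , drop = FALSE]
  blocks <- list(); pairs <- list(); bid <- 0L
  if (nrow(h) > 0L) {
    ca <- ranks$chromosome[idx[h$gene_a]]
    cb <- ranks$chromosome[idx[h$gene_b]]
    # orient each match so that chrom A <= chrom B
    flip <- ca > cb
    ga <- ifelse(flip, h$gene_b, h$gene_a)
    gb <- ifelse(flip, h$gene_a, h$gene_b)
    chr_a <- ifelse(flip, cb, ca)
    chr_b <- ifelse(flip, ca, cb)
    key <- paste(chr_a, chr_b, sep = "\r")
    for (kp in unique(key)) {
      sel <- which(key == kp)
      am <- ranks$rank[idx[ga[sel]]]
      bm <- ranks$rank[idx[gb[sel]]]
      orientations <- if (antiparallel) c(FALSE, TRUE) else FALSE
      for (dec in orientations) {
        for (chain in .chain_matches(am, bm, max_gap, dec)) {
          if (length(chain) < min_block) next
          bid <- bid + 1L
          blocks[[bid]] <- data.frame(
            block_id = bid, chr_a = chr_a[sel[1L]], chr_b = chr_b[sel[1L]],
            n_pairs = length(chain),
            orientation = if (dec) "antiparallel" else "parallel",
            stringsAsFactors = FALSE)
          pairs[[bid]] <- data.frame(
            block_id = bid, gene_a = ga[sel][chain], gene_b = gb[sel][chain],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = integer(0), chr_a = character(0),
               chr_b = character(0), n_pairs = integer(0),
               orientation = character(0))
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(block_id = integer(0), gene_a = character(0),
               gene_b = character(0))
  in_block <- unique(c(pairs$gene_a, pairs$gene_b))
  seg_genes <- intersect(family_ids, in_block)
  seg <- if (length(seg_genes)) {
    do.call(rbind, lapply(seg_genes, function(g) {
      bids <- unique(pairs$block_id[pairs$gene_a == g | pairs$gene_b == g])
      data.frame(gene_id = g, type = "SEGMENTAL", block_id = bids,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(0), type = character(0),
               block_id = integer(0))
  }
  list(blocks = blocks, pairs = pairs, segmental = seg)
}
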