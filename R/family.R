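#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`; terminal
#' gaps are penalized).
#'
#' @param a,b Protein sequences (strings).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return List with `score`, aligned `pattern` and `subject` strings,
#'   `matches` and `alignment_length`.
#' @export
global_alignment <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(toupper(a)),
    subject = Biostrings::AAString(toupper(b)),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  list(score = Biostrings::score(aln), pattern = pat, subject = sub,
       matches = Biostrings::nmatch(aln), alignment_length = nchar(pat))
}

#' Percent identity of a global alignment
#'
#' Identity is `100 * matches / alignment_length` where the alignment length
#' includes gapped columns (the Clustal-Omega-style denominator); set
#' `denominator = "shorter"` for the shorter-sequence convention.
#'
#' @inheritParams global_alignment
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Percent identity in \[0, 100\].
#' @export
global_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  aln <- global_alignment(a, b, gap_open, gap_extend)
  den <- switch(denominator,
                alignment = aln$alignment_length,
                shorter = min(nchar(a), nchar(b)))
  100 * aln$matches / den
}

#' All-vs-all identity between candidates and references
#'
#' @param candidates,references Protein data.frames (`id`, `sequence`).
#' @inheritParams global_identity
#' @return Numeric matrix (candidates x references) of percent identities.
#' @export
identity_matrix <- function(candidates, references, gap_open = 10,
                            gap_extend = 0.5,
                            denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  pat <- Biostrings::AAStringSet(setNames(candidates$sequence, candidates$id))
  out <- matrix(NA_real_, nrow = nrow(candidates), ncol = nrow(references),
                dimnames = list(candidates$id, references$id))
  for (j in seq_len(nrow(references))) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = pat, subject = Biostrings::AAString(references$sequence[j]),
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend, type = "global"
    )
    den <- switch(denominator,
                  alignment = Biostrings::nchar(aln),
                  shorter = pmin(nchar(candidates$sequence),
                                 nchar(references$sequence[j])))
    out[, j] <- 100 * Biostrings::nmatch(aln) / den
  }
  out
}

#' Name candidates after their best reference ortholog
#'
#' Each candidate is assigned the reference with the highest percent
#' identity (ties broken by reference order in the matrix columns). The
#' family number is taken from the trailing number of the reference id
#' (e.g. reference `AtbHLH47` yields `<base_prefix>47`). When two or more
#' candidates share a best reference they receive decimal suffixes `.1`,
#' `.2`, ... in strictly descending identity, ties broken by candidate id.
#'
#' @param identities Identity matrix from [identity_matrix()].
#' @param base_prefix Prefix for assigned names (default `"CgbHLH"`).
#' @return Data.frame with columns `candidate_id`, `best_reference`,
#'   `identity_pct`, `assigned_name`, in input candidate order.
#' @export
assign_names <- function(identities, base_prefix = "CgbHLH") {
  stopifnot(is.matrix(identities), !is.null(rownames(identities)),
            !is.null(colnames(identities)))
  best_j <- apply(identities, 1L, which.max)
  out <- data.frame(
    candidate_id = rownames(identities),
    best_reference = colnames(identities)[best_j],
    identity_pct = identities[cbind(seq_len(nrow(identities)), best_j)],
    assigned_name = NA_character_,
    stringsAsFactors = FALSE
  )
  num <- sub("^.*?(\\d+(\\.\\d+)?)$", "\\1", out$best_reference)
  no_num <- !grepl("\\d$", out$best_reference)
  num[no_num] <- out$best_reference[no_num]
  base <- paste0(base_prefix, num)
  for (b in unique(base)) {
    idx <- which(base == b)
    if (length(idx) == 1L) {
      out$assigned_name[idx] <- b
    } else {
      ord <- idx[order(-out$identity_pct[idx], out$candidate_id[idx])]
      out$assigned_name[ord] <- paste0(b, ".", seq_along(ord))
    }
  }
  out
}

#' Pairwise p-distance matrix of canonical domains
#'
#' `d(i, j)` is the fraction of mismatches over the canonical positions at
#' which both domains are present. A pair with no shared present position is
#' an error.
#'
#' @param domains Character matrix from [canonical_domains()] (rows =
#'   sequences, `NA` = absent).
#' @return Symmetric numeric matrix with zero diagonal, labeled by rownames.
#' @export
pdistance_matrix <- function(domains) {
  stopifnot(is.matrix(domains), nrow(domains) >= 2L)
  n <- nrow(domains)
  present <- (!is.na(domains)) * 1
  shared <- present %*% t(present)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1L, ]
    stop("no shared present positions between ",
         rownames(domains)[idx[1L]], " and ", rownames(domains)[idx[2L]])
  }
  matches <- matrix(0, n, n)
  for (a in AA_ALPHABET) {
    ia <- (!is.na(domains) & domains == a) * 1
    matches <- matches + ia %*% t(ia)
  }
  d <- 1 - matches / shared
  diag(d) <- 0
  dimnames(d) <- list(rownames(domains), rownames(domains))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (the agglomerative Q-criterion algorithm);
#' negative branch lengths are clamped to zero.
#'
#' @param dm Symmetric distance matrix with labels, or a `dist` object.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the reference NJ tree from the p-distances of the full canonical
#' alignment, then resamples alignment columns with replacement `n_reps`
#' times; each bipartition of the reference tree is annotated with the
#' percentage of replicate trees that contain it (stored in `node.label`).
#'
#' @param domains Character matrix from [canonical_domains()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed fixing the resampling.
#' @return A `phylo` tree with `node.label` holding supports in \[0, 100\]
#'   (the root label is empty).
#' @export
bootstrap_support <- function(domains, n_reps = 1000L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  ref <- nj_tree(pdistance_matrix(domains))
  reps <- local_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(domains), replace = TRUE)
      nj_tree(pdistance_matrix(domains[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps, 1)
  ref$node.label <- as.character(support)
  ref$node.label[1L] <- ""  # root of the unrooted representation
  ref
}

#' Inherit subfamily labels from reference leaves
#'
#' Each candidate leaf receives the label of the smallest clade containing
#' it whose reference leaves carry a single label; a candidate whose nearest
#' labeled clade is mixed is `UNASSIGNED`.
#'
#' @param tree A `phylo` tree whose tips include the reference leaves.
#' @param reference_labels Named character vector: reference tip ->
#'   subfamily label.
#' @return Named character vector of labels for all non-reference tips.
#' @export
assign_subfamilies <- function(tree, reference_labels) {
  tips <- tree$tip.label
  refs <- intersect(tips, names(reference_labels))
  if (length(refs) == 0L) stop("tree contains no reference leaves")
  n <- length(tips)
  n_nodes <- n + tree$Nnode
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  tr <- ape::reorder.phylo(tree, "postorder")
  node_labs <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) node_labs[[i]] <- character(0)
  for (i in seq_len(n)) {
    if (tips[i] %in% refs) node_labs[[i]] <- unname(reference_labels[tips[i]])
  }
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]
    ch <- tr$edge[k, 2L]
    node_labs[[p]] <- c(node_labs[[p]], node_labs[[ch]])
  }
  cands <- setdiff(tips, refs)
  out <- setNames(rep("UNASSIGNED", length(cands)), cands)
  for (cand in cands) {
    node <- parent[match(cand, tips)]
    while (!is.na(node)) {
      labs <- unique(node_labs[[node]])
      if (length(labs) == 1L) {
        out[cand] <- labs
        break
      }
      if (length(labs) > 1L) break  # mixed: every larger clade is mixed too
      node <- parent[node]
    }
  }
  out
}

#' Write a tree to a Newick file
#'
#' Bootstrap supports, when present as `node.label`, are written as internal
#' node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
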