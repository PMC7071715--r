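# DNA-binding category labels form a partition of all domains; the first two
# imply E-box binding and all but the last imply DNA binding.
BINDING_CATEGORIES <- c("G_BOX", "NON_G_BOX", "NON_E_BOX", "NON_DNA_BINDING")

#' Count basic residues in the basic region of a canonical domain
#'
#' Counts residues from `basic_set` (default K, R, H — the standard
#' biochemical definition of basic amino acids) at canonical positions 1-17.
#' Absent positions count as non-basic.
#'
#' @param domain Character vector of length 60 (canonical domain, `NA` =
#'   absent), or a row of the matrix from [canonical_domains()].
#' @param basic_set Residues counted as basic.
#' @return Integer count.
#' @export
count_basic_residues <- function(domain, basic_set = c("K", "R", "H")) {
  basic <- domain[CANONICAL_REGIONS$basic]
  sum(basic %in% basic_set)
}

#' Classify the DNA-binding category of a canonical domain
#'
#' Rules, applied in order:
#' \itemize{
#'   \item `NON_DNA_BINDING` if the basic region holds 5 or fewer basic
#'     residues (including fully absent basic regions);
#'   \item `NON_E_BOX` if not (Glu-13 and Arg-16), the E-box recognition
#'     pair;
#'   \item `G_BOX` if additionally His/Lys-9 and Arg-17, which confer
#'     specificity for the CACGTG G-box;
#'   \item `NON_G_BOX` otherwise (binds other CANNTG E-boxes).
#' }
#'
#' @inheritParams count_basic_residues
#' @return One of `"G_BOX"`, `"NON_G_BOX"`, `"NON_E_BOX"`,
#'   `"NON_DNA_BINDING"`.
#' @export
classify_binding <- function(domain, basic_set = c("K", "R", "H")) {
  if (count_basic_residues(domain, basic_set) <= 5L) {
    return("NON_DNA_BINDING")
  }
  e_box <- identical(unname(domain[13L]), "E") &&
    identical(unname(domain[16L]), "R")
  if (!e_box) return("NON_E_BOX")
  g_box <- !is.na(domain[9L]) && domain[9L] %in% c("H", "K") &&
    identical(unname(domain[17L]), "R")
  if (g_box) "G_BOX" else "NON_G_BOX"
}

#' Classify every domain of a canonical-domain matrix
#'
#' @param domains Character matrix from [canonical_domains()].
#' @inheritParams count_basic_residues
#' @return Named character vector of categories (names = protein ids).
#' @export
classify_domains <- function(domains, basic_set = c("K", "R", "H")) {
  out <- vapply(seq_len(nrow(domains)), function(i) {
    classify_binding(domains[i, ], basic_set)
  }, character(1))
  setNames(out, rownames(domains))
}

#' Count domains per DNA-binding category
#'
#' @param categories Character vector of categories, e.g. from
#'   [classify_domains()].
#' @return Named integer vector over all four categories (zero counts kept).
#' @export
category_counts <- function(categories) {
  bad <- setdiff(unique(categories), BINDING_CATEGORIES)
  if (length(bad) > 0L) stop("unknown category: ", paste(bad, collapse = ", "))
  vapply(BINDING_CATEGORIES, function(k) sum(categories == k), integer(1))
}

#' Per-position consensus conservation profile
#'
#' For each canonical position, residue frequencies are computed over the
#' domains with a present (non-absent) residue at that position; the
#' consensus is the modal residue and the consensus ratio its frequency.
#' Positions absent in every domain report `n_present = 0` and `NA` ratio.
#'
#' @param domains Character matrix from [canonical_domains()].
#' @return Data.frame with columns `position`, `region`, `consensus`,
#'   `ratio`, `n_present`; the 20 x 60 relative-frequency matrix is attached
#'   as attribute `"frequencies"`.
#' @export
consensus_profile <- function(domains) {
  stopifnot(is.matrix(domains), ncol(domains) == CANONICAL_LENGTH,
            nrow(domains) >= 1L)
  freq <- matrix(0, nrow = 20, ncol = CANONICAL_LENGTH,
                 dimnames = list(AA_ALPHABET, NULL))
  consensus <- rep(NA_character_, CANONICAL_LENGTH)
  ratio <- rep(NA_real_, CANONICAL_LENGTH)
  n_present <- integer(CANONICAL_LENGTH)
  for (j in seq_len(CANONICAL_LENGTH)) {
    col <- domains[, j]
    col <- col[!is.na(col)]
    n_present[j] <- length(col)
    if (length(col) == 0L) next
    cnt <- vapply(AA_ALPHABET, function(a) sum(col == a), numeric(1))
    freq[, j] <- cnt / length(col)
    consensus[j] <- AA_ALPHABET[which.max(cnt)]
    ratio[j] <- max(cnt) / length(col)
  }
  out <- data.frame(
    position = seq_len(CANONICAL_LENGTH),
    region = canonical_region(seq_len(CANONICAL_LENGTH)),
    consensus = consensus,
    ratio = ratio,
    n_present = n_present,
    stringsAsFactors = FALSE
  )
  attr(out, "frequencies") <- freq
  out
}

#' Positions conserved above a consensus-ratio threshold
#'
#' @param profile Data.frame from [consensus_profile()].
#' @param threshold Ratio threshold in (0, 1\]; positions with ratio
#'   strictly greater are returned.
#' @return Subset of `profile` rows (`position`, `consensus`, `ratio`,
#'   `region`, `n_present`), sorted by position.
#' @export
conserved_positions <- function(profile, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- !is.na(profile$ratio) & profile$ratio > threshold
  out <- profile[keep, , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

#' Write the per-gene category table as TSV
#'
#' @param categories Named category vector from [classify_domains()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_category_tsv <- function(categories, path) {
  write.table(data.frame(gene_id = names(categories),
                         binding_category = unname(categories)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-position consensus table as TSV
#'
#' @param profile Data.frame from [consensus_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_consensus_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
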