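# Independent oracles used across the suite. These deliberately re-derive
# results with different algorithms / conventions than the implementation.

# Affine-gap global alignment score by an independent Gotoh recursion over
# all alignments. Gap of length L costs gap_open + L * gap_extend; terminal
# gaps are penalized (global alignment). Substitution scores from BLOSUM62.
nw_affine_oracle_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  blosum <- get_blosum62()
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in a match/mismatch
  E <- matrix(NEG, n + 1L, m + 1L)  # ends in a gap in `a` (consumes y)
  F_ <- matrix(NEG, n + 1L, m + 1L) # ends in a gap in `b` (consumes x)
  M[1L, 1L] <- 0
  for (j in seq_len(m)) {
    E[1L, j + 1L] <- -(gap_open + gap_extend * j)
  }
  for (i in seq_len(n)) {
    F_[i + 1L, 1L] <- -(gap_open + gap_extend * i)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- blosum[x[i], y[j]]
      M[i + 1L, j + 1L] <- max(M[i, j], E[i, j], F_[i, j]) + s
      E[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                               E[i + 1L, j] - gap_extend,
                               F_[i + 1L, j] - gap_open - gap_extend)
      F_[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                                F_[i, j + 1L] - gap_extend,
                                E[i, j + 1L] - gap_open - gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], E[n + 1L, m + 1L], F_[n + 1L, m + 1L])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Isoelectric point by 0.001-step grid search on an independently written
# Henderson-Hasselbalch net-charge function (same pKa table as the package).
grid_pi_oracle <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  pka <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
           H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
  charge <- function(ph) {
    pos <- sum(vapply(c("K", "R", "H"), function(aa) {
      sum(res == aa) / (1 + 10^(ph - pka[[aa]]))
    }, numeric(1))) + 1 / (1 + 10^(ph - pka[["Nterm"]]))
    neg <- sum(vapply(c("D", "E", "C", "Y"), function(aa) {
      sum(res == aa) / (1 + 10^(pka[[aa]] - ph))
    }, numeric(1))) + 1 / (1 + 10^(pka[["Cterm"]] - ph))
    pos - neg
  }
  grid <- seq(0, 14, by = 0.001)
  grid[which.min(abs(vapply(grid, charge, numeric(1))))]
}

# Connected components of a homology graph restricted to one chromosome:
# brute-force reference for find_tandem with an unbounded gap.
components_oracle <- function(genes, pairs) {
  comp <- setNames(seq_along(genes), genes)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
      if (!(a %in% genes) || !(b %in% genes)) next
      if (comp[[a]] != comp[[b]]) {
        comp[comp == comp[[a]]] <- comp[[b]]
        changed <- TRUE
      }
    }
  }
  split(genes, comp[genes])
}

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

sim_consensus_string <- function() {
  paste(attr(bhlh_conservation_profile(), "consensus"), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# A small scaled-down simulated study used by the pipeline tests.
scaled_config <- function(seed = 11L, ...) {
  bhlh_sim_config(
    seed = seed,
    n_family = 40L,
    category_mix = c(G_BOX = 18L, NON_G_BOX = 12L, NON_E_BOX = 4L,
                     NON_DNA_BINDING = 6L),
    n_decoys = 30L,
    n_references = 60L,
    chrom_family = c(chr1 = 6L, chr2 = 8L, chr3 = 5L, chr4 = 2L, chr5 = 6L,
                     chr6 = 4L, chr7 = 3L, chr8 = 4L, chr9 = 2L),
    n_filler_per_chrom = 15L,
    expression = list(
      n_expressed = 30L, n_go = 25L, n_overlap = 20L, n_above_cut = 10L,
      tpm_range = c(0.05, 281.08), tpm_cut = 3,
      samples = c("root_run1", "root_run2"),
      go_term = c(term_id = "GO:0009628",
                  term_name = "response to abiotic stimulus")
    ),
    qpcr = list(
      noise_sd = 0.2, n_replicates = 3L, baseline_ct = 24, reference_ct = 18,
      pattern_counts = c(EARLY_UP = 4L, MID_UP = 2L, LATE_UP = 2L),
      pattern_folds = list(
        EARLY_UP = c(4, 3, 2.5, 2, 2),
        MID_UP = c(0.6, 2.5, 3, 1.8, 0.7),
        LATE_UP = c(0.8, 0.9, 0.7, 2.5, 3)
      )
    ),
    ...
  )
}

# Character matrix of planted truth domains from a proteome manifest.
truth_domain_matrix <- function(proteome) {
  td <- proteome$truth$domains
  m <- do.call(rbind, strsplit(td$domain, ""))
  rownames(m) <- td$protein_id
  m
}
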