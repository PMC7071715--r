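# Canonical 60-position consensus used by the domain simulator. The 19
# conserved positions (consensus probability 0.75, or 0.92 at the two
# extremely conserved leucines) are E13, R14, R16, R17 in the basic region;
# K19, R23, L27, L30, V31, P32 in helix 1; K39, D41 in the loop; and A43,
# L46, A49, I50, Y52, K54, L56 in helix 2. All remaining positions are
# weakly conserved (probability 0.28) with a non-basic consensus inside the
# basic region so that planted binding categories stay controllable.
SIM_CONSENSUS <- c(
  "A", "N", "E", "S", "T", "S", "Q", "A", "N", "S", "E", "S", "E", "R", "N",
  "R", "R", "D", "K", "I", "N", "E", "R", "F", "Q", "E", "L", "G", "S", "L",
  "V", "P", "N", "G", "S", "K", "N", "D", "K", "A", "D", "I", "A", "S", "M",
  "L", "D", "E", "A", "I", "Q", "Y", "M", "K", "S", "L", "Q", "Q", "Q", "V"
)
SIM_CONSERVED_POSITIONS <- c(13, 14, 16, 17, 19, 23, 27, 30, 31, 32,
                             39, 41, 43, 46, 49, 50, 52, 54, 56)
SIM_EXTREME_POSITIONS <- c(27, 56)

#' Per-position residue probability profile of the simulated bHLH domain
#'
#' @param p_conserved Consensus probability at conserved positions.
#' @param p_extreme Consensus probability at the extremely conserved
#'   positions (27, 56).
#' @param p_background Consensus probability elsewhere.
#' @return A 20 x 60 column-stochastic matrix (rows = residues); the
#'   consensus string and conserved positions are attached as attributes.
#' @export
bhlh_conservation_profile <- function(p_conserved = 0.75, p_extreme = 0.92,
                                      p_background = 0.28) {
  prof <- matrix(0, nrow = 20, ncol = CANONICAL_LENGTH,
                 dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(CANONICAL_LENGTH)) {
    p <- if (j %in% SIM_EXTREME_POSITIONS) p_extreme
    else if (j %in% SIM_CONSERVED_POSITIONS) p_conserved
    else p_background
    prof[, j] <- (1 - p) / 19
    prof[SIM_CONSENSUS[j], j] <- p
  }
  attr(prof, "consensus") <- SIM_CONSENSUS
  attr(prof, "conserved_positions") <- SIM_CONSERVED_POSITIONS
  prof
}

#' Default configuration of the synthetic bHLH study
#'
#' The defaults re-enact the shape of a real genome-wide bHLH survey: 128
#' family members with binding-category mix 58/40/6/24 (G-box, non-G-box,
#' non-E-box, non-DNA-binding), a chromosome layout with planted tandem
#' clusters of sizes 2 and 3 and two 6-pair collinear blocks (one
#' inverted), an expression table with 95 expressed genes, an 86-gene GO
#' set overlapping in 66 genes of which 39 exceed the TPM cut of 3.00
#' (TPM drawn log-uniformly on 0.05-281.08), and qPCR time courses over
#' 0.5/1.5/2/7/12 days with Ct noise sd 0.2 and three replicates.
#'
#' @param seed Integer master seed.
#' @param ... Named overrides of any default element.
#' @return A configuration list for [simulate_bhlh_study()].
#' @export
bhlh_sim_config <- function(seed = 101L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_family = 128L,
    category_mix = c(G_BOX = 58L, NON_G_BOX = 40L, NON_E_BOX = 6L,
                     NON_DNA_BINDING = 24L),
    n_decoys = 128L,
    n_references = 136L,
    n_subfamilies = 18L,
    flank_range = c(30L, 100L),
    profile = bhlh_conservation_profile(),
    chrom_family = c(chr1 = 14L, chr2 = 22L, chr3 = 12L, chr4 = 4L,
                     chr5 = 25L, chr6 = 6L, chr7 = 12L, chr8 = 18L,
                     chr9 = 12L, chrUn = 3L),
    n_filler_per_chrom = 40L,
    tandem_cluster_sizes = c(2L, 3L),
    block_n_pairs = 6L,
    expression = list(
      n_expressed = 95L, n_go = 86L, n_overlap = 66L, n_above_cut = 39L,
      tpm_range = c(0.05, 281.08), tpm_cut = 3,
      samples = c("root_run1", "root_run2"),
      go_term = c(term_id = "GO:0009628",
                  term_name = "response to abiotic stimulus")
    ),
    qpcr = list(
      noise_sd = 0.2, n_replicates = 3L, baseline_ct = 24, reference_ct = 18,
      pattern_counts = c(EARLY_UP = 21L, MID_UP = 9L, LATE_UP = 4L),
      pattern_folds = list(
        EARLY_UP = c(4, 3, 2.5, 2, 2),
        MID_UP = c(0.6, 2.5, 3, 1.8, 0.7),
        LATE_UP = c(0.8, 0.9, 0.7, 2.5, 3)
      )
    )
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(sum(cfg$category_mix) == cfg$n_family)
  cfg
}

# ids used throughout the simulated study
.sim_family_ids <- function(cfg) sprintf("CgSIM%03d", seq_len(cfg$n_family))
.sim_decoy_ids <- function(cfg) sprintf("DECOY%03d", seq_len(cfg$n_decoys))
.sim_ref_ids <- function(cfg) sprintf("AtSIM%d", seq_len(cfg$n_references))

.sample_domain <- function(profile) {
  vapply(seq_len(ncol(profile)), function(j) {
    sample(AA_ALPHABET, 1L, prob = profile[, j])
  }, character(1))
}

# Force the diagnostic residues of a sampled domain so that it classifies
# into the requested binding category by construction.
.force_category <- function(d, category, basic_set = c("K", "R", "H")) {
  if (category == "NON_DNA_BINDING") {
    basic_pos <- CANONICAL_REGIONS$basic
    is_basic <- d[basic_pos] %in% basic_set
    d[basic_pos[is_basic]] <- "A"
    return(d)
  }
  d[16] <- "R"
  d[17] <- "R"
  if (category == "NON_E_BOX") {
    d[13] <- "A"
  } else {
    d[13] <- "E"
    if (category == "G_BOX") {
      d[9] <- sample(c("H", "K"), 1L)
    } else {
      d[9] <- "A"
    }
  }
  # top up the basic-region count to at least 6 basic residues, using
  # positions that are neither diagnostic nor conserved
  candidates <- setdiff(CANONICAL_REGIONS$basic, c(9, 13, 14, 16, 17))
  need <- 6L - count_basic_residues(d, basic_set)
  if (need > 0L) {
    open <- candidates[!(d[candidates] %in% basic_set)]
    pick <- sample(open, need)
    d[pick] <- sample(c("K", "R"), need, replace = TRUE)
  }
  d
}

# Deterministic subfamily sequence signatures: six positions drawn from the
# weakly conserved helix/loop positions, imprinted with a fixed residue per
# subfamily so that subfamily members cluster in the phylogeny.
.subfamily_signatures <- function(n_subfamilies) {
  pool <- setdiff(18:60, SIM_CONSERVED_POSITIONS)
  residues <- c("W", "F", "M", "C", "G", "T", "S", "N", "Q", "D",
                "E", "V", "I", "L", "A", "P", "Y", "W", "F", "M")
  lapply(seq_len(n_subfamilies), function(s) {
    pos <- pool[(((s - 1L) * 7L + (0:5) * 3L) %% length(pool)) + 1L]
    list(positions = pos, residue = residues[((s - 1L) %% 20L) + 1L])
  })
}

#' Generate a synthetic proteome with planted bHLH domains
#'
#' Family proteins are random flanks around a 60-residue domain sampled
#' from the conservation profile, with the diagnostic residues (position 9,
#' 13, 16, 17 and the basic-region content) forced to match the assigned
#' binding category and a subfamily sequence signature imprinted. Decoys
#' are per-protein shuffles of the family proteins (same composition, no
#' domain). Reference proteins (used for naming, phylogeny and as the
#' profile seed alignment) are G-box-style domains carrying their
#' subfamily signature.
#'
#' @param config Configuration from [bhlh_sim_config()].
#' @return List with `proteins` (family + decoys), `references`,
#'   `seed_alignment` (a [seed_alignment()] of the reference domains) and
#'   `truth` (planted domain table, decoy ids, reference subfamily labels).
#' @export
generate_proteome <- function(config = bhlh_sim_config()) {
  cfg <- config
  local_seed(cfg$seed, {
    fam_ids <- .sim_family_ids(cfg)
    categories <- rep(names(cfg$category_mix), cfg$category_mix)
    subfam <- rep_len(seq_len(cfg$n_subfamilies), cfg$n_family)
    sigs <- .subfamily_signatures(cfg$n_subfamilies)

    make_protein <- function(domain) {
      n1 <- sample(cfg$flank_range[1]:cfg$flank_range[2], 1L)
      n2 <- sample(cfg$flank_range[1]:cfg$flank_range[2], 1L)
      flank1 <- paste(sample(AA_ALPHABET, n1, replace = TRUE), collapse = "")
      flank2 <- paste(sample(AA_ALPHABET, n2, replace = TRUE), collapse = "")
      list(seq = paste0(flank1, paste(domain, collapse = ""), flank2),
           start = n1 + 1L)
    }

    fam <- lapply(seq_len(cfg$n_family), function(i) {
      d <- .sample_domain(cfg$profile)
      sig <- sigs[[subfam[i]]]
      d[sig$positions] <- sig$residue
      d <- .force_category(d, categories[i])
      c(make_protein(d), list(domain = d))
    })
    proteins <- data.frame(
      id = fam_ids,
      sequence = vapply(fam, `[[`, character(1), "seq"),
      description = paste0("simulated bHLH family member (",
                           categories, ")"),
      stringsAsFactors = FALSE
    )
    truth_domains <- data.frame(
      protein_id = fam_ids,
      category = categories,
      domain_start = vapply(fam, `[[`, integer(1), "start"),
      domain = vapply(fam, function(x) paste(x$domain, collapse = ""),
                      character(1)),
      subfamily = as.character(subfam),
      stringsAsFactors = FALSE
    )

    decoy_ids <- .sim_decoy_ids(cfg)
    decoys <- data.frame(
      id = decoy_ids,
      sequence = vapply(seq_len(cfg$n_decoys), function(i) {
        src <- proteins$sequence[((i - 1L) %% cfg$n_family) + 1L]
        paste(sample(strsplit(src, "")[[1L]]), collapse = "")
      }, character(1)),
      description = "shuffled decoy",
      stringsAsFactors = FALSE
    )

    ref_ids <- .sim_ref_ids(cfg)
    ref_subfam <- rep_len(seq_len(cfg$n_subfamilies), cfg$n_references)
    refs <- lapply(seq_len(cfg$n_references), function(i) {
      d <- .sample_domain(cfg$profile)
      sig <- sigs[[ref_subfam[i]]]
      d[sig$positions] <- sig$residue
      d <- .force_category(d, "G_BOX")
      c(make_protein(d), list(domain = d))
    })
    references <- data.frame(
      id = ref_ids,
      sequence = vapply(refs, `[[`, character(1), "seq"),
      description = paste0("simulated reference bHLH, subfamily ",
                           ref_subfam),
      stringsAsFactors = FALSE
    )
    seed <- seed_alignment(
      ref_ids,
      vapply(refs, function(x) paste(x$domain, collapse = ""), character(1))
    )

    list(
      proteins = rbind(proteins, decoys),
      references = references,
      reference_domains = {
        rd <- do.call(rbind, lapply(refs, function(x) x$domain))
        rownames(rd) <- ref_ids
        rd
      },
      seed_alignment = seed,
      truth = list(
        domains = truth_domains,
        decoy_ids = decoy_ids,
        reference_labels = setNames(as.character(ref_subfam), ref_ids),
        category_mix = cfg$category_mix,
        conserved_positions = SIM_CONSERVED_POSITIONS
      )
    )
  })
}

#' Generate a synthetic genome layout with planted duplications
#'
#' Places the family genes on simulated chromosomes among filler genes,
#' making tandem clusters adjacent on one chromosome and planting two
#' collinear blocks (`block_n_pairs` homolog pairs each): one parallel
#' block between chr1 and chr2 containing two family-gene pairs, and one
#' inverted block between chr3 and chr6 containing one family-gene pair.
#' Planted homolog pairs are emitted with 85 percent identity.
#'
#' @param config Configuration from [bhlh_sim_config()].
#' @return List with `models` (gene-model data.frame), `homologs`
#'   (planted homolog pairs) and `truth` (tandem clusters and genes,
#'   blocks, segmental genes).
#' @export
generate_genome_layout <- function(config = bhlh_sim_config()) {
  cfg <- config
  local_seed(cfg$seed + 1L, {
    fam_ids <- .sim_family_ids(cfg)
    chroms <- names(cfg$chrom_family)
    fam_by_chrom <- split(fam_ids, rep(chroms, cfg$chrom_family))
    fill_count <- 0L
    new_fillers <- function(n) {
      ids <- sprintf("FILL%04d", fill_count + seq_len(n))
      fill_count <<- fill_count + n
      ids
    }
    # per chromosome the layout is built from "atoms": single genes plus
    # indivisible runs (tandem clusters, block anchor runs); shuffling the
    # atoms keeps every planted run contiguous
    atoms <- setNames(vector("list", length(chroms)), chroms)
    add_run <- function(ch, ids) {
      atoms[[ch]] <<- c(atoms[[ch]], list(ids))
    }

    # tandem clusters: adjacent family homologs on chr8 (size 2) and chr2
    # (size 3) by default; cluster k takes genes from the chromosome's tail
    tandem_chrom <- c("chr8", "chr2")
    tandem <- list()
    used <- character(0)
    for (k in seq_along(cfg$tandem_cluster_sizes)) {
      sz <- cfg$tandem_cluster_sizes[k]
      ch <- tandem_chrom[((k - 1L) %% length(tandem_chrom)) + 1L]
      pool <- setdiff(fam_by_chrom[[ch]], used)
      ids <- tail(pool, sz)
      used <- c(used, ids)
      add_run(ch, ids)
      tandem[[k]] <- list(chromosome = ch, genes = ids)
    }

    # collinear blocks: consecutive anchor runs on two chromosomes
    n_pairs <- cfg$block_n_pairs
    make_block <- function(ch_a, ch_b, fam_a, fam_b, inverted) {
      n_fam <- length(fam_a)
      fa <- new_fillers(n_pairs - n_fam)
      fb <- new_fillers(n_pairs - n_fam)
      fam_slots <- sort(sample(seq_len(n_pairs), n_fam))
      a_run <- character(n_pairs); b_run <- character(n_pairs)
      a_run[fam_slots] <- fam_a; a_run[-fam_slots] <- fa
      b_run[fam_slots] <- fam_b; b_run[-fam_slots] <- fb
      add_run(ch_a, a_run)
      add_run(ch_b, if (inverted) rev(b_run) else b_run)
      list(chr_a = ch_a, chr_b = ch_b,
           orientation = if (inverted) "antiparallel" else "parallel",
           pairs = data.frame(gene_a = a_run, gene_b = b_run,
                              stringsAsFactors = FALSE))
    }
    pool1 <- setdiff(fam_by_chrom$chr1, used)
    pool2 <- setdiff(fam_by_chrom$chr2, used)
    block1 <- make_block("chr1", "chr2", head(pool1, 2L), head(pool2, 2L),
                         inverted = FALSE)
    used <- c(used, head(pool1, 2L), head(pool2, 2L))
    pool3 <- setdiff(fam_by_chrom$chr3, used)
    pool6 <- setdiff(fam_by_chrom$chr6, used)
    block2 <- make_block("chr3", "chr6", head(pool3, 1L), head(pool6, 1L),
                         inverted = TRUE)
    used <- c(used, head(pool3, 1L), head(pool6, 1L))
    blocks <- list(block1, block2)

    # remaining genes are singleton atoms; shuffle atoms and flatten
    layout <- list()
    for (ch in chroms) {
      singles <- c(setdiff(fam_by_chrom[[ch]], used),
                   new_fillers(cfg$n_filler_per_chrom))
      at <- c(as.list(singles), atoms[[ch]])
      layout[[ch]] <- unlist(at[sample(length(at))], use.names = FALSE)
    }

    # coordinates: gene k on a chromosome spans [k*1e4, k*1e4 + 2999]
    models <- do.call(rbind, lapply(chroms, function(ch) {
      ids <- layout[[ch]]
      k <- seq_along(ids)
      start <- k * 10000L
      data.frame(id = ids, chromosome = ch, start = start,
                 end = start + 2999L,
                 strand = rep_len(c("+", "-"), length(ids)),
                 stringsAsFactors = FALSE)
    }))
    models$exons <- lapply(seq_len(nrow(models)), function(i) {
      s <- models$start[i]
      data.frame(start = c(s, s + 1500L), end = c(s + 1199L, s + 2999L))
    })
    models$n_exons <- 2L
    models$utr_present <- FALSE

    homolog_rows <- list()
    add_pair <- function(a, b) {
      homolog_rows[[length(homolog_rows) + 1L]] <<-
        data.frame(gene_a = a, gene_b = b, identity_pct = 85,
                   stringsAsFactors = FALSE)
    }
    for (tc in tandem) {
      ids <- tc$genes
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq.int(i + 1L, length(ids))) add_pair(ids[i], ids[j])
      }
    }
    for (bl in blocks) {
      for (i in seq_len(nrow(bl$pairs))) {
        add_pair(bl$pairs$gene_a[i], bl$pairs$gene_b[i])
      }
    }
    homologs <- do.call(rbind, homolog_rows)

    seg_genes <- intersect(
      fam_ids, unlist(lapply(blocks, function(b) unlist(b$pairs)))
    )
    list(
      models = models,
      homologs = homologs,
      truth = list(
        tandem_clusters = tandem,
        tandem_genes = sort(unlist(lapply(tandem, `[[`, "genes"))),
        blocks = blocks,
        segmental_genes = sort(seg_genes)
      )
    )
  })
}

#' Generate a synthetic TPM expression table with planted cascade counts
#'
#' Expressed genes draw TPM log-uniformly from `tpm_range`; non-expressed
#' genes are 0. The GO set and its overlap with the expressed set are
#' enforced exactly, as is the number of overlap genes whose TPM exceeds
#' the cut. The two samples bracket the planted TPM symmetrically so the
#' per-gene mean equals the planted value exactly.
#'
#' @param config Configuration from [bhlh_sim_config()].
#' @return List with `tpm` (matrix), `go` (annotation data.frame) and
#'   `truth` (expressed / GO / overlap / shortlist gene sets).
#' @export
generate_expression <- function(config = bhlh_sim_config()) {
  cfg <- config
  ex <- cfg$expression
  stopifnot(ex$n_overlap <= min(ex$n_expressed, ex$n_go),
            ex$n_above_cut <= ex$n_overlap,
            ex$n_go - ex$n_overlap <= cfg$n_family - ex$n_expressed)
  local_seed(cfg$seed + 2L, {
    ids <- .sim_family_ids(cfg)
    expressed <- sort(sample(ids, ex$n_expressed))
    not_expressed <- setdiff(ids, expressed)
    overlap <- sort(sample(expressed, ex$n_overlap))
    go_extra <- sample(not_expressed, ex$n_go - ex$n_overlap)
    go_set <- sort(c(overlap, go_extra))
    shortlist <- sort(sample(overlap, ex$n_above_cut))

    log_unif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
    lo <- ex$tpm_range[1]; hi <- ex$tpm_range[2]; cut <- ex$tpm_cut
    tpm <- setNames(rep(0, length(ids)), ids)
    tpm[shortlist] <- log_unif(length(shortlist), cut * 1.01, hi)
    below <- setdiff(overlap, shortlist)
    tpm[below] <- log_unif(length(below), lo, cut * 0.99)
    rest <- setdiff(expressed, overlap)
    tpm[rest] <- log_unif(length(rest), lo, hi)

    # two samples bracketing the planted value: mean is exact
    m <- cbind(tpm * 1.03, tpm * 0.97)
    colnames(m) <- ex$samples[1:2]

    go <- rbind(
      data.frame(gene_id = go_set, term_id = ex$go_term[["term_id"]],
                 term_name = ex$go_term[["term_name"]],
                 stringsAsFactors = FALSE),
      data.frame(gene_id = ids, term_id = "GO:0005634",
                 term_name = "nucleus", stringsAsFactors = FALSE)
    )
    list(
      tpm = m,
      go = go,
      truth = list(expressed = expressed, go_set = go_set,
                   overlap = overlap, shortlist = shortlist)
    )
  })
}

#' Generate a synthetic qPCR Ct table with planted fold trajectories
#'
#' Each panel gene gets a planted fold-change trajectory over the five
#' timepoints (default panel: 21 early-up, 9 mid-up, 4 late-up genes).
#' Control target Ct is the baseline plus Gaussian noise; treatment target
#' Ct is the baseline minus log2(fold) plus noise; reference Ct is constant
#' plus noise — all with sd `noise_sd` per well.
#'
#' @param config Configuration from [bhlh_sim_config()].
#' @param trajectories Optional data.frame (`gene_id` plus one column per
#'   timepoint) overriding the default panel.
#' @return List with `ct` (long Ct table) and `truth` (trajectories and
#'   planted pattern types).
#' @export
generate_qpcr <- function(config = bhlh_sim_config(), trajectories = NULL) {
  cfg <- config
  q <- cfg$qpcr
  local_seed(cfg$seed + 3L, {
    if (is.null(trajectories)) {
      pats <- rep(names(q$pattern_counts), q$pattern_counts)
      ids <- .sim_family_ids(cfg)[seq_along(pats)]
      trajectories <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
      folds <- t(vapply(pats, function(p) q$pattern_folds[[p]],
                        numeric(length(QPCR_TIMEPOINTS))))
      colnames(folds) <- as.character(QPCR_TIMEPOINTS)
      trajectories <- cbind(trajectories, as.data.frame(folds))
      rownames(trajectories) <- NULL
      planted_pattern <- setNames(pats, ids)
    } else {
      planted_pattern <- vapply(seq_len(nrow(trajectories)), function(i) {
        f <- unlist(trajectories[i, as.character(QPCR_TIMEPOINTS)])
        classify_pattern(setNames(f, as.character(QPCR_TIMEPOINTS)))
      }, character(1))
      names(planted_pattern) <- trajectories$gene_id
    }
    if (any(as.matrix(trajectories[, as.character(QPCR_TIMEPOINTS)]) <= 0)) {
      stop("planted fold changes must be positive")
    }
    rows <- list()
    for (i in seq_len(nrow(trajectories))) {
      g <- trajectories$gene_id[i]
      for (tp in QPCR_TIMEPOINTS) {
        fold <- trajectories[i, as.character(tp)]
        for (cond in c("CK", "FE_DEFICIENT")) {
          mu <- q$baseline_ct - if (cond == "CK") 0 else log2(fold)
          for (r in seq_len(q$n_replicates)) {
            rows[[length(rows) + 1L]] <- data.frame(
              gene_id = g, condition = cond, timepoint = tp, replicate = r,
              ct_target = mu + rnorm(1L, 0, q$noise_sd),
              ct_reference = q$reference_ct + rnorm(1L, 0, q$noise_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(
      ct = do.call(rbind, rows),
      truth = list(trajectories = trajectories,
                   pattern = planted_pattern,
                   noise_sd = q$noise_sd,
                   n_replicates = q$n_replicates)
    )
  })
}

#' Simulate a complete synthetic bHLH study
#'
#' Runs all four generators under one master seed and bundles their truth
#' manifests; this is the input of [run_full()].
#'
#' @param config Configuration from [bhlh_sim_config()].
#' @return List with `proteome`, `layout`, `expression`, `qpcr`, `config`.
#' @export
simulate_bhlh_study <- function(config = bhlh_sim_config()) {
  list(
    proteome = generate_proteome(config),
    layout = generate_genome_layout(config),
    expression = generate_expression(config),
    qpcr = generate_qpcr(config),
    config = config
  )
}
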