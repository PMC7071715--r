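QPCR_TIMEPOINTS <- c(0.5, 1.5, 2, 7, 12)  # days of treatment

#' Read a gene x sample TPM matrix from TSV
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @return Numeric matrix with gene rownames.
#' @export
read_tpm <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("gene_id" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m < 0)) stop("negative TPM values")
  m
}

#' Read a GO annotation table from TSV
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`.
#' @return Data.frame of the three columns.
#' @export
read_go <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "term_id", "term_name") %in% names(df)))
  df
}

#' Genes annotated to a GO term
#'
#' @param go GO table from [read_go()].
#' @param term A `term_id` or `term_name` value.
#' @return Character vector of gene ids.
#' @export
go_gene_set <- function(go, term) {
  unique(go$gene_id[go$term_id == term | go$term_name == term])
}

#' Read a qPCR Ct table from TSV
#'
#' @param path TSV with columns `gene_id`, `condition`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @return Data.frame of those columns.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "timepoint", "replicate",
            "ct_target", "ct_reference")
  stopifnot(all(need %in% names(df)))
  if (any(df$ct_target <= 0 | df$ct_target >= 45) ||
      any(df$ct_reference <= 0 | df$ct_reference >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  df
}

#' Genes expressed across a set of samples
#'
#' A gene counts as expressed when its mean TPM over the chosen samples is
#' strictly greater than `min_tpm` (default 0, i.e. any nonzero signal).
#'
#' @param table TPM matrix (genes x samples).
#' @param samples Sample (column) names to average over.
#' @param min_tpm Expression floor.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(table, samples = colnames(table), min_tpm = 0) {
  missing <- setdiff(samples, colnames(table))
  if (length(missing) > 0L) {
    stop("unknown sample name(s): ", paste(missing, collapse = ", "))
  }
  m <- rowMeans(table[, samples, drop = FALSE])
  rownames(table)[m > min_tpm]
}

#' Candidate cascade: expression filter, GO intersection, TPM cut
#'
#' `overlap` is the intersection of the expressed genes with a GO-defined
#' gene set; the `shortlist` keeps the overlap members whose mean TPM is
#' strictly greater than `tpm_cut` (default 3.00).
#'
#' @param expressed Character vector of expressed gene ids.
#' @param go_set Character vector of GO-set gene ids.
#' @param table TPM matrix.
#' @param samples Samples used for the TPM cut.
#' @param tpm_cut Strict lower TPM bound for the shortlist.
#' @return List with `overlap`, `shortlist` and `counts` (named vector:
#'   `expressed`, `go_set`, `overlap`, `shortlist`).
#' @export
cascade <- function(expressed, go_set, table, samples = colnames(table),
                    tpm_cut = 3) {
  overlap <- intersect(expressed, go_set)
  m <- rowMeans(table[, samples, drop = FALSE])
  shortlist <- overlap[m[overlap] > tpm_cut]
  list(
    overlap = overlap,
    shortlist = shortlist,
    counts = c(expressed = length(expressed), go_set = length(go_set),
               overlap = length(overlap), shortlist = length(shortlist))
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference`; `ddCt` is the mean dCt
#' of the treatment minus the mean dCt of the control, and the fold change
#' is `2^-ddCt`.
#'
#' @param measurements Data.frame for one gene and timepoint with columns
#'   `condition` (`"FE_DEFICIENT"` / `"CK"`), `ct_target`, `ct_reference`.
#' @param treatment,control Condition labels.
#' @return Fold change (positive number).
#' @export
ddct <- function(measurements, treatment = "FE_DEFICIENT", control = "CK") {
  dct <- measurements$ct_target - measurements$ct_reference
  trt <- dct[measurements$condition == treatment]
  ctl <- dct[measurements$condition == control]
  if (length(trt) == 0L || length(ctl) == 0L) {
    stop("missing condition: need both ", treatment, " and ", control)
  }
  2^-(mean(trt) - mean(ctl))
}

#' Per-timepoint significance test between treatment and control
#'
#' Two-sided Student's t-test (equal variance by default) on per-replicate
#' relative-expression values `2^-(dCt - mean dCt(control))`; with
#' `test_on = "ct"` the test is run on the dCt values directly. Identical
#' zero-variance groups yield p = 1.
#'
#' @inheritParams ddct
#' @param alpha Significance level (default 0.05).
#' @param test_on `"rel"` (relative expression, default) or `"ct"` (dCt).
#' @param var_equal Pool variances (Student's t) or not (Welch).
#' @return List with `p_value` and `significant`.
#' @export
timepoint_test <- function(measurements, alpha = 0.05,
                           treatment = "FE_DEFICIENT", control = "CK",
                           test_on = c("rel", "ct"), var_equal = TRUE) {
  test_on <- match.arg(test_on)
  dct <- measurements$ct_target - measurements$ct_reference
  trt <- dct[measurements$condition == treatment]
  ctl <- dct[measurements$condition == control]
  if (length(trt) < 2L || length(ctl) < 2L) {
    stop("need at least 2 replicates per condition")
  }
  if (test_on == "rel") {
    base <- mean(ctl)
    x <- 2^-(trt - base)
    y <- 2^-(ctl - base)
  } else {
    x <- trt
    y <- ctl
  }
  if (sd(x) == 0 && sd(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  } else {
    p <- t.test(x, y, var.equal = var_equal)$p.value
  }
  list(p_value = p, significant = p < alpha)
}

#' Classify the expression pattern of a fold-change time course
#'
#' Operational rules over the five timepoints (0.5, 1.5, 2, 7, 12 days),
#' with "up-regulated" meaning fold change above `margin` (default 1):
#' \itemize{
#'   \item `EARLY_UP`: up at 0.5 d;
#'   \item `MID_UP`: not up at 0.5 d or 12 d, up at one or more of 1.5, 2
#'     or 7 d;
#'   \item `LATE_UP`: not up at 0.5, 1.5 or 2 d, up at 7 d or 12 d;
#'   \item `OTHER`: anything else.
#' }
#'
#' @param folds Numeric vector of fold changes named by timepoint
#'   (`"0.5"`, `"1.5"`, `"2"`, `"7"`, `"12"`).
#' @param margin Fold threshold for "up" (strictly greater).
#' @return One of `"EARLY_UP"`, `"MID_UP"`, `"LATE_UP"`, `"OTHER"`.
#' @export
classify_pattern <- function(folds, margin = 1) {
  want <- as.character(QPCR_TIMEPOINTS)
  if (!all(want %in% names(folds))) {
    stop("missing timepoint(s): ",
         paste(setdiff(want, names(folds)), collapse = ", "))
  }
  f <- folds[want]
  up <- f > margin
  if (up[["0.5"]]) return("EARLY_UP")
  if (any(up[c("1.5", "2", "7")]) && !up[["12"]]) return("MID_UP")
  if (!any(up[c("1.5", "2")]) && (up[["7"]] || up[["12"]])) return("LATE_UP")
  "OTHER"
}

#' Full qPCR time-course analysis
#'
#' For every gene and timepoint in a Ct table, computes the 2^-ddCt fold
#' change and the per-timepoint significance test, then classifies each
#' gene's expression pattern and flags key candidates.
#'
#' @param ct_table Ct data.frame from [read_ct_table()] or the simulator.
#' @inheritParams timepoint_test
#' @param margin Fold threshold for pattern classification.
#' @return List with `per_timepoint` (data.frame `gene_id`, `timepoint`,
#'   `fold_change`, `p_value`, `significant`) and `per_gene` (`gene_id`,
#'   `pattern_type`, `n_significant`, `key_candidate`).
#' @export
qpcr_timecourse <- function(ct_table, alpha = 0.05, margin = 1,
                            treatment = "FE_DEFICIENT", control = "CK",
                            test_on = c("rel", "ct"), var_equal = TRUE) {
  test_on <- match.arg(test_on)
  genes <- unique(ct_table$gene_id)
  rows <- list()
  for (g in genes) {
    sub_g <- ct_table[ct_table$gene_id == g, , drop = FALSE]
    for (tp in sort(unique(sub_g$timepoint))) {
      m <- sub_g[sub_g$timepoint == tp, , drop = FALSE]
      fold <- ddct(m, treatment, control)
      tst <- timepoint_test(m, alpha, treatment, control, test_on, var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, timepoint = tp, fold_change = fold,
        p_value = tst$p_value, significant = tst$significant,
        stringsAsFactors = FALSE)
    }
  }
  per_tp <- do.call(rbind, rows)
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    sub_g <- per_tp[per_tp$gene_id == g, , drop = FALSE]
    folds <- setNames(sub_g$fold_change, as.character(sub_g$timepoint))
    pat <- if (all(as.character(QPCR_TIMEPOINTS) %in% names(folds))) {
      classify_pattern(folds, margin)
    } else {
      NA_character_
    }
    sig <- sub_g$significant
    dirs <- sign(sub_g$fold_change[sig] - 1)
    key <- sum(sig) >= 3L && length(unique(dirs)) == 1L
    data.frame(gene_id = g, pattern_type = pat, n_significant = sum(sig),
               key_candidate = key, stringsAsFactors = FALSE)
  }))
  list(per_timepoint = per_tp, per_gene = per_gene)
}

#' Key Fe-deficiency candidates from a time-course analysis
#'
#' A gene is a key candidate when it is significantly regulated at three or
#' more timepoints, all in the same direction (all up or all down among the
#' significant points).
#'
#' @param results Result list from [qpcr_timecourse()].
#' @return Character vector of key-candidate gene ids.
#' @export
key_candidates <- function(results) {
  pg <- results$per_gene
  pg$gene_id[pg$key_candidate]
}
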