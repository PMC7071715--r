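tpm_fixture <- function() {
  m <- rbind(off = c(0, 0), faint = c(0.04, 0.06), mid = c(2, 4),
             high = c(250, 260), exactly3 = c(3, 3))
  colnames(m) <- c("s1", "s2")
  m
}

test_that("expression filtering uses the mean TPM with a strict floor", {
  m <- tpm_fixture()
  expect_setequal(expressed_genes(m), c("faint", "mid", "high", "exactly3"))
  expect_false("off" %in% expressed_genes(m))
  # a faint 0.05-level gene counts as expressed at the default floor
  expect_true("faint" %in% expressed_genes(m))
  expect_setequal(expressed_genes(m, min_tpm = 1), c("mid", "high", "exactly3"))
  expect_error(expressed_genes(m, samples = "nope"), "nope")
})

test_that("the cascade intersects sets and applies a strict TPM cut", {
  m <- tpm_fixture()
  ex <- expressed_genes(m)
  # disjoint GO set: empty overlap
  expect_length(cascade(ex, c("zz"), m)$overlap, 0L)
  cs <- cascade(ex, c("mid", "high", "exactly3", "off"), m, tpm_cut = 3)
  expect_setequal(cs$overlap, c("mid", "high", "exactly3"))
  # mean TPM exactly 3.00 is excluded by the strict inequality
  expect_setequal(cs$shortlist, "high")
  expect_equal(unname(cs$counts), c(4L, 4L, 3L, 1L))
  # monotone: raising the cut never grows the shortlist
  for (cut in c(0, 1, 3, 100, 500)) {
    s_lo <- cascade(ex, rownames(m), m, tpm_cut = cut)$shortlist
    s_hi <- cascade(ex, rownames(m), m, tpm_cut = cut + 1)$shortlist
    expect_true(all(s_hi %in% s_lo))
  }
})

test_that("planted cascade structure is recovered exactly", {
  ex <- generate_expression(scaled_config(seed = 61))
  e <- expressed_genes(ex$tpm)
  expect_setequal(e, ex$truth$expressed)
  go_set <- go_gene_set(ex$go, "response to abiotic stimulus")
  expect_setequal(go_set, ex$truth$go_set)
  cs <- cascade(e, go_set, ex$tpm)
  expect_setequal(cs$overlap, ex$truth$overlap)
  expect_setequal(cs$shortlist, ex$truth$shortlist)
  expect_equal(unname(cs$counts), c(30L, 25L, 20L, 10L))
})

ct_fixture <- function(ck_dct, fe_dct, ref = 18) {
  n <- length(ck_dct)
  data.frame(
    gene_id = "g", timepoint = 1,
    condition = rep(c("CK", "FE_DEFICIENT"), each = n),
    replicate = rep(seq_len(n), 2),
    ct_target = ref + c(ck_dct, fe_dct),
    ct_reference = ref
  )
}

test_that("2^-ddCt fold changes follow the closed form", {
  expect_equal(ddct(ct_fixture(c(5, 5, 5), c(5, 5, 5))), 1.0)
  expect_equal(ddct(ct_fixture(c(5, 5, 5), c(4, 4, 4))), 2.0)   # ddCt = -1
  expect_equal(ddct(ct_fixture(c(5, 5, 5), c(7, 7, 7))), 0.25)  # ddCt = +2
  # reciprocal symmetry under swapping the conditions
  x <- ct_fixture(c(5.1, 4.9, 5.0), c(3.7, 4.2, 4.0))
  expect_equal(ddct(x), 1 / ddct(x, treatment = "CK", control = "FE_DEFICIENT"))
  expect_error(ddct(x[x$condition == "CK", ]), "missing condition")
})

test_that("the timepoint test behaves at the degenerate corners", {
  same <- ct_fixture(c(5, 5, 5), c(5, 5, 5))
  res <- timepoint_test(same)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  sep <- ct_fixture(c(5.01, 5.0, 4.99), c(3.01, 3.0, 2.99))
  expect_lt(timepoint_test(sep)$p_value, 0.05)
  # zero variance but different means: overwhelming evidence
  forced <- ct_fixture(c(5, 5, 5), c(3, 3, 3))
  expect_equal(timepoint_test(forced)$p_value, 0)
  expect_error(timepoint_test(ct_fixture(5, 5)), "2 replicates")
})

test_that("pattern classification matches the three verbal archetypes", {
  tp <- as.character(c(0.5, 1.5, 2, 7, 12))
  f <- function(v) setNames(v, tp)
  expect_equal(classify_pattern(f(c(2, 3, 2, 2, 2))), "EARLY_UP")
  expect_equal(classify_pattern(f(c(0.5, 2, 2, 0.8, 0.6))), "MID_UP")
  expect_equal(classify_pattern(f(c(0.8, 0.9, 0.7, 2, 3))), "LATE_UP")
  expect_equal(classify_pattern(f(c(0.4, 0.5, 0.6, 0.5, 0.4))), "OTHER")
  expect_error(classify_pattern(setNames(1:4, tp[1:4])), "missing timepoint")
  # mutually exclusive and exhaustive over random trajectories
  set.seed(901)
  for (r in 1:200) {
    v <- f(2^runif(5, -2, 2))
    expect_true(classify_pattern(v) %in%
                  c("EARLY_UP", "MID_UP", "LATE_UP", "OTHER"))
  }
  # a margin above 1 demands stronger induction
  expect_equal(classify_pattern(f(c(1.1, 1, 1, 1, 1))), "EARLY_UP")
  expect_equal(classify_pattern(f(c(1.1, 1, 1, 1, 1)), margin = 1.2), "OTHER")
})

test_that("key candidates need three same-direction significant timepoints", {
  mk <- function(gene, sig, fold) {
    data.frame(gene_id = gene, timepoint = c(0.5, 1.5, 2, 7, 12),
               fold_change = fold, p_value = ifelse(sig, 0.01, 0.5),
               significant = sig)
  }
  res <- list(per_timepoint = NULL, per_gene = NULL)
  pg <- do.call(rbind, list(
    data.frame(gene_id = "up3", pattern_type = "EARLY_UP", n_significant = 3,
               key_candidate = TRUE),
    data.frame(gene_id = "up2", pattern_type = "EARLY_UP", n_significant = 2,
               key_candidate = FALSE)
  ))
  res$per_gene <- pg
  expect_equal(key_candidates(res), "up3")

  # through the full analysis: mixed directions are excluded
  noise <- c(-0.01, 0, 0.01)
  rows <- list()
  for (tp in c(0.5, 1.5, 2, 7, 12)) {
    # 4-fold up at three points, 4-fold down at two points, all significant
    delta <- if (tp %in% c(0.5, 1.5, 2)) -2 else 2
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = "mixed", condition = rep(c("CK", "FE_DEFICIENT"), each = 3),
      timepoint = tp, replicate = 1:3,
      ct_target = 24 + c(noise, delta + noise), ct_reference = 18)
  }
  out <- qpcr_timecourse(do.call(rbind, rows))
  expect_equal(out$per_gene$n_significant, 5L)
  expect_false(out$per_gene$key_candidate)
})

test_that("noise-free planted trajectories are recovered verbatim", {
  cfg <- scaled_config(seed = 62)
  cfg$qpcr$noise_sd <- 0
  q <- generate_qpcr(cfg)
  res <- qpcr_timecourse(q$ct)
  tp <- as.character(c(0.5, 1.5, 2, 7, 12))
  for (g in q$truth$trajectories$gene_id) {
    folds <- res$per_timepoint$fold_change[res$per_timepoint$gene_id == g]
    planted <- unlist(q$truth$trajectories[
      q$truth$trajectories$gene_id == g, tp])
    expect_equal(unname(folds), unname(planted), tolerance = 1e-12)
  }
  got <- setNames(res$per_gene$pattern_type, res$per_gene$gene_id)
  expect_equal(got[names(q$truth$pattern)], q$truth$pattern)
})

test_that("strong planted responders are flagged with few false positives", {
  # 20 strong 4-fold responders at four timepoints plus 60 null genes
  tp <- c(0.5, 1.5, 2, 7, 12)
  traj <- data.frame(gene_id = sprintf("G%03d", 1:80))
  folds <- matrix(1, nrow = 80, ncol = 5,
                  dimnames = list(NULL, as.character(tp)))
  folds[1:20, c(1, 2, 3, 4)] <- 4
  traj <- cbind(traj, as.data.frame(folds))
  cfg <- scaled_config(seed = 63)
  q <- generate_qpcr(cfg, trajectories = traj)
  res <- qpcr_timecourse(q$ct)
  keys <- key_candidates(res)
  expect_gte(sum(sprintf("G%03d", 1:20) %in% keys), 19)
  expect_lte(sum(!keys %in% sprintf("G%03d", 1:20)), 1)
})
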