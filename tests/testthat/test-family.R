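test_that("global identity handles forced alignments and is symmetric", {
  expect_equal(global_identity("MKTLV", "MKTLV"), 100)
  expect_equal(global_identity("AAAA", "AAAT"), 75)
  set.seed(701)
  for (r in 1:5) {
    a <- random_protein(sample(8:20, 1))
    b <- random_protein(sample(8:20, 1))
    expect_equal(global_identity(a, b), global_identity(b, a))
  }
  # denominator conventions
  expect_equal(global_identity("AAAA", "AA", denominator = "shorter"), 100)
})

test_that("alignment scores match the brute-force affine DP oracle", {
  set.seed(702)
  for (r in 1:12) {
    a <- random_protein(sample(3:12, 1))
    b <- random_protein(sample(3:12, 1))
    expect_equal(global_alignment(a, b)$score,
                 nw_affine_oracle_score(a, b), tolerance = 1e-9)
  }
})

test_that("naming assigns best references with descending decimal suffixes", {
  idm <- matrix(c(62.1, 20.0,
                  30.0, 55.5), nrow = 2, byrow = TRUE,
                dimnames = list(c("c1", "c2"), c("AtbHLH47", "AtbHLH29")))
  nm <- assign_names(idm)
  expect_equal(nm$assigned_name, c("CgbHLH47", "CgbHLH29"))

  idm2 <- matrix(c(64.41, 10, 61.9, 10, 30, 35) , nrow = 3, byrow = TRUE,
                 dimnames = list(c("candB", "candA", "candC"),
                                 c("AtbHLH29", "AtbHLH5")))
  nm2 <- assign_names(idm2)
  # two candidates share AtbHLH29: suffixes in strictly descending identity
  expect_equal(nm2$assigned_name[nm2$candidate_id == "candB"], "CgbHLH29.1")
  expect_equal(nm2$assigned_name[nm2$candidate_id == "candA"], "CgbHLH29.2")
  expect_equal(nm2$assigned_name[nm2$candidate_id == "candC"], "CgbHLH5")

  # equal identities: suffix order by candidate id
  idm3 <- matrix(c(50, 50, 50), ncol = 1,
                 dimnames = list(c("z", "a", "m"), "Ref7"))
  nm3 <- assign_names(idm3, base_prefix = "Fam")
  expect_equal(nm3$assigned_name[match(c("a", "m", "z"), nm3$candidate_id)],
               c("Fam7.1", "Fam7.2", "Fam7.3"))

  # renaming is stable under row permutation
  perm <- sample(nrow(idm2))
  nm2p <- assign_names(idm2[perm, , drop = FALSE])
  nm2p <- nm2p[match(nm2$candidate_id, nm2p$candidate_id), ]
  expect_equal(nm2p$assigned_name, nm2$assigned_name)
})

test_that("p-distances count mismatches over shared present positions", {
  m <- matrix(strsplit(strrep("ACDEFGHIKL", 6), "")[[1]],
              nrow = 1)[rep(1, 3), ]
  rownames(m) <- c("a", "b", "c")
  m["b", 1:6] <- "W"   # 6 of 60 differ
  d <- pdistance_matrix(m)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.1)
  expect_equal(d, t(d))
  # absent positions drop out of the denominator
  m["c", 1:30] <- NA
  d2 <- pdistance_matrix(m)
  expect_equal(d2["a", "c"], 0)          # 30 shared, all equal
  expect_equal(d2["b", "c"], 0)          # W-columns not shared
  # counting oracle on random data with random absences
  set.seed(703)
  r <- matrix(sample(c(AA20, NA), 5 * 60, replace = TRUE,
                     prob = c(rep(1, 20), 4)), nrow = 5)
  rownames(r) <- paste0("s", 1:5)
  dr <- pdistance_matrix(r)
  for (i in 1:4) for (j in (i + 1):5) {
    both <- !is.na(r[i, ]) & !is.na(r[j, ])
    expect_equal(dr[i, j], mean(r[i, both] != r[j, both]))
  }
  # a pair with no shared position errors
  m2 <- rbind(a = c("A", NA), b = c(NA, "C"))
  expect_error(pdistance_matrix(m2), "shared")
})

test_that("neighbor joining recovers additive trees exactly", {
  # the worked 4-taxon case: terminal branches 1,2,3,4 and internal 5
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1 + 2
  d["a", "c"] <- d["c", "a"] <- 1 + 5 + 3
  d["a", "d"] <- d["d", "a"] <- 1 + 5 + 4
  d["b", "c"] <- d["c", "b"] <- 2 + 5 + 3
  d["b", "d"] <- d["d", "b"] <- 2 + 5 + 4
  d["c", "d"] <- d["d", "c"] <- 3 + 4
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  pd <- ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]]
  expect_equal(pd, d, tolerance = 1e-12)
  # internal edge of length 5 present
  internal <- tr$edge[, 1] > ape::Ntip(tr) & tr$edge[, 2] > ape::Ntip(tr)
  expect_equal(tr$edge.length[internal], 5)

  # 3 taxa: closed-form branch lengths v_i = (d(i,j) + d(i,k) - d(j,k)) / 2
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["x"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["y"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["z"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d3[1:2, 1:2]), "3 taxa")

  # random additive matrices from random 5-8 taxon trees
  set.seed(704)
  for (r in 1:10) {
    tr0 <- ape::rtree(sample(5:8, 1))
    tr0$edge.length <- runif(nrow(tr0$edge), 0.1, 2)
    dm <- ape::cophenetic.phylo(tr0)
    fit <- nj_tree(dm)
    expect_equal(ape::cophenetic.phylo(fit)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }

  # ultrametric distances: NJ topology agrees with UPGMA (average linkage)
  set.seed(705)
  coal <- ape::rcoal(6)
  dmu <- ape::cophenetic.phylo(coal)
  nj_fit <- nj_tree(dmu)
  upgma_fit <- ape::as.phylo(stats::hclust(stats::as.dist(dmu), "average"))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj_fit),
                                         ape::unroot(upgma_fit))), 0)
})

test_that("bootstrap supports are percentages of replicate bipartitions", {
  # perfectly congruent alignment: two clearly separated clades
  a_dom <- strsplit(strrep("AC", 30), "")[[1]]
  b_dom <- strsplit(strrep("WY", 30), "")[[1]]
  jitter_rows <- function(base, k, flip_at) {
    t(vapply(seq_len(k), function(i) {
      d <- base
      d[flip_at[i]] <- "G"
      d
    }, character(60)))
  }
  m <- rbind(jitter_rows(a_dom, 3, c(1, 3, 5)),
             jitter_rows(b_dom, 3, c(2, 4, 6)))
  rownames(m) <- paste0("t", 1:6)
  tr <- bootstrap_support(m, n_reps = 50, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # the a/b split is in every replicate
  expect_true(any(sup[!is.na(sup)] == 100))
  # a single replicate can only give 0 or 100
  tr1 <- bootstrap_support(m, n_reps = 1, seed = 5)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  # fixed seed: identical supports
  tr2 <- bootstrap_support(m, n_reps = 50, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("subfamily labels are inherited from the smallest monolabel clade", {
  tr <- ape::read.tree(
    text = "(((cand1:1,ref1:1):1,(ref2:1,ref3:1):1):1,((cand2:1,(ref4:1,ref5:1):1):1,(ref6:1,cand3:1):1):1);")
  labels <- c(ref1 = "6", ref2 = "6", ref3 = "6",
              ref4 = "2", ref5 = "2", ref6 = "9")
  got <- assign_subfamilies(tr, labels)
  expect_equal(got[["cand1"]], "6")   # sister to a single labeled reference
  expect_equal(got[["cand2"]], "2")   # inside a clade of monolabel references
  expect_equal(got[["cand3"]], "9")
  # mixed nearest labeled clade: unassigned
  tr2 <- ape::read.tree(text = "((candX:1,(refA:1,refB:1):1):1,refC:1);")
  got2 <- assign_subfamilies(tr2, c(refA = "1", refB = "2", refC = "1"))
  expect_equal(got2[["candX"]], "UNASSIGNED")
  expect_error(assign_subfamilies(tr2, c(zz = "1")), "no reference")
})

test_that("planted subfamily memberships are recovered from a built tree", {
  # construct a tree with one clade per subfamily, two references and two
  # candidates each
  make_clade <- function(s) {
    sprintf("((r%da:1,r%db:1):1,(c%da:1,c%db:1):1):1", s, s, s, s)
  }
  txt <- paste0("(", paste(vapply(1:4, make_clade, character(1)),
                           collapse = ","), ");")
  tr <- ape::read.tree(text = txt)
  labels <- setNames(rep(as.character(1:4), each = 2),
                     as.vector(t(outer(paste0("r", 1:4), c("a", "b"),
                                       paste0))))
  got <- assign_subfamilies(tr, labels)
  for (s in 1:4) {
    expect_equal(unname(got[paste0("c", s, c("a", "b"))]),
                 rep(as.character(s), 2))
  }
})

test_that("trees serialize to Newick with support labels", {
  m <- matrix(sample(AA20, 4 * 60, replace = TRUE), nrow = 4)
  rownames(m) <- paste0("t", 1:4)
  tr <- bootstrap_support(m, n_reps = 10, seed = 1)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, rownames(m))
})
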