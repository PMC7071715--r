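test_that("FASTA reading normalizes records and round-trips through write", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">geneA first protein", "mkTlv", ">geneB", "ACDEF*"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("geneA", "geneB"))
  expect_equal(rec$sequence, c("MKTLV", "ACDEF"))  # uppercased, stop stripped
  expect_equal(rec$description[1], "first protein")

  f2 <- tempfile(fileext = ".fa")
  write_fasta(rec, f2)
  expect_equal(read_fasta(f2), rec)
})

test_that("FASTA reading rejects duplicates, gaps and empty files", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">dup", "ACD", ">dup", "EFG"), f)
  expect_error(read_fasta(f), "dup")
  writeLines(c(">x", "AC-DE"), f)
  expect_error(read_fasta(f), "gap")
  writeLines(character(0), f)
  expect_error(read_fasta(f))
})

test_that("GFF3 gene models collate exons and record strand and UTRs", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t900\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t900\t.\t-\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t700\t900\t.\t-\t.\tID=e3;Parent=g1.t1",
    "chr1\tsrc\texon\t100\t200\t.\t-\t.\tID=e1;Parent=g1.t1",
    "chr1\tsrc\texon\t400\t500\t.\t-\t.\tID=e2;Parent=g1.t1",
    "chr1\tsrc\tfive_prime_UTR\t100\t120\t.\t-\t.\tID=u1;Parent=g1.t1"
  ), f)
  gm <- read_gff3(f)
  expect_equal(nrow(gm), 1L)
  expect_equal(gm$strand, "-")
  expect_equal(gm$n_exons, 3L)
  # exons sorted by ascending start even on the minus strand
  expect_equal(gm$exons[[1]]$start, c(100, 400, 700))
  expect_true(gm$utr_present)
})

test_that("GFF3 exons without a resolvable parent gene are an error", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=ghost"
  ), f)
  expect_error(read_gff3(f), "ghost")
})

test_that("synthetic GFF3 written by the generator round-trips to its truth", {
  lay <- generate_genome_layout(scaled_config(seed = 21))
  f <- tempfile(fileext = ".gff3")
  write_gff3(lay$models, f)
  back <- suppressWarnings(read_gff3(f))
  m <- merge(lay$models[, c("id", "chromosome", "start", "end", "strand")],
             back[, c("id", "chromosome", "start", "end", "strand")],
             by = "id")
  expect_equal(nrow(m), nrow(lay$models))
  expect_equal(m$chromosome.x, m$chromosome.y)
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
  expect_equal(m$strand.x, m$strand.y)
})

test_that("ORF length to protein length follows the stop-codon convention", {
  expect_identical(protein_length_from_orf(210), 69L)
  expect_identical(protein_length_from_orf(4401), 1466L)
  expect_identical(protein_length_from_orf(6), 1L)
  expect_error(protein_length_from_orf(211), "divisible")
  expect_error(protein_length_from_orf(3))
  # linearity: one codon more, one residue more
  orfs <- seq(6, 300, by = 3)
  expect_equal(protein_length_from_orf(orfs + 3),
               protein_length_from_orf(orfs) + 1L)
})

test_that("CDS translation emits no stop and rejects malformed input", {
  expect_identical(translate_cds("ATGGCTTAA"), "MA")
  expect_identical(translate_cds("ATGTAA"), "M")
  expect_error(translate_cds("ATGTAAGCT"), "internal stop")
  expect_error(translate_cds("ATGNNNTAA"), "non-ACGT")
  expect_error(translate_cds("GCTGCTTAA"), "ATG")
})

test_that("translation matches an independent genetic-code implementation", {
  set.seed(401)
  for (r in 1:10) {
    # random internal codons with no stop, then a stop codon
    codons <- character(0)
    while (length(codons) < 299) {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!cd %in% c("TAA", "TAG", "TGA")) codons <- c(codons, cd)
    }
    cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    mine <- translate_cds(cds)
    expect_equal(nchar(mine), nchar(cds) / 3 - 1)
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(paste0(mine, "*"), oracle)
  }
})

test_that("molecular weight is the residue-mass sum plus one water", {
  expect_equal(compute_mw("G"), 0.0750672, tolerance = 1e-7)
  s1 <- "GAVLK"; s2 <- "WYRH"
  expect_equal(compute_mw(paste0(s1, s2)),
               compute_mw(s1) + compute_mw(s2) - 18.0153 / 1000,
               tolerance = 1e-10)
  # brute-force summation oracle with independently transcribed masses
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  set.seed(402)
  for (r in 1:5) {
    s <- random_protein(100)
    oracle <- (sum(masses[strsplit(s, "")[[1]]]) + 18.0153) / 1000
    expect_equal(compute_mw(s), oracle, tolerance = 1e-6)
  }
  expect_error(compute_mw("GXV", strict = TRUE), "unknown")
  expect_gt(compute_mw("GXV"), compute_mw("GV"))  # lenient mean mass
})

test_that("isoelectric point solves the charge equation", {
  # only the termini ionize: pI is their pKa midpoint
  expect_equal(compute_pi("AAAA"), (8.6 + 3.6) / 2, tolerance = 1e-3)
  # basic residues raise the pI, acidic residues lower it
  set.seed(403)
  for (r in 1:5) {
    s <- random_protein(30)
    expect_gt(compute_pi(paste0(s, "R")), compute_pi(s))
    expect_lt(compute_pi(paste0(s, "D")), compute_pi(s))
  }
  # grid-search oracle agreement
  for (r in 1:20) {
    s <- random_protein(sample(10:60, 1))
    expect_equal(compute_pi(s), grid_pi_oracle(s), tolerance = 0.011)
  }
})

test_that("protein_stats exports the documented TSV columns", {
  rec <- data.frame(id = c("p1", "p2"), sequence = c("MKTLV", "ACDEFGH"),
                    description = "")
  st <- protein_stats(rec)
  expect_equal(st$gene_id, c("p1", "p2"))
  expect_equal(st$length_aa, c(5L, 7L))
  expect_true(all(st$mw_kda > 0) && all(st$pi > 0 & st$pi < 14))
  f <- tempfile(fileext = ".tsv")
  write_protein_stats(st, f)
  expect_equal(names(read.delim(f)), c("gene_id", "length_aa", "mw_kda", "pi"))
})
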