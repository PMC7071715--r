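# Average (isotope-averaged) residue masses in daltons, ExPASy-style, i.e.
# the monomer mass minus one water. A free protein adds one water molecule.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# EMBOSS-style pKa table used for the isoelectric-point model: side chains of
# C, D, E, H, K, R, Y plus the free termini. A single fixed table keeps pI
# values reproducible; different servers use slightly different tables.
PI_PKA <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

#' Protein length encoded by an open reading frame
#'
#' The ORF length convention includes the stop codon, so a complete ORF of
#' `orf_bp` base pairs encodes `orf_bp / 3 - 1` amino acids (e.g. 210 bp
#' encode 69 aa).
#'
#' @param orf_bp Integer vector of ORF lengths in base pairs; each must be
#'   divisible by 3 and at least 6 (one codon plus the stop).
#' @return Integer vector of protein lengths in amino acids.
#' @export
protein_length_from_orf <- function(orf_bp) {
  if (any(orf_bp %% 3 != 0)) {
    stop("ORF length not divisible by 3: ",
         paste(orf_bp[orf_bp %% 3 != 0], collapse = ", "))
  }
  if (any(orf_bp < 6)) stop("ORF length must be >= 6 bp")
  as.integer(orf_bp / 3 - 1)
}

#' Translate a coding sequence
#'
#' Standard genetic code. The CDS must start with ATG; a terminal stop codon
#' ends translation and is not emitted; an internal stop codon is an error.
#'
#' @param cds Nucleotide string (ACGT), length divisible by 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("non-ACGT character in CDS")
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS does not start with ATG")
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    if (any(stops < length(aa))) stop("internal stop codon at codon ",
                                      stops[stops < length(aa)][1L])
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

#' Average molecular weight of a protein, in kilodaltons
#'
#' Sum of average residue masses plus one water molecule (18.0153 Da),
#' matching the convention of protein parameter servers. In lenient mode
#' (default) the ambiguous residue `X` contributes the mean of the twenty
#' standard residue masses; in strict mode it is an error.
#'
#' @param sequence Amino-acid string.
#' @param strict If `TRUE`, any non-standard residue is an error.
#' @return Molecular weight in kDa.
#' @export
compute_mw <- function(sequence, strict = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(toupper(sequence), "")[[1L]]
  known <- res %in% names(AA_AVG_MASS)
  if (!all(known)) {
    bad <- unique(res[!known])
    if (strict || any(bad != "X")) {
      stop("unknown residue(s): ", paste(bad, collapse = ", "))
    }
  }
  masses <- AA_AVG_MASS[res]
  masses[is.na(masses)] <- mean(AA_AVG_MASS)
  (sum(masses) + WATER_MASS) / 1000
}

# Net charge of a peptide at a given pH under the Henderson-Hasselbalch
# model; counts holds the number of each ionizable side chain.
.net_charge <- function(ph, counts, pka = PI_PKA) {
  pos <- c(Nterm = 1, K = unname(counts["K"]), R = unname(counts["R"]),
           H = unname(counts["H"]))
  neg <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
           C = unname(counts["C"]), Y = unname(counts["Y"]))
  cr_pos <- 10^(pka[names(pos)] - ph)
  cr_neg <- 10^(ph - pka[names(neg)])
  sum(pos * cr_pos / (cr_pos + 1)) - sum(neg * cr_neg / (cr_neg + 1))
}

#' Isoelectric point of a protein
#'
#' pH at which the Henderson-Hasselbalch net charge is zero, found by
#' bisection on \[0, 14\] to a tolerance of 1e-4 pH units. The fixed
#' EMBOSS-style pKa table is exported as `PI_PKA`.
#'
#' @param sequence Amino-acid string (standard residues; `X` carries no
#'   charge).
#' @return Isoelectric point in pH units.
#' @export
compute_pi <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(toupper(sequence), "")[[1L]]
  counts <- vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                   function(a) sum(res == a), numeric(1))
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (.net_charge(mid, counts) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical statistics for a set of proteins
#'
#' @param records Protein data.frame from [read_fasta()].
#' @return A data.frame with columns `gene_id`, `length_aa`, `mw_kda`, `pi`.
#' @export
protein_stats <- function(records) {
  data.frame(
    gene_id = records$id,
    length_aa = nchar(records$sequence),
    mw_kda = vapply(records$sequence, compute_mw, numeric(1), USE.NAMES = FALSE),
    pi = vapply(records$sequence, compute_pi, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write protein statistics as TSV
#'
#' @param stats Data.frame from [protein_stats()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
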