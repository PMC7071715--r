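---
title: "Methods: mining and characterizing a bHLH transcription-factor family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterizing a bHLH transcription-factor family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`bhlhtools` implements a genome-wide gene-family survey workflow for the
basic/helix-loop-helix (bHLH) transcription factors: discover the domain in
a proteome, classify each member's DNA-binding potential, profile
conservation, name members after their closest reference orthologs, build a
neighbor-joining phylogeny with bootstrap support, call tandem and
segmental (collinear) duplications, and prioritize candidates for an
iron-deficiency response from expression data and qPCR time courses. A
synthetic-data generator emulates every input with a ground-truth manifest,
so the whole pipeline is testable offline, end to end.

# The canonical domain and its discovery

The bHLH domain is modeled as a fixed 60-position coordinate system: a
basic region (positions 1–17) that contacts DNA, helix 1 (18–32), a loop
(33–42) and helix 2 (43–60). Domain discovery uses a position-specific
scoring matrix (PSSM) built from a seed alignment of reference domains.
Per column the score of residue $r$ is the smoothed log-odds

$$s_j(r) = \log_2 \frac{(c_{j,r} + \alpha\, b_r) / (n_j + \alpha)}{b_r},$$

with $c_{j,r}$ the residue count among the $n_j$ non-gap rows, $b$ a
background distribution (uniform by default) and $\alpha$ a pseudocount.
Columns that are more than half gaps are excluded from scoring but keep
their place, so profile column $i$ always maps to canonical position $i$.

The scan is a fixed-width sliding window with terminal truncation: every
placement leaving at least 35 columns inside the protein is scored, and
placements above the calling threshold are reduced to the best-scoring
non-overlapping set (ties to the leftmost start). There are no
insert/delete states: the bHLH core is nearly fixed-length, and a
window scan is exactly reproducible and shift-equivariant. The price is
that a protein with a sizable internal indel relative to the profile is
only detectable if 35 or more contiguous columns still match; this is a
deliberate trade of sensitivity for determinism.

Two numbers govern calling and were calibrated together on the synthetic
benchmark (the calibration is re-run by the test suite):

* **pseudocount** `pseudocount = 20`. With a uniform background a zero
  count would otherwise cost about $-5$ bits per column; domains are drawn
  from profiles whose minor residues are individually rare, so heavy
  smoothing is needed to avoid punishing legitimate but unseen residues.
* **threshold** `threshold_bits = 10`. Planted domains (including ones
  whose basic region has been stripped of basic residues) stay above this
  threshold while per-protein shuffled decoys stay below it, with zero
  decoy calls across repeated benchmark runs.

Multiple hits per protein are allowed, but downstream stages use only the
best hit per protein, treating each protein as one bHLH.

# DNA-binding classification

Classification is a pure function of the basic region, applied in order:

1. `NON_DNA_BINDING` if positions 1–17 carry five or fewer basic residues
   (the "more than 5" rule read as $\ge 6$); an entirely absent basic
   region (a truncated hit) also lands here.
2. `NON_E_BOX` if Glu-13 and Arg-16 are not both present — the pair
   required to recognize the E-box motif CANNTG.
3. `G_BOX` if, additionally, position 9 is His or Lys and position 17 is
   Arg, the residues conferring specificity for the CACGTG G-box.
4. `NON_G_BOX` otherwise.

"Basic residues" defaults to {K, R, H}, the standard biochemical set; the
`basic_set` argument exposes the stricter {K, R} convention because the
literature on this rule does not state whether histidine was counted.
The four categories partition any domain set, and the counts nest:
G-box $\subseteq$ E-box $\subseteq$ DNA-binding.

Conservation is summarized per canonical position as the consensus ratio —
the modal residue frequency among domains *present* at that position.
Absent positions are excluded from numerator and denominator; the
alternative (counting all members in the denominator) would conflate
truncation with divergence. Thresholded queries (`conserved_positions`)
use a strict inequality.

# Naming, phylogeny and subfamilies

Candidates are named after the reference with the highest global percent
identity: Needleman–Wunsch with BLOSUM62, gap open 10 and gap extension
0.5 per residue (conventional defaults), identity = matches / full
alignment length including gap columns (the Clustal-Omega-style
denominator; the shorter-sequence denominator is available). When several
candidates share a best reference they are distinguished with decimal
suffixes `.1`, `.2`, … in strictly descending identity, ties broken by
candidate id so renaming is stable under input permutation.

The phylogeny is distance-based and deterministic: domains are compared in
canonical coordinates (no re-estimated multiple alignment), pairwise
p-distance = mismatches over shared present positions, and the tree is
Saitou–Nei neighbor joining with negative branch lengths clamped to zero.
NJ recovers any additive distance matrix exactly, which the tests exploit
as an oracle: a random tree's path-length matrix must be reproduced to
within 1e-9. Bootstrap support resamples alignment columns with
replacement under a fixed seed; support is the percentage of replicate
trees containing each reference-tree bipartition.

Subfamily labels are inherited from references: each candidate takes the
label of the smallest clade containing it whose reference leaves carry a
single label, and stays `UNASSIGNED` when the nearest labeled clade is
mixed. On the simulated study (which plants weak subfamily signatures, six
positions per subfamily) this recovers most memberships but is not exact —
agreement is a property of the signal strength, not of the algorithm, and
no test asserts it.

# Duplication calling

Duplication analysis works on gene ranks (ordinal position by start
coordinate per chromosome) and a homolog-pair table. Two family genes are
*tandem* when they are homologous, on one chromosome, and within
`max_gap_genes = 1` rank of each other; calls are connected components of
those links, so an adjacent homologous trio is one three-gene cluster.
*Collinear blocks* are dynamic-programming chains of homolog pairs whose
ranks advance consistently on both regions, requiring at least
`min_block = 5` pairs with per-step gaps of at most `max_gap = 25` ranks —
the defaults of the standard collinearity-scanning tool this module
replaces. Antiparallel chaining (for inverted blocks) is on by default.
Family genes inside any block are segmental-duplication calls; tandem and
segmental membership may overlap and are reported separately.

Homology defaults to a global-identity threshold of 40% when derived from
sequences (`homolog_pairs`), standing in for the BLAST e-value cutoff that
cannot be reproduced without the original search stack; the synthetic
generator instead emits its planted pairs explicitly.

# Candidate prioritization

The cascade is three strict set operations: genes expressed in root
samples (mean TPM > `min_tpm`, default 0), intersected with a GO-defined
gene set ("response to abiotic stimulus"), then shortlisted at mean TPM
strictly above `tpm_cut = 3.00` — the cut reflecting that qPCR is less
sensitive than RNA-seq.

qPCR analysis uses the $2^{-\Delta\Delta C_t}$ estimator with the control
condition at the same timepoint as baseline: per replicate
$\Delta C_t = C_t^{target} - C_t^{reference}$, $\Delta\Delta C_t$ is the
difference of condition means, and fold $= 2^{-\Delta\Delta C_t}$.
Per-timepoint significance is a two-sided Student's t-test (pooled
variance) on per-replicate relative expressions
$2^{-(\Delta C_t - \overline{\Delta C_t}^{\,CK})}$; whether the published
analyses tested Ct or fold values is unstated, so `test_on = "ct"` is
provided. Identical zero-variance groups give $p = 1$. No multiple-testing
correction is applied across genes or timepoints (raw $p < 0.05$, as is
conventional in qPCR panels of this kind).

Expression patterns over the five timepoints (0.5, 1.5, 2, 7, 12 days)
formalize three verbal archetypes, with "up" meaning fold > `margin`
(default 1; a margin of e.g. 1.2 guards against noise-only calls):
`EARLY_UP` is up at 0.5 d; `MID_UP` is not up at 0.5 d or 12 d but up at
some middle point; `LATE_UP` is not up at 0.5–2 d and up at 7 or 12 d;
`OTHER` absorbs the remainder, making the classes exclusive and
exhaustive. *Key candidates* are genes significant at three or more
timepoints, all in the same direction.

# What the simulator emulates — and what it does not

`simulate_bhlh_study()` re-enacts the shape of a real genome-wide survey
under one master seed. Defaults: 128 family members with binding-category
mix 58 / 40 / 6 / 24 (G-box / non-G-box / non-E-box / non-DNA-binding);
136 references in 18 subfamilies; 128 shuffled decoys; a 60-position
conservation profile with 19 positions planted at consensus probability
0.75 (0.92 at the two extreme leucines 27 and 56) and all others at 0.28,
so that exactly 19 positions exceed the 50% consensus ratio in expectation
and with large margin in samples of 128; a ten-chromosome layout with the
observed per-chromosome family counts, tandem clusters of sizes 2 and 3,
and two six-pair collinear blocks (one inverted); an expression table with
95 expressed genes drawn log-uniformly on the observed TPM range
0.05–281.08, an 86-gene GO set, a 66-gene overlap and 39 genes above the
3.00 cut, enforced exactly; and qPCR time courses (21 early-up, 9 mid-up,
4 late-up genes) with Gaussian Ct noise, sd 0.2 per well — a typical
replicate variation for the assay — and three biological replicates.

Category diagnostics are *forced* during domain sampling (positions 9, 13,
16, 17 and the basic-residue count), so the planted classification is a
construction guarantee, not a statistical one. Basic-count top-ups are
spread over random non-conserved basic-region positions to avoid creating
spurious conserved positions.

The simulator does **not** emulate: real amino-acid composition or
phylogenetic autocorrelation between family members (domains are sampled
i.i.d. from the profile, plus weak subfamily signatures); insertions or
deletions inside domains; intron/exon realism beyond a fixed two-exon
model; read-level expression noise (TPM values are planted, not
quantified); or primer efficiency effects in qPCR. Passing tests therefore
demonstrate that the algorithms recover what was planted under the stated
noise models — not that the discovery thresholds or pattern rules are
optimal for any particular real proteome.

A note on the qPCR recovery bound used in the acceptance tests: with Ct
noise sd 0.2 on both target and reference wells and three replicates, the
standard deviation of $\log_2$ of the estimated fold is
$0.2\sqrt{2}\sqrt{2/3} \approx 0.231$, so the 3.0–5.3 band around a
planted 4-fold induction analytically covers about 92.5% of estimates.
The test asserts the binomial floor of that coverage over 100 genes plus
an unbiasedness check on the mean, rather than a nominal 95% that the
noise model itself cannot deliver.

# Numerical choices

* Molecular weight: average (not monoisotopic) residue masses plus one
  water (18.0153 Da), the convention of the common protein-parameter
  servers; the ambiguous residue X contributes the mean residue mass in
  lenient mode and errors in strict mode.
* Isoelectric point: Henderson–Hasselbalch net charge with a fixed
  EMBOSS-style pKa table (exported as `PI_PKA`), zeroed by bisection on
  [0, 14] to 1e-4 pH units. Different servers ship slightly different pKa
  tables; a single committed table keeps results reproducible.
* ORF lengths include the stop codon: a complete ORF of $3(n+1)$ bp
  encodes $n$ residues. This convention is forced by the packaged family
  table (210 bp ↔ 69 aa).
* Coordinates are 1-based inclusive throughout (GFF3 convention); the BED
  export converts to 0-based half-open.
* All randomness (generators, bootstrap) flows from explicit integer
  seeds through R's default Mersenne-Twister generator; callers' RNG
  state is saved and restored.
* Scan ties are broken by leftmost start; NJ inherits deterministic
  tie-breaking from its implementation; exact bit-for-bit agreement with
  any particular GUI phylogenetics program is out of scope.

# Problem sizes

The shipped tests run the full-size synthetic study (128 + 136 + 128
sequences) where exactness matters and a scaled study (40 family members,
60 references) for pipeline-level checks; the pipeline's bootstrap default
is 100 replicates (1000, the conventional publication setting, remains a
parameter). The null calibration of the timepoint test uses 10,000
simulated tests. These sizes were chosen so the whole suite completes in
about a minute while every assertion retains its statistical margin.

# Known limitations

* The fixed-width scan cannot represent internal indels; a profile-HMM
  with insert states would be the next step in sensitivity at the cost of
  reproducibility and complexity.
* Subfamily inheritance depends on the reference tree being roughly
  correct; with weak signal it degrades to `UNASSIGNED` rather than
  guessing.
* The collinearity chainer is a deliberate simplification of a full
  synteny tool: no e-value weighting, no block scoring, no overlapping
  block resolution beyond greedy extraction of disjoint chains.
* The packaged 128-row family table is a transcription of a published
  summary table; one of its prose-level counts (genes with ORF length in
  700–2000 bp) disagrees with the table's own contents by one gene, and
  the package reports what the table contains.
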