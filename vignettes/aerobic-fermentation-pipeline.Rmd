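---
title: "Quantifying and dissecting aerobic fermentation across yeasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and dissecting aerobic fermentation across yeasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastferm)
```

`yeastferm` implements the computational core of a comparative screen for
aerobic fermentation in budding yeasts: quantification of glucose-driven
extracellular acidification rates (ECAR) from microplate kinetics,
phylogenetically corrected correlation of glycolytic gene-family sizes
with ECAR, orthogroup-level cross-species expression comparison, and
counting of degenerate transcription-factor binding-site consensus
matches in promoters. This vignette documents the models, their
assumptions, the defaults, and the design decisions taken where the
methodology admitted more than one defensible reading.

## 1. ECAR from phenol-red kinetics

**Model.** Phenol red's absorbance at 560 nm responds approximately
linearly to pH between 6.5 and 7.5. A calibration table of media at known
pH is fitted by ordinary least squares as `pH = a * A560 + b`
(`fit_standard_curve()`). We deliberately fit pH *as a function of*
absorbance — the direction needed downstream — rather than inverting an
absorbance-on-pH fit, which would divide by an estimated slope. Each
well's kinetic reads (every 3 min for 90 min, 31 timepoints) are
converted to pH and the acidification slope is fitted by OLS over the
full window, reported in pH/h. The ECAR statistic for one biological
replicate is the difference between its 2%-dextrose well's slope and its
water-control well's slope; rapid glycolysis gives negative ECAR.
Species-level values are replicate means with sample standard deviations
(`aggregate_replicates()`).

**Assumptions and choices.**

* *Fitting window*: the full 90-minute window by default. The maximal
  acidification phase could instead be isolated with the optional
  `window = c(t0, t1)` argument; full-window OLS is the simplest reading
  of "the slope of the pH trace" and is what the defaults use.
* *Pairing*: carbon and control wells are paired by (strain, replicate)
  before differencing. Wells without a partner are reported and skipped,
  never pooled. Differencing per pair (rather than between condition
  means) keeps day effects of a replicate inside its own difference.
* *Extrapolation*: absorbances outside the calibration range convert
  anyway and are flagged per timepoint; nothing is clipped, because a
  clipped trace would bias the slope invisibly.
* *Missing reads*: non-finite absorbances are dropped pairwise; fewer
  than 3 remaining timepoints is an error rather than a silent 2-point
  "fit".

## 2. PGLS under Brownian-motion covariance

**Model.** Across species, trait and predictor residuals are not
independent: closely related species inherited much of their biology from
a common ancestor. Under Brownian trait evolution the residual covariance
between species *i* and *j* is proportional to the branch length they
share from the root, `C[i, j] = depth(MRCA(i, j))` with root-to-tip
distances on the diagonal (`bm_covariance()`). `pgls()` fits

\[ y = \beta_0 + \beta_1 x + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2 C_\lambda), \]

where `C_λ` multiplies the off-diagonal of `C` by Pagel's λ: λ = 0 is a
star phylogeny (tip variances kept, correlations removed), λ = 1 pure
Brownian motion. Estimation is exact generalized least squares through an
upper Cholesky factor of `C_λ` (no explicit inverse is ever formed);
`σ²` uses the whitened residual sum of squares over `n − 2` degrees of
freedom, the slope test is a two-sided t test on `n − 2` df, and the
signed correlation `r_signed` is `sign(β₁) √R²` with `R²` measured
against the intercept-only GLS fit — so it is comparable to a Pearson r
while accounting for the tree.

**λ handling.** Fixed λ = 1 is the default: it is the canonical PGLS
assumption and is exactly reproducible. `lambda = "ml"` profiles the
λ likelihood on a 0.01 grid over [0, 1] (σ² profiled out analytically),
refines the best grid cell by golden-section search, and re-checks both
boundaries, which guards against a boundary optimum that the interior
refinement would miss.

**Numerical choices.** Singular `C_λ` — typically two tips joined by
zero-length branches — is an error that names the offending taxa; no
jitter is added silently. Species labels across tree, trait and count
tables are matched after case and space/underscore folding
(`normalize_species()`); unmatched species are reported and dropped.
Regressions run trait-on-counts; the direction is a documented choice,
as correlation-style summaries (`r_signed`) are direction-symmetric in
magnitude.

**Per-family tables.** `pearson_by_family()` and `pgls_by_family()`
produce one row per gene family plus a `total` (row-sum) column.
Families with constant copy number have no defined correlation and are
reported as missing with a reason, never as r = 0. Significance stars
follow the 0.05 / 0.01 / 0.005 convention without multiple-testing
correction, matching how such figures are usually annotated; a
Benjamini–Hochberg column is emitted alongside for users who want it.

## 3. Orthogroup expression and TPM

Counts arrive as HTSeq-style two-column files (summary rows starting
with `__` are set aside); orthogroup membership as an OrthoFinder-style
`Orthogroups.tsv`. Per orthogroup and sample the member counts are
summed; per orthogroup and species the member gene lengths are summed
(`aggregate_orthogroups()`). TPM divides each orthogroup's count/length
rate by the sample's total rate and scales by 10⁶, so each sample's TPM
sums to one million over the orthogroups included in its normalisation
(`compute_tpm()`).

Choices worth knowing:

* *Gene length* defaults to the annotated gene span (`end − start + 1`);
  exon-union length is available (`lengths_from_gff(..., "exon_union")`).
* Orthogroups with no members in a species are *excluded* from that
  species' normalisation (and get `NA` TPM) rather than being given a
  pseudo-length.
* Fractional counts (fractional multi-mapper assignment upstream) are
  accepted as nonnegative reals with a warning.
* Between-species comparisons (`compare_to_reference()`) use Welch
  two-sided t tests on `log2(TPM + 1)` against a designated reference
  species, with the log2 fold change of pseudocounted mean TPM. The test
  choice mirrors the two-sided t tests used for the accompanying
  physiological assays; no variance shrinkage across orthogroups is
  attempted — this is deliberately plain TPM comparison, not a
  dispersion-modelled differential-expression method.

## 4. Promoters and degenerate motifs

Putative promoters are the flat 1 kb immediately upstream of the coding
sequence (anchor feature selectable: CDS by default, gene or mRNA by
flag), strand-aware: minus-strand promoters are the reverse complement
of the kilobase 3' of the gene's end. Neighbouring genes are *not*
trimmed out of the window, and windows shortened by a contig edge carry a
`truncated` flag. Coordinates are GFF3 1-based inclusive at every
interface.

Motifs are written in IUPAC codes with run-length shorthand
(`"CGGN{11}CCG"`, 17 bp). Scanning (`count_sites()`) reports all —
possibly overlapping — offsets where each base lies in the motif's
allowed set; `N` in the *sequence* never matches, which is the
conservative reading for assembly gaps. The default Gal4p consensus is
its own reverse complement (`is_self_reverse_complement()` asserts
this), so forward-only scanning already finds every site; `strands =
"both"` exists for non-palindromic motifs and de-duplicates hits by
genomic window. When a species has several family members, the family
summary takes the member with the *most* sites (`summarize_by_family()`),
matching the convention of visualising the strongest candidate ortholog.

`ablate_sites()` emulates binding-site mutagenesis: within each matched
window it substitutes bases only at the motif's non-degenerate positions
(the CGG/CCG anchors), choosing replacements — deterministically from a
seed — that break the match on both strands, one edit per hit first and
escalating across the motif's fixed runs only if rescanning still finds
matches. Typical cost is one edit per site; the procedure errors if ten
rounds do not reach zero matches.

## 5. What the synthetic data emulate — and what they do not

Each generator draws from a named substream of the root seed, so adding
one never perturbs another, and identical configurations give
byte-identical output files.

* `simulate_plate()`: linear pH trajectories from pH 6.8, inverted
  through a standard curve of slope 1 pH per absorbance unit (A560
  0.1–1.1 across pH 6.5–7.5, the dynamic range typical of 0.002% phenol
  red in a microplate), plus Gaussian absorbance noise of sd 0.005.
  Default strains reproduce the screen's two headline phenotypes: a
  rapid acidifier at ECAR −0.032 pH/h and a low-ECAR strain at
  +0.022 pH/h, three replicates each. Real traces are only piecewise
  linear (lag, substrate exhaustion) and real noise has drift; recovery
  tests on these data therefore validate the estimator, not the
  linearity assumption itself.
* `simulate_tree_trait_counts()`: a pure-birth tree rescaled to depth 1
  (so σ² is the tip variance), Poisson copy numbers whose mean doubles
  in one clade of 20–60% of the tips — giving the *predictor*
  phylogenetic signal, without which PGLS and OLS would be
  indistinguishable — and a trait `β·total + BM noise` with β = −0.005
  pH/h per copy and σ² = 4×10⁻⁴ (tip sd 0.02 pH/h), effect and noise
  scales chosen to resemble the measured ECAR range (≈ −0.03…+0.03).
* `simulate_expression()`: four species in two groups (two rapid, two
  low, four replicates each, mirroring the focal *Saturnispora* design),
  1–3 member genes per orthogroup per species with lengths uniform on
  500–5000 bp. Expected gene counts are proportional to gene length
  times an orthogroup expression level θ (reads/kb, log-normal), the
  standard RNA-seq generative model, under which orthogroup TPM
  estimates θ and a no-fold-change experiment is genuinely null.
  Designated orthogroups carry a 4× fold change on θ (rapid up);
  negative-binomial dispersion defaults to 0.1. Because TPM is
  compositional, the planted 4× appears at the TPM scale divided by the
  renormalisation factor; recovery tests score against that expectation
  computed from the recorded truth.
* `simulate_genome_with_motifs()`: uniform-background contigs, genes on
  alternating strands each with a dedicated upstream kilobase carrying a
  recorded number of non-overlapping implanted consensus instances. The
  G-free background option makes spurious CGG/CCG-anchored matches
  impossible, so recovered counts must equal implanted counts exactly;
  in a uniform background the expected spurious rate is 4⁻⁶ per
  position (six fixed bases), about 0.24 expected sites per kilobase.
  These genomes have none of the compositional structure (GC skew,
  repeats) of real yeast genomes; they validate coordinate arithmetic
  and scanning, not biological site density.

## 6. Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at desk scale: 100 random
16-taxon trees for the GLS oracle comparison; 400 null and 200
effect replicates on 128-tip trees for calibration and coverage; 10
expression experiments of 60 orthogroups for TPM conservation and
fold-change detection; 1000 random kilobases for the motif-scan oracle;
50 random mini-genomes for extraction. These sizes give binomial error
bars comfortably inside the asserted bands while keeping a full run in
the low minutes on one core.

## 7. Known limitations

* PGLS is simple regression (one predictor) under Brownian motion with
  optional λ; Ornstein–Uhlenbeck models, multivariate responses and
  measurement-error models are out of scope.
* ECAR fitting is linear; sigmoidal calibration or biphasic trace models
  are not provided.
* TPM comparison does not borrow variance information across
  orthogroups; with few replicates its power is modest and its p values
  are only as good as the Welch approximation at n = 4.
* The motif scanner is an exact-consensus counter by design — no
  position-weight matrices, no conservation filtering.
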