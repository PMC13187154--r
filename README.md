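# yeastferm

Comparative analysis of aerobic fermentation (Crabtree/Warburg-like
phenotypes) across yeast species.

Aerobic fermentation — fermenting sugar even when oxygen is available —
has evolved repeatedly in budding yeasts. A cheap, high-throughput proxy
for glycolytic rate is the glucose-dependent **extracellular acidification
rate (ECAR)**: actively glycolysing cells extrude protons, so the medium's
pH drops, and a phenol-red indicator read at 560 nm in a plate reader
tracks that drop. `yeastferm` implements the complete computational
pipeline around such a screen:

1. **ECAR quantification** (`ecar_from_plate()`): absorbance kinetics are
   converted to pH through an OLS standard curve fitted over the
   phenol-red linear range (pH 6.5–7.5), acidification slopes are fitted
   by OLS over the 90-minute window, and ECAR is the paired difference
   `slope(2% dextrose well) − slope(water-control well)` in pH/h,
   averaged over biological replicates. Rapid acidifiers have *negative*
   ECAR.
2. **Phylogenetic comparative analysis** (`pgls()`, `pearson_by_family()`,
   `pgls_by_family()`): gene-family copy numbers (e.g. glycolytic gene
   counts) are correlated with ECAR across species, both by plain Pearson
   correlation and by phylogenetic generalized least squares. PGLS fits
   `y = b0 + b1 x + e` with `e ~ N(0, s2 * C_l)`, where `C[i, j]` is the
   branch length shared by tips *i* and *j* from the root under Brownian
   motion and `C_l` is Pagel's lambda transformation (off-diagonals
   scaled by `l`; `l = 1` by default, `"ml"` supported). The fit is exact
   GLS through a Cholesky factorisation; slope inference uses a t
   statistic on `n − 2` degrees of freedom.
3. **Cross-species orthogroup expression** (`aggregate_orthogroups()`,
   `compute_tpm()`, `compare_to_reference()`): HTSeq-style per-gene counts
   are summed over OrthoFinder orthogroups, gene lengths are summed per
   species, `TPM(og) = (count/length) / sum(count/length) * 1e6` per
   sample, and each species is compared to a reference species by Welch
   t tests on `log2(TPM + 1)`.
4. **Promoter motif scanning** (`extract_promoters()`, `count_sites()`,
   `ablate_sites()`): 1 kb windows upstream of coding sequences are
   extracted strand-aware from FASTA + GFF3, and exact matches to an
   IUPAC degenerate consensus — by default the Gal4p-binding site
   CGG-N₁₁-CCG, which is its own reverse complement — are counted,
   summarised per gene family (max over in-paralogs), or ablated by
   minimal targeted substitutions.
5. **Synthetic data** (`simulate_plate()`, `simulate_tree_trait_counts()`,
   `simulate_expression()`, `simulate_genome_with_motifs()`): seeded
   generators with recorded ground truth for every stage, so the whole
   pipeline runs and is testable without external downloads.

## Worked example

```r
library(yeastferm)

## plate assay: 2 strains x 3 replicates, true ECAR -0.032 and +0.022 pH/h
sim  <- simulate_plate(seed = 1)
ecar <- ecar_from_plate(sim$plate, sim$layout, sim$calibration)
ecar
#> ECAR analysis: 6 replicate measurements, 2 species
#>       strain   mean_ecar     sd_ecar n low_n
#> 1   low_ecar  0.01947341 0.004745048 3 FALSE
#> 2 rapid_ecar -0.03233179 0.001704547 3 FALSE

## copy number vs trait, corrected for phylogeny (true slope -0.005)
cg  <- simulate_tree_trait_counts(seed = 1, n_taxa = 32)
d   <- merge(cg$trait, cg$counts)
fit <- pgls(mean_ecar ~ total, d, cg$tree)
summary(fit)
#> PGLS regression under Brownian-motion covariance
#> Call:  pgls(formula = mean_ecar ~ total, data = d, tree = cg$tree)
#>
#>               Estimate Std. Error t value Pr(>|t|)
#> (Intercept) -0.0234735  0.0123068  -1.907   0.0661 .
#> total       -0.0051645  0.0002247 -22.979   <2e-16 ***
#>
#> n = 32, residual df = 30, lambda = 1
#> R-squared = 0.9462 (r_signed = -0.9727), sigma2 = 0.0004905, logLik = 95.883

## Gal4p-binding sites in a promoter fragment
count_sites(paste0("TATA", "CGG", strrep("A", 11), "CCG", "GCGC"),
            "CGGN{11}CCG")
#> 1 match(es) of CGGNNNNNNNNNNNCCG (forward strand) at 0-based offsets: 4
```

The recovered mean ECAR of the rapid strain (−0.0323 pH/h) sits within
the assay noise of the simulated truth (−0.032 pH/h); the PGLS slope
estimate (−0.00516 ± 0.00022) covers the simulated effect of −0.005 pH/h
per gene copy; the scanner reports the single implanted consensus site at
its offset.

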