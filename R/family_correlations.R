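#' Significance stars at the 0.05 / 0.01 / 0.005 thresholds
#'
#' @param p numeric vector of p values.
#' @return character vector: `"***"` for p < 0.005, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, otherwise `""` (`NA` propagates).
#' @export
significance_stars <- function(p) {
  out <- ifelse(p < 0.005, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
  out[is.na(p)] <- NA_character_
  out
}

# Align a trait table and a copy-number table on normalised species names.
# Returns list(trait = named numeric, counts = numeric matrix, species).
.align_trait_counts <- function(trait, counts, subset = NULL) {
  if (is.numeric(trait) && !is.null(names(trait)))
    trait <- data.frame(species = names(trait), mean_ecar = unname(trait))
  if (!"species" %in% names(trait))
    stopf("trait table needs a 'species' column")
  tv_col <- setdiff(names(trait), "species")[1L]

  if (is.null(counts$species)) {
    if (is.null(rownames(counts))) stopf("counts table needs species labels")
    counts <- data.frame(species = rownames(counts), counts,
                         check.names = FALSE)
  }
  fam_cols <- names(counts)[vapply(counts, is.numeric, TRUE)]
  if (!length(fam_cols)) stopf("counts table has no numeric family columns")

  kt <- normalize_species(trait$species)
  kc <- normalize_species(counts$species)
  shared <- intersect(kt, kc)
  if (!is.null(subset)) shared <- intersect(shared, normalize_species(subset))
  if (length(shared) < 3L)
    stopf("fewer than 3 species shared between trait and counts tables")
  ti <- match(shared, kt); ci <- match(shared, kc)
  m <- as.matrix(counts[ci, fam_cols, drop = FALSE])
  rownames(m) <- counts$species[ci]
  if ((dropped <- length(kt) - length(intersect(kt, kc))) > 0)
    message(dropped, " trait species absent from the counts table were dropped")
  list(trait = stats::setNames(as.numeric(trait[[tv_col]][ti]),
                               counts$species[ci]),
       counts = m,
       species = counts$species[ci])
}

# Add the row-sum 'total' column unless the caller already supplies one.
.with_total <- function(m, total_column) {
  if (total_column && !"total" %in% colnames(m))
    m <- cbind(m, total = rowSums(m))
  m
}

#' Pearson correlation of each gene family's copy number with a trait
#'
#' Computes, for every gene-family column of the copy-number table (plus a
#' `total` row-sum column), the Pearson correlation with the species trait
#' and its two-sided p value from the t transform.  Families with constant
#' copy number across the analysed species have no defined correlation and
#' are reported as missing with a reason, never as r = 0.  No
#' multiple-testing correction is applied to the stars (which follow the
#' 0.05/0.01/0.005 convention); a Benjamini-Hochberg column is appended for
#' reference.
#'
#' @param trait data frame with columns `species` and a numeric trait
#'   (e.g. `mean_ecar`), or a named numeric vector.
#' @param counts data frame of per-species gene-family copy numbers:
#'   a `species` column (or row names) plus one numeric column per family.
#' @param subset optional character vector restricting the analysis to a
#'   species subset (e.g. one taxonomic order).
#' @param total_column add the row-sum `total` family? (default `TRUE`)
#' @return data frame with columns `family`, `n`, `r`, `p_value`, `stars`,
#'   `p_adj`, `note`.
#' @export
pearson_by_family <- function(trait, counts, subset = NULL,
                              total_column = TRUE) {
  al <- .align_trait_counts(trait, counts, subset)
  m <- .with_total(al$counts, total_column)
  rows <- lapply(colnames(m), function(fam) {
    x <- m[, fam]; y <- al$trait
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      return(data.frame(family = fam, n = length(x), r = NA_real_,
                        p_value = NA_real_, note = "fewer than 3 species"))
    if (var(x) == 0 || var(y) == 0)
      return(data.frame(family = fam, n = length(x), r = NA_real_,
                        p_value = NA_real_, note = "zero variance"))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(family = fam, n = length(x), r = unname(ct$estimate),
               p_value = ct$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  if (any(out$note != ""))
    message("families without a defined correlation: ",
            paste(out$family[out$note != ""], collapse = ", "))
  out$stars <- significance_stars(out$p_value)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("family", "n", "r", "p_value", "stars", "p_adj", "note")]
}

#' Phylogenetically corrected correlation of each gene family with a trait
#'
#' Runs [pgls_fit()] of the trait on each family's copy number (plus the
#' `total` column) under the Brownian-motion covariance of the supplied
#' tree.  Families whose fit fails (e.g. constant copy number) are reported
#' with missing statistics and the failure reason, not dropped silently.
#'
#' @inheritParams pearson_by_family
#' @param tree rooted `phylo` with branch lengths; pruned per family to the
#'   species with complete data.
#' @param lambda fixed Pagel's lambda in `[0, 1]` or `"ml"`.
#' @return data frame with columns `family`, `n`, `beta`, `se`, `t`, `df`,
#'   `p_value`, `r_signed`, `lambda`, `stars`, `p_adj`, `note`.
#' @export
pgls_by_family <- function(trait, counts, tree, lambda = 1, subset = NULL,
                           total_column = TRUE) {
  al <- .align_trait_counts(trait, counts, subset)
  m <- .with_total(al$counts, total_column)
  rows <- lapply(colnames(m), function(fam) {
    x <- m[, fam]; y <- al$trait
    ok <- is.finite(x) & is.finite(y)
    na_row <- function(note, n = sum(ok))
      data.frame(family = fam, n = n, beta = NA_real_, se = NA_real_,
                 t = NA_real_, df = NA_integer_, p_value = NA_real_,
                 r_signed = NA_real_, lambda = NA_real_, note = note)
    if (sum(ok) < 4L) return(na_row("fewer than 4 species"))
    if (var(x[ok]) == 0) return(na_row("zero variance"))
    fit <- tryCatch({
      tr <- prune_to_overlap(tree, names(y)[ok])
      idx <- match(normalize_species(tr$tip.label),
                   normalize_species(names(y)))
      C <- bm_covariance(tr)
      dimnames(C) <- list(names(y)[idx], names(y)[idx])
      pgls_fit(y[idx], x[idx], C, lambda = lambda)
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) return(na_row(fit))
    data.frame(family = fam, n = fit$n, beta = fit$beta, se = fit$se,
               t = fit$t_stat, df = fit$df, p_value = fit$p_value,
               r_signed = fit$r_signed, lambda = fit$lambda, note = "")
  })
  out <- do.call(rbind, rows)
  if (any(out$note != ""))
    message("families that could not be fitted: ",
            paste(out$family[out$note != ""], collapse = ", "))
  out$stars <- significance_stars(out$p_value)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("family", "n", "beta", "se", "t", "df", "p_value", "r_signed",
          "lambda", "stars", "p_adj", "note")]
}
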