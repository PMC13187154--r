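#' Pagel's lambda transformation of a Brownian-motion covariance
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal untouched: `lambda = 1` is pure Brownian motion, `lambda = 0`
#' a star phylogeny (independent tips with their original tip variances).
#'
#' @param C covariance matrix from [bm_covariance()].
#' @param lambda value in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            lambda >= 0, lambda <= 1)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Cholesky of C_lambda with a helpful error when it is singular, e.g. two
# tips joined by zero-length branches (identical covariance rows).
.chol_or_fail <- function(Cl) {
  tryCatch(chol(Cl), error = function(e) {
    r <- round(Cl, 12)
    dup <- rownames(Cl)[duplicated(r) | duplicated(r, fromLast = TRUE)]
    if (length(dup))
      stopf("covariance matrix is singular; taxa with identical phylogenetic positions (zero-length branches?): %s",
            paste(dup, collapse = ", "))
    stopf("covariance matrix is not positive definite: %s", conditionMessage(e))
  })
}

# GLS solve via the Cholesky factor (no explicit inverse).  U is upper
# triangular with Cl = t(U) %*% U; whitening is backsolve with transpose.
.gls_core <- function(y, X, U) {
  z  <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  A  <- crossprod(Xw)
  beta <- solve(A, crossprod(Xw, z))
  e  <- y - drop(X %*% beta)
  ew <- backsolve(U, e, transpose = TRUE)
  list(beta = drop(beta), rss = sum(ew^2), A = A, resid = e,
       logdet = 2 * sum(log(diag(U))))
}

# Profile ML log-likelihood of lambda (sigma2 profiled out analytically).
.pgls_loglik <- function(y, X, C, lambda) {
  U <- .chol_or_fail(lambda_transform(C, lambda))
  f <- .gls_core(y, X, U)
  n <- length(y)
  s2 <- f$rss / n
  -0.5 * (n * log(2 * pi * s2) + f$logdet + n)
}

#' Phylogenetic generalized least squares: low-level fit
#'
#' Fits the simple regression `y = b0 + b1 * x + e`, `e ~ N(0, s2 * C_l)`,
#' where `C_l` is the Brownian-motion covariance with off-diagonals scaled
#' by Pagel's lambda.  Estimation is exact GLS through a Cholesky
#' factorisation of `C_l` (no explicit matrix inverse); the slope's
#' standard error, t statistic and two-sided p value use `n - 2` degrees of
#' freedom; `r_signed` is the signed square root of the GLS R-squared
#' against the intercept-only GLS fit.  With `lambda = "ml"`, the lambda
#' profile likelihood is evaluated on a 0.01 grid over `[0, 1]` and refined
#' by golden-section search around the grid optimum.
#'
#' @param y,x numeric vectors of trait and predictor; if named, they are
#'   aligned to `rownames(C)`.
#' @param C covariance matrix from [bm_covariance()] (or any symmetric
#'   positive-definite matrix; the identity reduces the fit to OLS).
#' @param lambda fixed value in `[0, 1]` (default 1, pure Brownian motion)
#'   or `"ml"` for maximum-likelihood estimation.
#' @return object of class `pgls`; see [pgls()] for the fields.
#' @export
#' @examples
#' C <- diag(8); dimnames(C) <- list(letters[1:8], letters[1:8])
#' x <- rnorm(8); y <- 2 * x + rnorm(8)
#' pgls_fit(y, x, C)$beta   # identical to lm(y ~ x) on a star phylogeny
pgls_fit <- function(y, x, C, lambda = 1) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  nm <- rownames(C)
  if (!is.null(nm)) {
    if (!is.null(names(y))) {
      if (!all(nm %in% names(y))) stopf("y names do not cover the taxa of C")
      y <- y[nm]
    }
    if (!is.null(names(x))) {
      if (!all(nm %in% names(x))) stopf("x names do not cover the taxa of C")
      x <- x[nm]
    }
  }
  y <- as.numeric(unlist(y)); x <- as.numeric(unlist(x))
  n <- length(y)
  if (n != nrow(C) || length(x) != n)
    stopf("y (%d), x (%d) and C (%d) disagree in size", n, length(x), nrow(C))
  if (n < 4L) stopf("PGLS needs at least 4 taxa, got %d", n)
  if (anyNA(y) || anyNA(x)) stopf("y and x must be complete")
  X <- cbind("(Intercept)" = 1, x = x)

  if (identical(lambda, "ml")) {
    grid <- seq(0, 1, by = 0.01)
    ll <- vapply(grid, function(l) .pgls_loglik(y, X, C, l), 0)
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    lambda <- if (lo == hi) lo else
      stats::optimize(function(l) .pgls_loglik(y, X, C, l),
                      c(lo, hi), maximum = TRUE, tol = 1e-6)$maximum
    # the boundary can still beat the interior refinement
    for (b in c(0, 1))
      if (.pgls_loglik(y, X, C, b) > .pgls_loglik(y, X, C, lambda)) lambda <- b
  }

  Cl <- lambda_transform(C, lambda)
  U <- .chol_or_fail(Cl)
  f <- .gls_core(y, X, U)
  f0 <- .gls_core(y, matrix(1, n, 1L), U)
  cn <- colnames(X)
  names(f$beta) <- cn
  df <- n - 2L
  sigma2 <- f$rss / df
  vcov <- sigma2 * solve(f$A)
  dimnames(vcov) <- list(cn, cn)
  se <- sqrt(diag(vcov))
  tval <- f$beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  r2 <- if (f0$rss > 0) 1 - f$rss / f0$rss else NA_real_
  r_signed <- if (is.na(r2)) NA_real_ else
    unname(sign(f$beta[2L])) * sqrt(max(min(r2, 1), 0))
  ll <- -0.5 * (n * log(2 * pi * f$rss / n) + f$logdet + n)

  structure(list(
    coefficients = f$beta,
    beta = unname(f$beta[2L]),
    se = unname(se[2L]),
    se_all = se,
    t_stat = unname(tval[2L]),
    t_all = tval,
    df = df,
    p_value = unname(pval[2L]),
    p_all = pval,
    r_squared = r2,
    r_signed = r_signed,
    lambda = lambda,
    sigma2 = sigma2,
    vcov = vcov,
    loglik = ll,
    residuals = stats::setNames(f$resid, nm),
    fitted.values = stats::setNames(drop(X %*% f$beta), nm),
    y = stats::setNames(y, nm), x = stats::setNames(x, nm),
    chol = U,
    n = n, taxa = nm,
    xname = "x", yname = "y",
    call = match.call()),
    class = "pgls")
}

#' Phylogenetic generalized least squares regression
#'
#' Formula interface to [pgls_fit()]: regresses a species trait (such as
#' the extracellular acidification rate) on a single predictor (such as a
#' glycolytic gene-family copy number) while modelling the error covariance
#' as proportional to the shared-branch-length matrix of the phylogeny
#' under Brownian motion, optionally scaled by Pagel's lambda.
#'
#' Species are matched between `data` and the tree by [normalize_species()]
#' folding; the tree is pruned to the overlap and rows with missing values
#' are dropped (with their tips).
#'
#' @param formula a two-sided formula with exactly one predictor,
#'   e.g. `mean_ecar ~ total`.
#' @param data data frame holding the variables, with species in the
#'   column named by `species` or in the row names.
#' @param tree a rooted `phylo` with branch lengths.
#' @param lambda fixed value in `[0, 1]` or `"ml"`.
#' @param species name of the species column of `data`
#'   (default: `"species"` if present, otherwise row names).
#' @return an object of class `pgls` with components `coefficients`,
#'   `beta`/`se`/`t_stat`/`df`/`p_value` (for the predictor), `r_signed`,
#'   `r_squared`, `lambda`, `sigma2`, `loglik`, `residuals`,
#'   `fitted.values`, `n`, `taxa`, and the pruned `tree`.  Supports
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `logLik`, `simulate` and `plot`.
#' @export
#' @examples
#' sim <- simulate_tree_trait_counts(seed = 1, n_taxa = 24)
#' d <- merge(sim$trait, sim$counts)
#' fit <- pgls(mean_ecar ~ total, d, sim$tree)
#' summary(fit)
pgls <- function(formula, data, tree, lambda = 1, species = NULL) {
  sp <- if (!is.null(species)) data[[species]]
        else if ("species" %in% names(data)) data$species
        else rownames(data)
  if (is.null(sp)) stopf("cannot find species labels in 'data'")
  sp <- as.character(sp)
  if (anyDuplicated(normalize_species(sp)))
    stopf("duplicated species in 'data'")

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  if (ncol(mf) != 2L)
    stopf("pgls() supports exactly one predictor, got %d", ncol(mf) - 1L)
  yv <- stats::setNames(as.numeric(stats::model.response(mf)), sp)
  xv <- stats::setNames(as.numeric(mf[[2L]]), sp)
  ok <- is.finite(yv) & is.finite(xv)

  tr <- prune_to_overlap(tree, sp[ok])
  key <- normalize_species(sp)
  idx <- match(normalize_species(tr$tip.label), key)
  C <- bm_covariance(tr)
  dimnames(C) <- list(sp[idx], sp[idx])

  fit <- pgls_fit(yv[sp[idx]], xv[sp[idx]], C, lambda = lambda)
  fit$call <- match.call()
  fit$formula <- formula
  fit$tree <- tr
  fit$yname <- as.character(formula[[2L]])
  fit$xname <- colnames(mf)[2L]
  for (fld in c("coefficients", "se_all", "t_all", "p_all"))
    names(fit[[fld]])[2L] <- fit$xname
  dimnames(fit$vcov) <- list(names(fit$coefficients),
                             names(fit$coefficients))
  fit
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic generalized least squares (Brownian motion)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("n = %d taxa, lambda = %.4g\n", x$n, x$lambda))
  print(round(x$coefficients, 6))
  cat(sprintf("slope: beta = %.6g, se = %.3g, t(%d) = %.3f, p = %.4g\n",
              x$beta, x$se, x$df, x$t_stat, x$p_value))
  cat(sprintf("r_signed = %.4f\n", x$r_signed))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se_all,
               `t value` = object$t_all,
               `Pr(>|t|)` = object$p_all)
  structure(list(call = object$call, coefficients = tab, df = object$df,
                 lambda = object$lambda, r_squared = object$r_squared,
                 r_signed = object$r_signed, sigma2 = object$sigma2,
                 loglik = object$loglik, n = object$n),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("PGLS regression under Brownian-motion covariance\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nn = %d, residual df = %d, lambda = %.4g\n",
              x$n, x$df, x$lambda))
  cat(sprintf("R-squared = %.4f (r_signed = %.4f), sigma2 = %.4g, logLik = %.3f\n",
              x$r_squared, x$r_signed, x$sigma2, x$loglik))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
logLik.pgls <- function(object, ...)
  structure(object$loglik, df = 3, nobs = object$n, class = "logLik")

#' @export
#' @rdname pgls
#' @param object,... method arguments.
#' @param type residual scale: `"response"` (raw) or `"normalized"`
#'   (whitened by the Cholesky factor of the fitted covariance, i.i.d.
#'   under the model).
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  e <- object$residuals
  if (type == "normalized")
    e <- stats::setNames(drop(backsolve(object$chol, e, transpose = TRUE)),
                         names(e))
  e
}

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- if (is.data.frame(newdata)) {
    if (!object$xname %in% names(newdata))
      stopf("newdata lacks column '%s'", object$xname)
    newdata[[object$xname]]
  } else as.numeric(newdata)
  drop(cbind(1, x) %*% object$coefficients)
}

#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  out <- as.data.frame(vapply(seq_len(nsim), function(i) {
    object$fitted.values +
      sqrt(object$sigma2) * drop(t(object$chol) %*% rnorm(n))
  }, numeric(n)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$taxa
  out
}

#' @export
plot.pgls <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xname, ylab = x$yname,
                 main = sprintf("PGLS (lambda = %.2f)", x$lambda), ...)
  graphics::abline(x$coefficients[1L], x$coefficients[2L], col = "firebrick")
  invisible(x)
}
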