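test_that("PGLS with identity covariance reproduces OLS exactly", {
  set.seed(61)
  n <- 12
  x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
  C <- diag(n); dimnames(C) <- list(letters[1:n], letters[1:n])
  fit <- pgls_fit(setNames(y, letters[1:n]), setNames(x, letters[1:n]), C)
  ols <- lm(y ~ x)
  so <- summary(ols)$coefficients
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$se, so["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(fit$p_value, so["x", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("a perfectly collinear trait gives signed correlation +-1", {
  set.seed(62)
  tr <- ape::rphylo(10, 1, 0)
  C <- bm_covariance(tr)
  x <- rnorm(10)
  up <- pgls_fit(2 + 3 * x, x, C)
  dn <- pgls_fit(2 - 3 * x, x, C)
  expect_equal(up$r_signed, 1, tolerance = 1e-8)
  expect_equal(dn$r_signed, -1, tolerance = 1e-8)
  expect_lt(sum(abs(up$residuals)), 1e-8)
})

test_that("PGLS agrees with the explicit-inversion GLS oracle", {
  set.seed(63)
  for (i in 1:20) {
    tr <- ape::rphylo(16, 1, 0)
    C <- bm_covariance(tr)
    x <- rnorm(16)
    y <- 0.5 - 0.3 * x + drop(t(chol(C)) %*% rnorm(16)) * 0.5
    fit <- pgls_fit(y, x, C)
    ref <- gls_oracle(y, x, C)
    expect_equal(unname(fit$coefficients), unname(ref$beta), tolerance = 1e-8)
    expect_equal(unname(fit$se_all), unname(ref$se), tolerance = 1e-8)
  }
})

test_that("lambda = 0 reduces PGLS to tip-variance weighted OLS", {
  set.seed(64)
  tr <- ape::rphylo(14, 1, 0)
  C <- bm_covariance(tr)
  x <- rnorm(14); y <- 1 + x + rnorm(14)
  fit <- pgls_fit(y, x, C, lambda = 0)
  w <- lm(y ~ x, weights = 1 / diag(C))
  expect_equal(unname(fit$coefficients), unname(coef(w)), tolerance = 1e-10)
  expect_equal(unname(fit$se_all),
               unname(summary(w)$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
})

test_that("PGLS matches nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(65)
  tr <- ape::rphylo(18, 1, 0)
  C <- bm_covariance(tr)
  x <- setNames(rnorm(18), tr$tip.label)
  y <- setNames(0.2 + 0.7 * x + drop(t(chol(C)) %*% rnorm(18)), tr$tip.label)
  fit <- pgls_fit(y, x, C)
  d <- data.frame(y = y, x = x, sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(phy = tr, form = ~sp))
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  # rphylo trees are ultrametric, so the BM correlation is C/depth and the
  # REML standard errors coincide with the df-based GLS ones
  expect_equal(fit$se, unname(sqrt(diag(g$varBeta))[2]), tolerance = 1e-6)
})

test_that("formula interface prunes, matches names, and equals the core fit", {
  sim <- simulate_tree_trait_counts(seed = 66, n_taxa = 20)
  d <- merge(sim$trait, sim$counts)
  fit <- pgls(mean_ecar ~ total, d, sim$tree)
  C <- bm_covariance(sim$tree)
  ref <- pgls_fit(setNames(d$mean_ecar, d$species)[rownames(C)],
                  setNames(d$total, d$species)[rownames(C)], C)
  expect_equal(fit$beta, ref$beta, tolerance = 1e-12)
  expect_equal(fit$p_value, ref$p_value, tolerance = 1e-12)
  # dropping tips not in the data equals fitting a pre-pruned tree
  d8 <- d[1:8, ]
  pre <- prune_to_overlap(sim$tree, d8$species)
  expect_equal(pgls(mean_ecar ~ total, d8, sim$tree)$beta,
               pgls(mean_ecar ~ total, d8, pre)$beta, tolerance = 1e-12)
})

test_that("ML lambda lies in [0,1] and beats both boundary fits", {
  sim <- simulate_tree_trait_counts(seed = 67, n_taxa = 40, sigma2 = 1e-3)
  d <- merge(sim$trait, sim$counts)
  fit <- pgls(mean_ecar ~ total, d, sim$tree, lambda = "ml")
  expect_gte(fit$lambda, 0); expect_lte(fit$lambda, 1)
  l0 <- pgls(mean_ecar ~ total, d, sim$tree, lambda = 0)$loglik
  l1 <- pgls(mean_ecar ~ total, d, sim$tree, lambda = 1)$loglik
  expect_gte(fit$loglik, max(l0, l1) - 1e-8)
})

test_that("duplicated zero-length tips are reported as singular", {
  tr <- read_newick("((A:0,B:0):1,C:1);")
  C <- bm_covariance(tr)
  y <- setNames(rnorm(3), rownames(C)); x <- setNames(rnorm(3), rownames(C))
  expect_error(pgls_fit(c(y, D = 1), c(x, D = 1),
                        rbind(cbind(C, D = 0), D = c(0, 0, 0, 1))),
               "singular|positive definite|identical")
  expect_error(pgls_fit(y, x, C), "at least 4")
})

test_that("pgls methods are mutually consistent", {
  sim <- simulate_tree_trait_counts(seed = 68, n_taxa = 16)
  d <- merge(sim$trait, sim$counts)
  fit <- pgls(mean_ecar ~ total, d, sim$tree)
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(unname(predict(fit, data.frame(total = c(0, 10)))),
               unname(fit$coefficients[1] + fit$coefficients[2] * c(0, 10)))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  s <- summary(fit)
  expect_equal(unname(s$coefficients[2, "Pr(>|t|)"]), fit$p_value)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3L))
  expect_output(print(fit), "Phylogenetic generalized least squares")
})

test_that("simulated responses reproduce the fitted covariance", {
  sim <- simulate_tree_trait_counts(seed = 69, n_taxa = 12, sigma2 = 1e-3)
  d <- merge(sim$trait, sim$counts)
  fit <- pgls(mean_ecar ~ total, d, sim$tree)
  sims <- as.matrix(simulate(fit, nsim = 2000, seed = 2))
  S <- cov(t(sims))
  target <- fit$sigma2 * crossprod(fit$chol)
  expect_lt(norm(S - target, "F") / norm(target, "F"), 0.1)
})
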