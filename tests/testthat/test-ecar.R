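tm31 <- seq(0, 90, by = 3)

test_that("acidification slope handles flat, linear and noisy series", {
  expect_equal(acidification_slope(rep(7, 31), tm31)$slope, 0)
  expect_equal(acidification_slope(rep(7, 31), tm31)$r_squared, 1)
  # 0.001 pH/min decline is -0.06 pH/h
  expect_equal(acidification_slope(7 - 0.001 * tm31, tm31)$slope, -0.06)
  set.seed(21)
  ph <- 7 - 0.0005 * tm31 + rnorm(31, 0, 0.01)
  ref <- ols_oracle(tm31 / 60, ph)
  expect_equal(acidification_slope(ph, tm31)$slope, ref[2], tolerance = 1e-10)
})

test_that("slope fitting rejects underdetermined input and honours windows", {
  expect_error(acidification_slope(c(7, 7.1), c(0, 3)), "at least 3")
  expect_error(acidification_slope(c(7, 7, 7), c(5, 5, 5)), "zero variance")
  # non-finite pairs are dropped pairwise before fitting
  ph <- 7 - 0.001 * tm31; ph[c(4, 9)] <- NA
  expect_equal(acidification_slope(ph, tm31)$n, 29)
  expect_equal(acidification_slope(ph, tm31)$slope, -0.06)
  # sub-window restriction
  ph2 <- ifelse(tm31 <= 45, 7 - 0.001 * tm31, 7 - 0.045)
  expect_equal(acidification_slope(ph2, tm31, window = c(0, 45))$slope, -0.06)
})

test_that("slope estimator is affine-equivariant", {
  set.seed(22)
  for (i in 1:10) {
    ph <- 7 + cumsum(rnorm(31, 0, 0.01))
    s0 <- acidification_slope(ph, tm31)$slope
    expect_equal(acidification_slope(ph + 0.37, tm31)$slope, s0,
                 tolerance = 1e-10)
    k <- runif(1, 0.5, 3)
    expect_equal(acidification_slope(ph, tm31 * k)$slope, s0 / k,
                 tolerance = 1e-10)
  }
})

test_that("ECAR is the carbon minus control slope and identical wells cancel", {
  curve <- fit_standard_curve(data.frame(ph = c(6.5, 7.5), a560 = c(0.5, 1.0)))
  mk <- function(cond, slope) data.frame(
    well = "X", strain = "s1", condition = cond, replicate = 1L,
    time_min = tm31, a560 = ((6.8 + slope * tm31 / 60) - 5.5) / 2)
  r <- dextrose_dependent_ecar(mk("carbon", -0.05), mk("control", -0.01), curve)
  expect_equal(r$ecar, -0.04, tolerance = 1e-12)
  expect_equal(r$ecar, r$slope_carbon - r$slope_control)
  same <- dextrose_dependent_ecar(mk("carbon", -0.02),
                                  within(mk("control", -0.02), well <- "Y"),
                                  curve)
  expect_equal(same$ecar, 0, tolerance = 1e-12)
})

test_that("shared pH drift added to both wells leaves ECAR unchanged", {
  set.seed(23)
  ph_c <- 6.8 - 0.04 * tm31 / 60 + rnorm(31, 0, 0.01)
  ph_0 <- 6.8 - 0.01 * tm31 / 60 + rnorm(31, 0, 0.01)
  drift <- 0.05 * sin(tm31 / 20) + 0.002 * tm31
  ecar <- function(a, b)
    acidification_slope(a, tm31)$slope - acidification_slope(b, tm31)$slope
  expect_equal(ecar(ph_c + drift, ph_0 + drift), ecar(ph_c, ph_0),
               tolerance = 1e-10)
})

test_that("mismatched carbon/control pairing is an error", {
  curve <- fit_standard_curve(data.frame(ph = c(6.5, 7.5), a560 = c(0.5, 1.0)))
  a <- data.frame(well = "A1", strain = "s1", condition = "carbon",
                  replicate = 1L, time_min = tm31, a560 = 0.7)
  b <- data.frame(well = "A2", strain = "s2", condition = "control",
                  replicate = 1L, time_min = tm31, a560 = 0.7)
  expect_error(dextrose_dependent_ecar(a, b, curve), "not a pair")
  expect_error(dextrose_dependent_ecar(b, a, curve), "carbon/control")
})

test_that("replicate aggregation matches a two-pass oracle", {
  r3 <- data.frame(strain = "s", ecar = c(-0.03, -0.03, -0.03))
  agg <- aggregate_replicates(r3, min_n = 3)
  expect_equal(agg$mean_ecar, -0.03)
  expect_equal(agg$sd_ecar, 0)
  expect_equal(agg$n, 3L)
  expect_equal(aggregate_replicates(
    data.frame(strain = "s", ecar = c(-0.02, -0.04)))$mean_ecar, -0.03)
  set.seed(24)
  v <- rnorm(50, -0.02, 0.01)
  agg50 <- aggregate_replicates(data.frame(strain = "s", ecar = v))
  expect_equal(agg50$mean_ecar, sum(v) / 50, tolerance = 1e-12)
  expect_equal(agg50$sd_ecar,
               sqrt(sum((v - sum(v) / 50)^2) / 49), tolerance = 1e-12)
  expect_error(aggregate_replicates(data.frame()), "no ECAR")
})

test_that("wide and long plate dialects parse to the same table", {
  sim <- simulate_plate(seed = 31, n_replicates = 1)
  long_file <- tempfile(fileext = ".csv")
  write.csv(sim$plate, long_file, row.names = FALSE, quote = FALSE)
  wide <- reshape(sim$plate, idvar = "well", timevar = "time_min",
                  direction = "wide")
  names(wide) <- sub("^a560\\.", "", names(wide))
  wide_file <- tempfile(fileext = ".csv")
  write.csv(wide, wide_file, row.names = FALSE, quote = FALSE)
  a <- read_plate(long_file); b <- read_plate(wide_file)
  a <- a[order(a$well, a$time_min), ]; b <- b[order(b$well, b$time_min), ]
  expect_equal(a$a560, b$a560, tolerance = 1e-12)
})

test_that("full plate analysis recovers simulated ECAR within +-0.005 pH/h", {
  sim <- simulate_plate(seed = 41)  # 3 replicates, noise sd 0.005
  an <- ecar_from_plate(sim$plate, sim$layout, sim$calibration)
  truth <- setNames(sim$truth$strains$ecar, sim$truth$strains$strain)
  for (s in names(truth)) {
    est <- an$traits$mean_ecar[an$traits$strain == s]
    expect_lt(abs(est - truth[[s]]), 0.005)
  }
})

test_that("unpaired wells are reported and skipped, not used", {
  sim <- simulate_plate(seed = 42, n_replicates = 2)
  layout <- sim$layout[!(sim$layout$strain == "low_ecar" &
                           sim$layout$replicate == 2 &
                           sim$layout$condition == "control"), ]
  expect_message(
    an <- ecar_from_plate(sim$plate, layout, sim$calibration),
    "unpaired")
  expect_equal(nrow(an$results), 3L)
  expect_equal(an$traits$n[an$traits$strain == "low_ecar"], 1L)
  expect_true(an$traits$low_n[an$traits$strain == "low_ecar"])
})
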