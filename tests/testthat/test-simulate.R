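test_that("simulate_standardized is deterministic and leaves the RNG alone", {
  m <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  a <- simulate_standardized(m, 200, seed = 11)
  b <- simulate_standardized(m, 200, seed = 11)
  expect_identical(a, b)
  expect_equal(attr(a, "seed"), 11L)
  # ambient RNG stream is restored
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_standardized(m, 10, 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a zero-coefficient model yields uncorrelated columns", {
  m <- parse_path_model(c("x -> y = 0", "z -> y = 0", "x ~~ z = 0"))
  m$exog_var[] <- 1; m$resid_var[] <- 1
  d <- simulate_standardized(m, 10000, seed = 4)
  C <- cor(as.matrix(d[m$variables]))
  expect_lt(max(abs(C[upper.tri(C)])), 3 / sqrt(10000))
})

test_that("sample correlations converge to the implied correlation matrix", {
  m <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  mm <- streamsem:::model_matrices(m)
  Sigma <- implied_covariance(mm$B, mm$Psi) # oracle: the population truth
  d <- simulate_standardized(m, 100000, seed = 8)
  C <- cor(as.matrix(d[m$variables]))
  expect_lt(max(abs(C - Sigma[m$variables, m$variables])), 3 / sqrt(100000))
})

test_that("simulate_standardized contract errors", {
  m <- lu_wq_bmi_model("refined", fixed = FALSE)
  expect_error(simulate_standardized(m, 10, 1), "unset")
  m2 <- parse_path_model(c("a -> y = .5", "b -> y = .5", "a ~~ b = 1.5"))
  m2$exog_var[] <- 1; m2$resid_var[] <- 0.5
  expect_error(simulate_standardized(m2, 10, 1), "positive definite")
})

test_that("to_raw_scale hits target marginals", {
  tg <- default_marginals()
  z <- data.frame(bod = 0, bmi = 0)
  raw <- to_raw_scale(z, tg)
  # affine variable: z = 0 -> the target mean
  expect_equal(raw$bmi, 66.71)
  # lognormal moment matching: large-sample mean/SD within 2% of target
  m <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  big <- to_raw_scale(simulate_standardized(m, 60000, seed = 5), tg)
  expect_equal(mean(big$bod), 1.81, tolerance = 0.02)
  expect_equal(sd(big$bod), 1.05, tolerance = 0.04)
  expect_equal(mean(big$tn), 3.85, tolerance = 0.02)
  # bmi is clamped into [0, 100], never resampled
  z2 <- data.frame(bmi = c(3, -4))
  raw2 <- suppressMessages(to_raw_scale(z2, tg))
  expect_equal(raw2$bmi, c(100, 0))
  bad <- tg; bad$sd[bad$variable == "bod"] <- 0
  expect_error(to_raw_scale(z, bad), "sd must be positive")
})

test_that("raw tables put back through preprocessing recover the implied correlations", {
  m <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  mm <- streamsem:::model_matrices(m)
  Sigma <- implied_covariance(mm$B, mm$Psi)
  raw <- simulate_sites(n = 40000, seed = 13)
  logged <- as.data.frame(lapply(raw[m$variables], log_transform))
  C <- cor(as.matrix(logged))
  # the lognormal map is monotone exp of an affine map, so logging
  # restores the Gaussian scale exactly (up to bmi, affine + clamped)
  offdiag <- abs(C - Sigma[m$variables, m$variables])
  expect_lt(max(offdiag[setdiff(m$variables, "bmi"),
                        setdiff(m$variables, "bmi")]), 0.02)
  expect_lt(max(offdiag), 0.05) # bmi rows: log of a clamped affine map
})

test_that("simulate_taxa hits the target BMI exactly", {
  for (target in c(0, 12.5, 50, 66.71, 94.7, 100)) {
    tab <- simulate_taxa(target, richness = 10, seed = 3)
    expect_equal(compute_bmi(tab), target, tolerance = 1e-6)
    expect_true(all(tab$h > 0 & tab$q > 0 & tab$s >= 0 & tab$s <= 4))
  }
  # richness 2 reduces to a two-stratum hand case
  t2 <- simulate_taxa(50, richness = 2, seed = 7)
  expect_equal(compute_bmi(t2), 50, tolerance = 1e-9)
  expect_identical(simulate_taxa(70, 8, 2), simulate_taxa(70, 8, 2))
  expect_error(simulate_taxa(101, 5, 1), "\\[0, 100\\]")
  expect_error(simulate_taxa(50, 1, 1), "richness")
})
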