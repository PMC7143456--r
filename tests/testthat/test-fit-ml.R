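test_that("a single free path on a correlation matrix recovers r exactly", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("X", "Y"),
                                                    c("X", "Y")))
  fit <- fit_ml(parse_path_model("X -> Y"), sample_moments(S, 50))
  expect_equal(unname(fit$estimates["X -> Y"]), 0.4, tolerance = 1e-8)
  expect_equal(fit$chi_square, 0, tolerance = 1e-10)
  expect_equal(fit$df, 0)
  # saturated model: TLI/AGFI/RMSEA are n/a, not 0 or 1
  idx <- fit_indices(fit)
  expect_true(is.na(idx$tli) && is.na(idx$rmsea) && is.na(idx$agfi))
})

test_that("just-identified ML equals equationwise least squares (oracle)", {
  for (seed in 1:30) {
    p <- sample(3:5, 1)
    S <- random_pd(p, seed)
    model <- random_just_identified(p, seed)
    fit <- fit_ml(model, sample_moments(S, 200))
    ols <- oracle_ols(model, S)
    expect_equal(fit$estimates[names(ols)], ols, tolerance = 1e-6)
    expect_equal(fit$chi_square, 0, tolerance = 1e-6)
  }
})

test_that("self-consistency: fitting a model to its own implied matrix", {
  mom <- refined_population_moments()
  fit <- fit_ml(lu_wq_bmi_model("refined", fixed = FALSE), mom)
  expect_true(fit$converged)
  expect_lt(fit$chi_square, 1e-6)
  truth <- lu_wq_bmi_coefficients()
  expect_equal(fit$standardized[names(truth)], truth, tolerance = 1e-4)
  # implied matrix reproduces the input
  expect_equal(fit$implied[rownames(mom$S), rownames(mom$S)], mom$S,
               tolerance = 1e-6)
})

test_that("standardized estimates are invariant to rescaling observed variables", {
  mom <- refined_population_moments()
  scl <- c(urban = 4.58, agri = 14.26, bod = 1.05, tn = 1.88, tp = 0.07,
           bmi = 18.82) # realistic raw-scale SDs
  D <- diag(scl[mom$names]); dimnames(D) <- list(mom$names, mom$names)
  S_cov <- D %*% mom$S %*% D; dimnames(S_cov) <- dimnames(D)
  model <- lu_wq_bmi_model("refined", fixed = FALSE)
  f_cor <- fit_ml(model, mom)
  f_cov <- fit_ml(model, sample_moments(S_cov, mom$n))
  expect_equal(f_cov$standardized, f_cor$standardized, tolerance = 1e-6)
})

test_that("critical ratios are estimate/SE with two-sided normal p", {
  m <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  d <- simulate_standardized(m, 111, 42)
  mom <- sample_moments(cor(as.matrix(d[m$variables])), 111)
  fit <- fit_ml(lu_wq_bmi_model("refined", fixed = FALSE), mom)
  expect_true(fit$converged)
  expect_equal(unname(fit$cr), unname(fit$estimates / fit$se))
  expect_equal(unname(fit$p_value), unname(2 * pnorm(-abs(fit$cr))))
  expect_true(all(is.finite(fit$se)))
})

test_that("fit_ml rejects a non-PD sample matrix and unknown variables", {
  S <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(c("X", "Y"),
                                                    c("X", "Y")))
  expect_error(sample_moments(S, 50), "positive definite")
  mom <- refined_population_moments()
  expect_error(fit_ml(parse_path_model("urban -> nitrate"), mom),
               "nitrate")
})

test_that("parameter recovery at the study's sample size (scaled down)", {
  # 60 replicates at n = 111 (the acceptance suite runs the full 500):
  # mean estimate within 3 Monte-Carlo SEs of truth for every path
  gen <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  model <- lu_wq_bmi_model("refined", fixed = FALSE)
  truth <- lu_wq_bmi_coefficients()
  R <- 60
  est <- matrix(NA_real_, R, length(truth),
                dimnames = list(NULL, names(truth)))
  for (r in 1:R) {
    d <- simulate_standardized(gen, 111, 5000 + r)
    mom <- sample_moments(cor(as.matrix(d[gen$variables])), 111)
    fit <- fit_ml(model, mom)
    est[r, ] <- fit$standardized[names(truth)]
  }
  mc_se <- apply(est, 2, sd) / sqrt(R)
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se))
})
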