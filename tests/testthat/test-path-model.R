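test_that("parse_path_model reads the line grammar", {
  m <- parse_path_model("U -> Y")
  expect_s3_class(m, "path_model")
  expect_equal(m$endogenous, "Y")
  expect_false(m$edges$fixed)
  m2 <- parse_path_model(c("# a comment", "A -> B = 0.5", "A ~~ C = 0.1",
                           "C -> B"))
  expect_equal(m2$variables, c("A", "B", "C")) # first-appearance order
  expect_equal(m2$edges$value[1], 0.5)
  expect_equal(nrow(m2$covs), 1)
})

test_that("parse errors carry line numbers", {
  expect_error(parse_path_model(c("A -> B", "B -> B")), "line 2.*self-loop")
  expect_error(parse_path_model(c("A -> B", "A -> B")), "line 2.*duplicate")
  expect_error(parse_path_model("A -+ B"), "line 1")
})

test_that("free-parameter counting matches the hypothesized and refined models", {
  # full hypothesis: 11 paths + 2 exog variances + 1 covariance +
  # 4 residual variances = 18 free parameters, df = 21 - 18 = 3
  init <- lu_wq_bmi_model("initial")
  expect_equal(validate_path_model(init)$n_free, 18)
  expect_equal(model_df(init), 3)
  # refined free-coefficient version: 8 paths -> 15 free, df = 6
  ref <- lu_wq_bmi_model("refined", fixed = FALSE)
  expect_equal(model_df(ref), 6)
  # saturated 3-variable chain + direct path is just-identified
  sat <- parse_path_model(c("X -> M", "M -> Y", "X -> Y"))
  expect_equal(model_df(sat), 0)
})

test_that("validate_path_model rejects cycles and under-identification", {
  expect_error(parse_path_model(c("A -> B", "B -> A")), "cycl")
  m <- parse_path_model(c("A -> B", "C -> B"))
  m$covs <- rbind(m$covs, data.frame(from = "A", to = "C", fixed = FALSE,
                                     value = NA_real_))
  # 2 paths + 2 exog var + 1 cov + 1 resid = 6 free on p = 3 -> ok;
  # force under-identification by inflating the covariance list
  m2 <- m
  m2$covs <- rbind(m2$covs, data.frame(from = c("A", "C"), to = c("A", "C"),
                                       fixed = FALSE, value = NA_real_))
  expect_error(validate_path_model(m2), "under-identified")
})

test_that("implied_covariance matches hand algebra", {
  # B = 0 -> Sigma = Psi
  Psi <- diag(c(1, 2)); dimnames(Psi) <- list(c("x", "y"), c("x", "y"))
  B0 <- Psi * 0
  expect_equal(implied_covariance(B0, Psi), Psi)
  # single path X -> Y, beta: Cov = beta, Var(Y) = beta^2 + psi
  beta <- 0.7; psi <- 0.4
  B <- matrix(c(0, beta, 0, 0), 2, dimnames = dimnames(Psi))
  P <- diag(c(1, psi)); dimnames(P) <- dimnames(Psi)
  S <- implied_covariance(B, P)
  expect_equal(S["y", "x"], beta)
  expect_equal(S["y", "y"], beta^2 + psi)
  expect_error(implied_covariance(B, matrix(c(1, .2, .3, 1), 2)),
               "symmetric")
})

test_that("solve_unit_variance_residuals realizes standardized models", {
  # single path beta = 0.5 -> residual 1 - 0.25
  m <- parse_path_model("X -> Y = 0.5")
  m <- solve_unit_variance_residuals(m)
  expect_equal(unname(m$resid_var["Y"]), 0.75)
  # two correlated parents: 1 - (b1^2 + b2^2 + 2 b1 b2 phi)
  m2 <- parse_path_model(c("u -> w = 0.20", "a -> w = 0.53",
                           "u ~~ a = 0.2"))
  m2 <- solve_unit_variance_residuals(m2)
  expect_equal(unname(m2$resid_var["w"]),
               1 - (0.04 + 0.2809 + 2 * 0.20 * 0.53 * 0.2))
  # impossible standardized coefficient
  expect_error(solve_unit_variance_residuals(parse_path_model("X -> Y = 1.2")),
               "inconsistent with unit variance")
})

test_that("unit-variance solve makes the implied matrix a correlation matrix", {
  m <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  mm <- streamsem:::model_matrices(m)
  Sigma <- implied_covariance(mm$B, mm$Psi)
  expect_equal(unname(diag(Sigma)), rep(1, 6), tolerance = 1e-12)
})

test_that("decompose_effects matches the path-tracing oracle", {
  # chain with direct shortcut: indirect X on Y = a*b, total = c + a*b
  a <- 0.6; b <- 0.5; cc <- -0.2
  nm <- c("X", "M", "Y")
  B <- matrix(0, 3, 3, dimnames = list(nm, nm))
  B["M", "X"] <- a; B["Y", "M"] <- b; B["Y", "X"] <- cc
  eff <- decompose_effects(B)
  expect_equal(eff$indirect["Y", "X"], a * b)
  expect_equal(eff$total["Y", "X"], cc + a * b)
  expect_equal(eff$total, eff$direct + eff$indirect)
  # random recursive systems vs exhaustive enumeration, plus the finite
  # Neumann-sum identity total = sum_k B^k
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(3:6, 1)
    B <- matrix(0, p, p, dimnames = list(paste0("v", 1:p), paste0("v", 1:p)))
    B[lower.tri(B)] <- rbinom(p * (p - 1) / 2, 1, 0.6) * runif(p * (p - 1) / 2, -0.8, 0.8)
    eff <- decompose_effects(B)
    expect_equal(eff$total, oracle_total_effects(B), tolerance = 1e-10)
    neumann <- B * 0; Bk <- diag(p)
    for (k in 1:(p - 1)) { Bk <- Bk %*% B; neumann <- neumann + Bk }
    expect_equal(unname(eff$total), unname(neumann), tolerance = 1e-10)
  }
  expect_error(decompose_effects(matrix(c(0, 1, 1, 0), 2)), "cyclic")
})
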