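# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra shortcuts.

# Brute-force BMI: term-by-term evaluation of the weighted-mean formula.
oracle_bmi <- function(s, h, q) {
  num <- 0
  den <- 0
  for (i in seq_along(s)) {
    num <- num + s[i] * h[i] * q[i]
    den <- den + h[i] * q[i]
  }
  (4 - num / den) * 25
}

# Equationwise least-squares (normal equations): the ML solution for a
# just-identified recursive model.
oracle_ols <- function(model, S) {
  out <- list()
  for (v in model$endogenous) {
    pa <- model$edges$from[model$edges$to == v]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
    names(b) <- paste(pa, "->", v)
    out[[v]] <- b
  }
  unlist(unname(out))
}

# Total effects by exhaustive enumeration of directed paths (DFS),
# summing products of coefficients along each path.
oracle_total_effects <- function(B) {
  p <- nrow(B)
  tot <- matrix(0, p, p, dimnames = dimnames(B))
  walk <- function(start, node, prod) {
    for (nxt in seq_len(p)) {
      if (B[nxt, node] != 0) {
        tot[nxt, start] <<- tot[nxt, start] + prod * B[nxt, node]
        walk(start, nxt, prod * B[nxt, node])
      }
    }
  }
  for (s in seq_len(p)) walk(s, s, 1)
  tot
}

# KS distance against N(mu, sigma) by dense-grid search.
oracle_ks_grid <- function(x, mu, sigma, grid_n = 200000) {
  xs <- sort(x)
  n <- length(xs)
  lo <- min(xs) - 4 * sigma
  hi <- max(xs) + 4 * sigma
  g <- seq(lo, hi, length.out = grid_n)
  g <- sort(c(g, xs, xs - 1e-9)) # include jump points from both sides
  Fn <- ecdf(xs)(g)
  Fn_left <- ecdf(xs)(g - 1e-12)
  Phi <- pnorm(g, mu, sigma)
  max(abs(Fn - Phi), abs(Fn_left - Phi))
}

# Random PD covariance matrix with unit-ish scale.
random_pd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p + diag(p) * 0.5
  dimnames(S) <- list(paste0("v", 1:p), paste0("v", 1:p))
  S
}

# Random just-identified recursive model over the variables of S:
# full lower-triangular DAG in a random order, saturated exogenous block.
random_just_identified <- function(p, seed) {
  set.seed(seed + 1000)
  vars <- paste0("v", sample(p))
  lines <- character(0)
  for (j in 2:p) for (i in 1:(j - 1))
    lines <- c(lines, paste(vars[i], "->", vars[j]))
  parse_path_model(lines)
}

# Population moments of the refined reference model (unit variances).
refined_population_moments <- function(n = 111) {
  m <- solve_unit_variance_residuals(lu_wq_bmi_model("refined"))
  mm <- streamsem:::model_matrices(m)
  sample_moments(implied_covariance(mm$B, mm$Psi), n)
}
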