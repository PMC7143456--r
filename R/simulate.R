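#' Simulate standardized site data from a path model
#'
#' Draws `n` sites from the linear-Gaussian system the model describes:
#' exogenous variables come from a zero-mean Gaussian with the model's
#' exogenous covariance block, and each endogenous variable is generated
#' in topological order as the linear combination of its parents plus an
#' independent Gaussian structural error with the model's residual
#' variance. With residual variances from
#' [solve_unit_variance_residuals()] every column has unit population
#' variance, so sample correlations converge to the model-implied
#' correlation matrix. R's Mersenne-Twister generator is used; the same
#' seed always returns the identical table.
#'
#' @param model a fully specified `path_model` (all coefficients,
#'   exogenous moments and residual variances fixed).
#' @param n number of sites.
#' @param seed integer seed.
#' @return data frame with a `site_id` column plus one column per model
#'   variable, `n` rows; the seed is recorded in `attr(, "seed")`.
#' @export
simulate_standardized <- function(model, n, seed) {
  stopifnot(inherits(model, "path_model"), n >= 1)
  mm <- model_matrices(model) # errors on any unset parameter
  exo <- model$exogenous
  Psi_x <- mm$Psi[exo, exo, drop = FALSE]
  ev <- eigen(Psi_x, symmetric = TRUE)
  if (min(ev$values) <= 0) stop("exogenous covariance is not positive definite")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  L <- ev$vectors %*% diag(sqrt(ev$values), length(exo)) %*% t(ev$vectors)
  X <- matrix(stats::rnorm(n * length(exo)), n) %*% L
  colnames(X) <- exo
  dat <- matrix(NA_real_, n, length(model$variables),
                dimnames = list(NULL, model$variables))
  dat[, exo] <- X
  for (v in topological_order(model$variables, model$edges)) {
    if (!v %in% model$endogenous) next
    pa <- model$edges$from[model$edges$to == v]
    dat[, v] <- dat[, pa, drop = FALSE] %*% mm$B[v, pa] +
      stats::rnorm(n, sd = sqrt(model$resid_var[v]))
  }
  out <- data.frame(site_id = sprintf("S%03d", seq_len(n)), dat,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Map standardized site data to raw measurement scales
#'
#' Standardized (z-scale) columns are mapped to the units of the target
#' marginals. Variables flagged lognormal (the right-skewed
#' concentration and percent-cover variables) go through
#' \eqn{\exp(\mu_{log} + \sigma_{log} z)} with the log-scale moments
#' solved by method of moments so the raw mean and SD match the target:
#' \eqn{\sigma_{log}^2 = \log(1 + sd^2/mean^2)},
#' \eqn{\mu_{log} = \log(mean) - \sigma_{log}^2/2}. Other variables are
#' mapped affinely (`mean + sd * z`). The `bmi` column is clamped to
#' \[0, 100\] (clamping, not resampling, preserves seed determinism); any
#' clamping is reported via a message.
#'
#' @param table standardized table from [simulate_standardized()].
#' @param targets marginal targets as in [default_marginals()] (columns
#'   `variable`, `mean`, `sd`, `lognormal`).
#' @return table on raw scales, same shape.
#' @export
to_raw_scale <- function(table, targets = default_marginals()) {
  stopifnot(is.data.frame(table), is.data.frame(targets))
  out <- table
  for (i in seq_len(nrow(targets))) {
    v <- targets$variable[i]
    if (!v %in% names(table)) next
    m <- targets$mean[i]; s <- targets$sd[i]
    if (s <= 0) stop("target sd must be positive for ", v)
    z <- table[[v]]
    if (isTRUE(targets$lognormal[i])) {
      if (m <= 0) stop("lognormal target mean must be positive for ", v)
      s2 <- log(1 + s^2 / m^2)
      out[[v]] <- exp(log(m) - s2 / 2 + sqrt(s2) * z)
    } else {
      out[[v]] <- m + s * z
    }
  }
  if ("bmi" %in% names(out)) {
    n_clamp <- sum(out$bmi < 0 | out$bmi > 100)
    if (n_clamp > 0)
      message(n_clamp, " bmi value(s) clamped to [0, 100]")
    out$bmi <- pmin(pmax(out$bmi, 0), 100)
  }
  out
}

#' Simulate a site-table on raw scales in one call
#'
#' Convenience wrapper: unit-variance residual solve on the refined
#' reference model, standardized simulation, then raw-scale mapping.
#'
#' @param n number of sites (default 111, the size of the monitoring
#'   network the generator emulates).
#' @param seed integer seed.
#' @param model fully specified `path_model`; default the refined
#'   reference model with unit-variance residuals.
#' @param raw map to raw scales (default TRUE).
#' @param targets marginal targets for the raw mapping.
#' @return site data frame.
#' @export
simulate_sites <- function(n = 111, seed = 1,
                           model = solve_unit_variance_residuals(lu_wq_bmi_model("refined")),
                           raw = TRUE, targets = default_marginals()) {
  tab <- simulate_standardized(model, n, seed)
  if (raw) tab <- to_raw_scale(tab, targets) # nolint
  tab
}

#' Simulate a taxa table hitting a target BMI score
#'
#' Constructs an assemblage of `richness` taxa whose [compute_bmi()] score
#' equals `target_bmi` (to ~1e-12). Saprobic values and indicator weights
#' are drawn at random; the score is then forced exactly by rescaling the
#' frequencies of the low-saprobity stratum so the hq-weighted mean
#' saprobic value equals \eqn{4 (1 - target/100)}. The boundary targets 0
#' and 100 are realized by degenerate assemblages with all s = 4 or all
#' s = 0 (the only way under strictly positive weights).
#'
#' @param target_bmi score in \[0, 100\].
#' @param richness number of taxa, >= 2.
#' @param seed integer seed.
#' @return data frame with columns `taxon_id`, `s`, `h`, `q`.
#' @export
simulate_taxa <- function(target_bmi, richness = 10, seed = 1) {
  if (target_bmi < 0 || target_bmi > 100)
    stop("target_bmi must lie in [0, 100]")
  if (richness < 2) stop("richness must be >= 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  m_star <- 4 * (1 - target_bmi / 100) # required weighted mean saprobity
  q <- stats::runif(richness, 0.5, 5)
  h <- stats::rlnorm(richness, meanlog = 2, sdlog = 1)
  if (m_star == 0 || m_star == 4) {
    s <- rep(m_star, richness)
  } else {
    s <- stats::runif(richness, 0, 4)
    # guarantee both strata are populated
    s[1] <- stats::runif(1, 0, m_star)
    s[2] <- stats::runif(1, m_star, 4)
    low <- s < m_star
    w <- h * q
    # scale the low stratum's frequencies so sum w (s - m_star) = 0
    alpha <- -sum(w[!low] * (s[!low] - m_star)) /
      sum(w[low] * (s[low] - m_star))
    h[low] <- h[low] * alpha
  }
  data.frame(taxon_id = sprintf("T%02d", seq_len(richness)),
             s = s, h = h, q = q, stringsAsFactors = FALSE)
}
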