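#' Sample moments container
#'
#' Bundles the analyzed covariance (or correlation) matrix with its sample
#' size. The matrix must be symmetric positive definite and `n > p`.
#'
#' @param S symmetric p x p covariance or correlation matrix with
#'   dimnames naming the variables.
#' @param n sample size used to compute `S`.
#' @return object of class `sample_moments` with fields `S`, `n`, `names`.
#' @export
sample_moments <- function(S, n) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (is.null(rownames(S))) stop("S needs dimnames naming the variables")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("S is not positive definite")
  if (max(ev) / min(ev) > 1e10)
    warning("S is near-singular (condition number > 1e10)")
  if (n <= nrow(S)) stop("need n > p")
  structure(list(S = S, n = as.integer(n), names = rownames(S)),
            class = "sample_moments")
}

# --- free-parameter bookkeeping -------------------------------------------

free_param_table <- function(model) {
  lab <- character(0); kind <- character(0); a <- character(0); b <- character(0)
  e <- model$edges[!model$edges$fixed, , drop = FALSE]
  if (nrow(e)) {
    lab <- c(lab, paste(e$from, "->", e$to))
    kind <- c(kind, rep("path", nrow(e))); a <- c(a, e$from); b <- c(b, e$to)
  }
  ev <- names(model$exog_var)[is.na(model$exog_var)]
  if (length(ev)) {
    lab <- c(lab, paste0("var(", ev, ")"))
    kind <- c(kind, rep("exog_var", length(ev))); a <- c(a, ev); b <- c(b, ev)
  }
  cv <- model$covs[!model$covs$fixed, , drop = FALSE]
  if (nrow(cv)) {
    lab <- c(lab, paste(cv$from, "~~", cv$to))
    kind <- c(kind, rep("exog_cov", nrow(cv))); a <- c(a, cv$from); b <- c(b, cv$to)
  }
  rv <- names(model$resid_var)[is.na(model$resid_var)]
  if (length(rv)) {
    lab <- c(lab, paste0("resid(", rv, ")"))
    kind <- c(kind, rep("resid_var", length(rv))); a <- c(a, rv); b <- c(b, rv)
  }
  data.frame(label = lab, kind = kind, a = a, b = b,
             stringsAsFactors = FALSE)
}

# Materialize (B, Psi) from a parameter vector theta.
theta_to_matrices <- function(model, params, theta) {
  p <- length(model$variables)
  B <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  fx <- model$edges[model$edges$fixed, , drop = FALSE]
  for (i in seq_len(nrow(fx))) B[fx$to[i], fx$from[i]] <- fx$value[i]
  Psi <- matrix(0, p, p, dimnames = dimnames(B))
  diag(Psi)[names(model$exog_var)[!is.na(model$exog_var)]] <-
    model$exog_var[!is.na(model$exog_var)]
  diag(Psi)[names(model$resid_var)[!is.na(model$resid_var)]] <-
    model$resid_var[!is.na(model$resid_var)]
  cf <- model$covs[model$covs$fixed, , drop = FALSE]
  for (i in seq_len(nrow(cf)))
    Psi[cf$from[i], cf$to[i]] <- Psi[cf$to[i], cf$from[i]] <- cf$value[i]
  for (j in seq_len(nrow(params))) {
    k <- params$kind[j]
    if (k == "path") B[params$b[j], params$a[j]] <- theta[j]
    else if (k == "exog_cov")
      Psi[params$a[j], params$b[j]] <- Psi[params$b[j], params$a[j]] <- theta[j]
    else Psi[params$a[j], params$a[j]] <- theta[j]
  }
  list(B = B, Psi = Psi)
}

# Equationwise least-squares starting values (exact ML solution for
# just-identified recursive models, near-solution otherwise).
ls_start <- function(model, S, params) {
  p <- nrow(S)
  theta <- numeric(nrow(params))
  Bhat <- matrix(0, p, p, dimnames = dimnames(S))
  resid <- stats::setNames(numeric(length(model$endogenous)), model$endogenous)
  for (v in model$endogenous) {
    pa <- model$edges$from[model$edges$to == v]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
    Bhat[v, pa] <- b
    resid[v] <- S[v, v] - as.numeric(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
  }
  for (j in seq_len(nrow(params))) {
    theta[j] <- switch(params$kind[j],
      path = Bhat[params$b[j], params$a[j]],
      exog_var = S[params$a[j], params$a[j]],
      exog_cov = S[params$a[j], params$b[j]],
      resid_var = max(resid[params$a[j]], 1e-4 * S[params$a[j], params$a[j]]))
  }
  theta
}

#' Fit a recursive path model by maximum likelihood
#'
#' Minimizes the ML covariance-structure discrepancy
#' \deqn{F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1})
#'   - \log|S| - p}
#' over the model's free parameters (path coefficients, exogenous
#' variances/covariances, residual variances), using a quasi-Newton search
#' started from equationwise least-squares values. The model chi-square is
#' \eqn{(n-1) F_{min}} (switchable to \eqn{n F_{min}}), with
#' \eqn{df = p(p+1)/2 - t}. Standard errors come from the inverse numerical
#' Hessian of \eqn{F} scaled by \eqn{2/(n-1)}; the critical ratio is
#' estimate/SE with a two-sided normal p-value. Standardized path
#' coefficients are computed from the fitted coefficients and the implied
#' variances (so they are invariant to rescaling the observed variables);
#' SEs are reported on the unstandardized parameterization only.
#'
#' @param model a `path_model` (free parameters are estimated, fixed ones
#'   held at their values).
#' @param moments a [sample_moments()] object; variables must cover the
#'   model's variables.
#' @param options list: `n_convention` ("n-1" default, or "n"), `maxit`
#'   (default 500), `reltol` (default 1e-12).
#' @return object of class `fitted_path_model`: `estimates`, `se`, `cr`,
#'   `p_value` (named per free parameter), `standardized` (named per
#'   path), `chi_square`, `df`, `implied` (Sigma(theta-hat)), `F_min`,
#'   `converged`, `iterations`, plus the inputs.
#' @export
fit_ml <- function(model, moments, options = list()) {
  stopifnot(inherits(model, "path_model"), inherits(moments, "sample_moments"))
  opt <- utils::modifyList(
    list(n_convention = "n-1", maxit = 500L, reltol = 1e-12), options)
  if (!all(model$variables %in% moments$names))
    stop("moments do not cover model variables: ",
         paste(setdiff(model$variables, moments$names), collapse = ", "))
  S <- moments$S[model$variables, model$variables, drop = FALSE]
  n <- moments$n
  p <- nrow(S)
  chk <- validate_path_model(model)
  params <- free_param_table(model)
  t_free <- nrow(params)
  df <- p * (p + 1) / 2 - t_free

  logdetS <- determinant(S, logarithm = TRUE)$modulus
  Ip <- diag(p)
  objective <- function(theta) {
    mm <- theta_to_matrices(model, params, theta)
    A <- tryCatch(solve(Ip - mm$B), error = function(e) NULL)
    if (is.null(A)) return(1e10)
    Sigma <- A %*% mm$Psi %*% t(A)
    Sigma <- (Sigma + t(Sigma)) / 2
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e10) # retreat: non-PD implied matrix
    logdet <- 2 * sum(log(diag(R)))
    tr <- sum(diag(chol2inv(R) %*% S))
    as.numeric(logdet + tr - logdetS - p)
  }

  # analytic gradient: dF = tr[ Sigma^-1 (Sigma - S) Sigma^-1 dSigma ],
  # with dSigma assembled per parameter from A = (I - B)^-1
  gradient <- function(theta) {
    mm <- theta_to_matrices(model, params, theta)
    A <- tryCatch(solve(Ip - mm$B), error = function(e) NULL)
    if (is.null(A)) return(numeric(length(theta)))
    Sigma <- A %*% mm$Psi %*% t(A)
    Sigma <- (Sigma + t(Sigma)) / 2
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(numeric(length(theta)))
    Sinv <- chol2inv(R)
    G <- Sinv %*% (Sigma - S) %*% Sinv
    SGA <- Sigma %*% G %*% A      # for path parameters
    AGA <- t(A) %*% G %*% A       # for (co)variance parameters
    vapply(seq_len(nrow(params)), function(j) {
      k <- params$kind[j]
      if (k == "path") 2 * SGA[params$a[j], params$b[j]]
      else if (k == "exog_cov") 2 * AGA[params$a[j], params$b[j]]
      else AGA[params$a[j], params$a[j]]
    }, numeric(1))
  }

  theta0 <- if (t_free) ls_start(model, S, params) else numeric(0)
  if (t_free) {
    fit <- stats::optim(theta0, objective, gr = gradient, method = "BFGS",
                        control = list(maxit = opt$maxit,
                                       reltol = opt$reltol))
    # polish: a second pass from the first solution guards against early
    # termination of BFGS on flat stretches
    fit2 <- stats::optim(fit$par, objective, gr = gradient, method = "BFGS",
                         control = list(maxit = opt$maxit,
                                        reltol = opt$reltol))
    if (fit2$value < fit$value) fit <- fit2
    theta <- fit$par
    F_min <- fit$value
    iterations <- fit$counts[["function"]]
    converged <- fit$convergence == 0
  } else {
    theta <- numeric(0); F_min <- objective(theta)
    iterations <- 0L; converged <- TRUE
  }
  if (!converged)
    warning("ML search did not converge within the iteration cap")

  mm <- theta_to_matrices(model, params, theta)
  implied <- implied_covariance(mm$B, mm$Psi)
  nn <- if (opt$n_convention == "n") n else n - 1
  chi_square <- max(nn * F_min, 0)

  se <- cr <- pval <- rep(NA_real_, t_free)
  if (t_free) {
    H <- stats::optimHess(theta, objective, gr = gradient)
    V <- tryCatch((2 / nn) * solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
      cr <- theta / se
      pval <- 2 * stats::pnorm(-abs(cr))
    } else warning("Hessian singular: standard errors unavailable")
  }

  sds <- sqrt(diag(implied))
  stdB <- mm$B * outer(1 / sds, sds) # beta_std[t,s] = beta * sd(s)/sd(t)
  standardized <- if (nrow(model$edges)) {
    stats::setNames(stdB[cbind(model$edges$to, model$edges$from)],
                    paste(model$edges$from, "->", model$edges$to))
  } else stats::setNames(numeric(0), character(0))

  structure(list(
    model = model, moments = moments, params = params,
    estimates = stats::setNames(theta, params$label),
    se = stats::setNames(se, params$label),
    cr = stats::setNames(cr, params$label),
    p_value = stats::setNames(pval, params$label),
    standardized = standardized,
    B = mm$B, Psi = mm$Psi, implied = implied,
    chi_square = chi_square, df = df, F_min = F_min,
    n = n, converged = converged, iterations = iterations
  ), class = "fitted_path_model")
}

#' @export
print.fitted_path_model <- function(x, digits = 3, ...) {
  cat("ML path-model fit: chi-square =", format(x$chi_square, digits = 5),
      "on", x$df, "df (n =", paste0(x$n, ")"),
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  cat(path_table_text(x), sep = "\n")
  invisible(x)
}

#' Standardized effect decomposition of a fitted model
#'
#' @param fit a `fitted_path_model`.
#' @return list of `direct`, `indirect`, `total` standardized effect
#'   matrices (entry `[t, s]` = effect of `s` on `t`).
#' @export
effects_table <- function(fit) {
  stopifnot(inherits(fit, "fitted_path_model"))
  sds <- sqrt(diag(fit$implied))
  decompose_effects(fit$B * outer(1 / sds, sds))
}
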