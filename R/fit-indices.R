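#' Independence-baseline chi-square
#'
#' The baseline ("lowest performing") model lets every variable keep its
#' own variance but sets all covariances to zero, so its ML discrepancy
#' has the closed form
#' \deqn{F_b = \log|\mathrm{diag}(S)| - \log|S| = -\log|R|,}
#' with `R` the correlation matrix. The baseline chi-square is
#' \eqn{(n-1) F_b} on \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param moments a [sample_moments()] object.
#' @param n_convention "n-1" (default) or "n", matched to [fit_ml()].
#' @return list with `chi_square`, `df`, `F_b`.
#' @export
baseline_chi_square <- function(moments, n_convention = "n-1") {
  stopifnot(inherits(moments, "sample_moments"))
  R <- stats::cov2cor(moments$S)
  F_b <- -as.numeric(determinant(R, logarithm = TRUE)$modulus)
  p <- nrow(R)
  nn <- if (n_convention == "n") moments$n else moments$n - 1
  list(chi_square = max(nn * F_b, 0), df = p * (p - 1) / 2, F_b = F_b)
}

#' Goodness-of-fit indices
#'
#' Computes the six indices used to judge covariance-structure models
#' against the acceptance thresholds NFI/TLI/CFI/GFI/AGFI >= 0.90 and
#' RMSEA <= 0.05 (inclusive comparisons):
#' \itemize{
#'   \item NFI = (chi2_b - chi2) / chi2_b
#'   \item TLI = (chi2_b/df_b - chi2/df) / (chi2_b/df_b - 1); may exceed 1
#'   \item CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0),
#'     defined as 1 when both excesses are <= 0 (clamped to \[0, 1\])
#'   \item GFI = 1 - tr\{(Sigma-hat^-1 S - I)^2\} / tr\{(Sigma-hat^-1 S)^2\}
#'     (the ML-weighted variant)
#'   \item AGFI = 1 - \[p(p+1)/(2 df)\](1 - GFI)
#'   \item RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1))), with the
#'     denominator following the chi-square convention
#' }
#' For a saturated model (df = 0) TLI, AGFI and RMSEA are undefined and
#' reported as `NA` ("n/a"), never as 0 or 1.
#'
#' @param chi_square,df model fit statistics.
#' @param chi_square_baseline,df_baseline independence-model statistics
#'   from [baseline_chi_square()].
#' @param n sample size.
#' @param S sample matrix (needed for GFI/AGFI; may be `NULL` to skip).
#' @param Sigma_hat implied matrix (as `S`).
#' @param n_convention "n-1" (default) or "n" for the RMSEA denominator.
#' @return object of class `fit_index_report`.
#' @export
compute_fit_indices <- function(chi_square, df, chi_square_baseline,
                                df_baseline, n, S = NULL, Sigma_hat = NULL,
                                n_convention = "n-1") {
  if (df_baseline <= 0) stop("degenerate baseline: df_baseline must be > 0")
  if (n <= 1) stop("need n > 1")
  nn <- if (n_convention == "n") n else n - 1

  nfi <- (chi_square_baseline - chi_square) / chi_square_baseline
  excess_m <- chi_square - df
  excess_b <- chi_square_baseline - df_baseline
  denom <- max(excess_b, excess_m, 0)
  cfi <- if (denom <= 0) 1 else 1 - max(excess_m, 0) / denom

  if (df > 0) {
    tli <- (chi_square_baseline / df_baseline - chi_square / df) /
      (chi_square_baseline / df_baseline - 1)
    rmsea <- sqrt(max(excess_m, 0) / (df * nn))
  } else {
    tli <- NA_real_
    rmsea <- NA_real_
  }

  gfi <- agfi <- NA_real_
  if (!is.null(S) && !is.null(Sigma_hat)) {
    p <- nrow(S)
    W <- solve(Sigma_hat, S) # Sigma-hat^-1 S
    M <- W - diag(p)
    gfi <- 1 - sum(M * t(M)) / sum(W * t(W)) # tr(M^2) / tr(W^2)
    if (df > 0) agfi <- 1 - (p * (p + 1) / (2 * df)) * (1 - gfi)
  }

  structure(list(chi_square = chi_square, df = df,
                 chi_square_baseline = chi_square_baseline,
                 df_baseline = df_baseline, n = n,
                 nfi = nfi, tli = tli, cfi = cfi,
                 gfi = gfi, agfi = agfi, rmsea = rmsea),
            class = "fit_index_report")
}

#' Fit indices straight from a fitted model
#' @param fit a `fitted_path_model`.
#' @return a `fit_index_report`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "fitted_path_model"))
  S <- fit$moments$S[fit$model$variables, fit$model$variables, drop = FALSE]
  base <- baseline_chi_square(sample_moments(S, fit$n))
  compute_fit_indices(fit$chi_square, fit$df, base$chi_square, base$df,
                      fit$n, S, fit$implied)
}

#' Evaluate the acceptance criteria
#'
#' Inclusive thresholds: >= 0.90 for NFI, TLI, CFI, GFI and AGFI;
#' <= 0.05 for RMSEA. Indices reported as `NA` (saturated model) are
#' skipped; `suitable` is TRUE when every applicable index passes.
#'
#' @param report a `fit_index_report`.
#' @return list with logical entries per index plus `suitable`.
#' @export
evaluate_criteria <- function(report) {
  stopifnot(inherits(report, "fit_index_report"))
  up <- function(x) if (is.na(x)) NA else x >= 0.90
  res <- list(nfi = up(report$nfi), tli = up(report$tli),
              cfi = up(report$cfi), gfi = up(report$gfi),
              agfi = up(report$agfi),
              rmsea = if (is.na(report$rmsea)) NA else report$rmsea <= 0.05)
  res$suitable <- all(unlist(res), na.rm = TRUE)
  res
}

#' @export
print.fit_index_report <- function(x, ...) {
  cat(fit_index_text(x), sep = "\n")
  invisible(x)
}
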