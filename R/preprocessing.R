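#' Descriptive statistics per variable
#'
#' Min, max, sample mean and sample standard deviation (n - 1 denominator)
#' for every numeric column of a site table; the conventional first look
#' at monitoring data before any transformation.
#'
#' @param table data frame; non-numeric columns other than `site_id` are
#'   rejected with their location.
#' @return data frame with columns `variable`, `n`, `min`, `max`, `mean`,
#'   `sd`, one row per variable, in column order.
#' @export
describe_sites <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("empty table")
  cols <- setdiff(names(table), "site_id")
  rows <- lapply(cols, function(cn) {
    v <- table[[cn]]
    if (!is.numeric(v)) stop("non-numeric column '", cn, "'")
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric/missing cell at row ", bad[1L], ", column '", cn, "'")
    data.frame(variable = cn, n = length(v), min = min(v), max = max(v),
               mean = mean(v), sd = stats::sd(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exact KS distance between the empirical CDF and N(mu, sigma^2),
# evaluated at the order statistics (both one-sided gaps).
ks_distance <- function(x, mu, sigma) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean = mu, sd = sigma)
  i <- seq_len(n)
  max(max(i / n - z), max(z - (i - 1) / n))
}

# Asymptotic Kolmogorov tail probability with Stephens' small-sample
# adjustment of the argument.
kolmogorov_p <- function(D, n) {
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  if (lambda < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# Dallal-Wilkinson (1986) analytic approximation to the Lilliefors
# p-value (parameters estimated from the sample).
lilliefors_p <- function(D, n) {
  nd <- n
  Dd <- D
  if (nd > 100) {
    Dd <- D * (nd / 100)^0.49
    nd <- 100
  }
  p <- exp(-7.01256 * Dd^2 * (nd + 2.78019) +
             2.99587 * Dd * sqrt(nd + 2.78019) -
             0.122119 + 0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    # the exponential form is only calibrated for small p; switch to the
    # polynomial interpolation of the null distribution
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) 1
    else if (KK <= 0.5)
      2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9)
      -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31)
      6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov normality screen
#'
#' Tests a sample against the normal distribution. With
#' `variant = "known"` the hypothesized mean and standard deviation are
#' supplied and the p-value comes from the asymptotic Kolmogorov
#' distribution; with `variant = "estimated"` (the default, appropriate
#' when population moments are unknown) mu and sigma are estimated from
#' the sample and the Lilliefors approximation is used. The statistic
#' \eqn{D = \sup_x |F_n(x) - \Phi((x-\mu)/\sigma)|} is computed exactly at
#' the order statistics in both cases.
#'
#' @param values numeric vector (n >= 1 for "known", n >= 4 for
#'   "estimated").
#' @param variant "estimated" (Lilliefors) or "known".
#' @param mu,sigma hypothesized moments for `variant = "known"` (default
#'   standard normal).
#' @return list with `D`, `p`, `variant`, `n`.
#' @export
ks_normality <- function(values, variant = c("estimated", "known"),
                         mu = 0, sigma = 1) {
  variant <- match.arg(variant)
  x <- values
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (variant == "known") {
    if (n < 1) stop("need n >= 1")
    if (sigma <= 0) stop("sigma must be positive")
    D <- ks_distance(x, mu, sigma)
    p <- kolmogorov_p(D, n)
  } else {
    if (n < 4) stop("need n >= 4 when parameters are estimated")
    s <- stats::sd(x)
    if (s == 0) stop("zero variance: cannot standardize the sample")
    D <- ks_distance(x, mean(x), s)
    p <- lilliefors_p(D, n)
  }
  list(variable = NULL, D = D, p = p, variant = variant, n = n)
}

#' Natural-log transform with a zero-aware offset
#'
#' Skewed water-quality and land-use variables are routinely
#' log-transformed before covariance-structure analysis. Monitoring
#' tables contain exact zeros (e.g. total phosphorus and urban cover
#' minima of 0.00), so a deterministic scale-aware offset is used:
#' \eqn{\epsilon = 0} when all values are positive, otherwise half the
#' smallest positive value in the vector. The natural log is used; the
#' base only rescales covariances and leaves correlations and
#' standardized path coefficients unchanged.
#'
#' @param values numeric vector.
#' @param offset either "auto" (the policy above) or a number added
#'   before taking logs.
#' @return `log(values + offset)`; strictly monotone in the input.
#' @export
log_transform <- function(values, offset = "auto") {
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  eps <- if (identical(offset, "auto")) {
    if (all(values > 0)) 0
    else {
      pos <- values[values > 0]
      if (length(pos) == 0L) stop("no positive values: cannot log-transform")
      min(pos) / 2
    }
  } else as.numeric(offset)
  if (any(values + eps <= 0))
    stop("non-positive values remain after offset ", format(eps))
  log(values + eps)
}
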