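#' Built-in land-use / water-quality / BMI path models
#'
#' Returns the path-model specification text for the two stages of the
#' watershed analysis this package supports out of the box, over the six
#' observed variables `urban`, `agri` (percent land cover, exogenous),
#' `bod`, `tn`, `tp` (mg/L, mediating water quality) and `bmi` (0-100
#' biotic score, outcome):
#' \describe{
#'   \item{"initial"}{the full hypothesis: both land-use variables point
#'     at every water-quality variable and at BMI, and each water-quality
#'     variable points at BMI (11 free paths, df = 3). All coefficients
#'     free.}
#'   \item{"refined"}{the pruned model in which urban -> TN, TN -> BMI and
#'     TP -> BMI are dropped (8 paths, df = 6). Coefficients are fixed at
#'     the reference standardized set (agri -> bod 0.53, agri -> tp 0.43,
#'     agri -> tn 0.35, agri -> bmi -0.23, urban -> bod 0.20,
#'     urban -> tp 0.26, urban -> bmi -0.29, bod -> bmi -0.33) so the
#'     model doubles as a population generator; pass `fixed = FALSE` for a
#'     free-coefficient version suitable for fitting.}
#' }
#' The urban-agri exogenous correlation is not part of the published
#' coefficient set; the generator default is 0.2 (plausible for
#' co-occurring development) and nothing downstream depends on its value.
#'
#' @param stage "initial" or "refined".
#' @param fixed logical; keep the reference coefficients fixed (refined
#'   stage only). Default TRUE.
#' @param exog_cor urban-agri correlation written into the spec when
#'   `fixed = TRUE`; default 0.2.
#' @return a `path_model` (see [parse_path_model()]).
#' @export
lu_wq_bmi_model <- function(stage = c("refined", "initial"),
                            fixed = TRUE, exog_cor = 0.2) {
  stage <- match.arg(stage)
  if (stage == "initial") {
    spec <- c(
      "urban -> bod", "urban -> tn", "urban -> tp", "urban -> bmi",
      "agri  -> bod", "agri  -> tn", "agri  -> tp", "agri  -> bmi",
      "bod -> bmi", "tn -> bmi", "tp -> bmi",
      "urban ~~ agri")
    return(parse_path_model(spec))
  }
  beta <- lu_wq_bmi_coefficients()
  suffix <- if (fixed) paste(" =", format(beta, trim = TRUE)) else ""
  spec <- c(paste0(names(beta), suffix),
            if (fixed) paste("urban ~~ agri =", format(exog_cor))
            else "urban ~~ agri")
  parse_path_model(spec)
}

#' Reference standardized coefficients of the refined model
#'
#' Named numeric vector, names in `from -> to` notation. These are the
#' published standardized path coefficients of the refined watershed
#' model; they serve as the population truth for the synthetic-data
#' generator and for self-consistency checks of the estimator.
#' @return named numeric vector of length 8.
#' @export
lu_wq_bmi_coefficients <- function() {
  c("agri -> bod"  =  0.53,
    "agri -> tp"   =  0.43,
    "agri -> tn"   =  0.35,
    "agri -> bmi"  = -0.23,
    "urban -> bod" =  0.20,
    "urban -> tp"  =  0.26,
    "urban -> bmi" = -0.29,
    "bod -> bmi"   = -0.33)
}

#' Raw-scale marginal targets for the six site variables
#'
#' Mean, SD, minimum and maximum of each variable on its measurement
#' scale, matching the descriptive statistics of the 111-site monitoring
#' dataset the synthetic generator emulates: BOD 0.50-7.60 mg/L (mean
#' 1.81, SD 1.05), TN 0.69-11.20 (3.85, 1.88), TP 0.00-0.39 (0.05, 0.07),
#' urban cover 0.00-21.57 % (5.87, 4.58), agricultural cover
#' 5.68-62.50 % (26.75, 14.26), BMI 22.6-94.7 (66.71, 18.82).
#'
#' @return data frame with columns `variable`, `mean`, `sd`, `min`,
#'   `max`, `lognormal` (whether the raw-scale back-transform is
#'   lognormal rather than affine).
#' @export
default_marginals <- function() {
  data.frame(
    variable  = c("urban", "agri", "bod", "tn", "tp", "bmi"),
    mean      = c(5.87, 26.75, 1.81, 3.85, 0.05, 66.71),
    sd        = c(4.58, 14.26, 1.05, 1.88, 0.07, 18.82),
    min       = c(0.00, 5.68, 0.50, 0.69, 0.00, 22.6),
    max       = c(21.57, 62.50, 7.60, 11.20, 0.39, 94.7),
    lognormal = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}
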