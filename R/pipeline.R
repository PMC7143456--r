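#' Run the full land-use / water-quality / biotic-condition analysis
#'
#' Orchestrates the whole workflow on a site table: descriptive
#' statistics, normality screening, log transformation of configured
#' variables, standardization, ML fit of the hypothesized model,
#' goodness-of-fit indices, critical-ratio pruning, refit with indices,
#' and standardized effect decomposition of the refined model.
#'
#' @param config a list with elements:
#' \describe{
#'   \item{sites}{a site data frame, or path to a CSV with columns
#'     `site_id,urban,agri,bod,tn,tp,bmi` (aliases `urban_pct`,
#'     `agri_pct` accepted). Alternatively supply `simulate`.}
#'   \item{simulate}{list(n, seed) - generate the sites with
#'     [simulate_sites()] instead of reading them.}
#'   \item{taxa}{optional path to a long taxa CSV (or data frame); BMI is
#'     then computed per site with [bmi_per_site()] and overrides/fills
#'     the `bmi` column.}
#'   \item{model}{a `path_model`, spec text, or path to a spec file;
#'     default the initial (full-hypothesis) model.}
#'   \item{log_vars}{variables to log-transform before standardization;
#'     default all six.}
#'   \item{threshold}{critical-ratio pruning cutoff, default 1.96.}
#'   \item{batch}{prune all insignificant paths at once, default FALSE.}
#' }
#' @return object of class `analysis_report` with fields `descriptives`,
#'   `normality`, `initial` (fit + indices + criteria), `prune_log`,
#'   `refined` (fit + indices + criteria), `effects`, `meta`.
#' @export
run_pipeline <- function(config = list()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  cfg <- utils::modifyList(list(
    model = lu_wq_bmi_model("initial"),
    log_vars = c("urban", "agri", "bod", "tn", "tp", "bmi"),
    threshold = 1.96, batch = FALSE), config)

  sites <- stage("load", {
    if (!is.null(cfg$simulate)) {
      sim <- utils::modifyList(list(n = 111, seed = 1), cfg$simulate)
      simulate_sites(n = sim$n, seed = sim$seed)
    } else if (is.data.frame(cfg$sites)) cfg$sites
    else if (is.character(cfg$sites)) read_sites_csv(cfg$sites)
    else stop("config needs 'sites' (data frame or CSV path) or 'simulate'")
  })

  if (!is.null(cfg$taxa)) {
    sites$bmi <- stage("bmi", {
      taxa <- if (is.data.frame(cfg$taxa)) cfg$taxa else read_taxa_csv(cfg$taxa)
      scores <- bmi_per_site(taxa)
      if (!all(sites$site_id %in% names(scores)))
        stop("taxa table lacks site(s): ",
             paste(setdiff(sites$site_id, names(scores)), collapse = ", "))
      unname(scores[sites$site_id])
    })
  }

  model <- stage("model", {
    if (inherits(cfg$model, "path_model")) cfg$model
    else parse_path_model(cfg$model)
  })
  need <- model$variables
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("stage 'load': site table missing column(s): ",
         paste(miss, collapse = ", "))

  descriptives <- stage("describe", describe_sites(sites[c("site_id", need)]))
  normality <- stage("normality", {
    out <- lapply(need, function(v) {
      r <- ks_normality(sites[[v]], variant = "estimated")
      data.frame(variable = v, D = r$D, p = r$p, variant = r$variant,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })

  analyzed <- sites
  for (v in intersect(cfg$log_vars, need))
    analyzed[[v]] <- stage("log_transform", log_transform(analyzed[[v]]))
  Z <- scale(as.matrix(analyzed[need]))
  moments <- stage("moments",
                   sample_moments(stats::cor(Z), n = nrow(Z)))

  initial_fit <- stage("fit_initial", fit_ml(model, moments))
  initial_idx <- fit_indices(initial_fit)
  pr <- stage("prune", prune_model(model, moments,
                                   threshold = cfg$threshold,
                                   batch = cfg$batch))
  refined_idx <- fit_indices(pr$fit)

  structure(list(
    sites = sites,
    descriptives = descriptives,
    normality = normality,
    initial = list(fit = initial_fit, indices = initial_idx,
                   criteria = evaluate_criteria(initial_idx)),
    prune_log = pr$log,
    refined = list(fit = pr$fit, indices = refined_idx,
                   criteria = evaluate_criteria(refined_idx)),
    effects = effects_table(pr$fit),
    meta = list(seed = if (!is.null(cfg$simulate)) cfg$simulate$seed else NA,
                n = nrow(sites), threshold = cfg$threshold,
                log_vars = intersect(cfg$log_vars, need),
                package_version = as.character(utils::packageVersion("streamsem")))
  ), class = "analysis_report")
}

#' Read a site-table CSV
#'
#' Columns `site_id,urban,agri,bod,tn,tp,bmi`; `urban_pct`/`agri_pct`
#' are accepted as aliases and renamed.
#' @param path CSV path.
#' @return site data frame.
#' @export
read_sites_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "urban_pct"] <- "urban"
  names(tab)[names(tab) == "agri_pct"] <- "agri"
  tab
}

#' Write a site-table CSV
#' @param table site data frame.
#' @param path output path.
#' @export
write_sites_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
}
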