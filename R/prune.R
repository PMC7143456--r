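#' Prune insignificant paths by critical ratio
#'
#' Refines a fitted model the way covariance-structure practitioners
#' trim a hypothesis: any structural path whose critical ratio
#' (estimate / SE) falls inside the +/- `threshold` band (1.96 for a
#' 0.05-level screen) is a candidate for removal. By default removal is
#' stepwise - the single path with the smallest |C.R.| is dropped, the
#' model refitted, and the screen repeated - because batch removal can
#' discard paths that regain significance after refitting. `batch = TRUE`
#' removes every insignificant path at once and refits a single time.
#' Only free structural paths are ever removed; variances and exogenous
#' covariances are kept, and a variable left with no incident path stays
#' in the model with a free variance.
#'
#' @param model a `path_model` with free paths.
#' @param moments a [sample_moments()] object.
#' @param threshold critical-ratio cutoff, default 1.96.
#' @param batch remove all insignificant paths at once (default FALSE).
#' @param options passed to [fit_ml()].
#' @return list with `fit` (the final `fitted_path_model`), `model` (the
#'   pruned `path_model`) and `log`, a data frame with one row per
#'   removed path (`removed_path`, `cr_at_removal`, `p_at_removal`,
#'   `refit_chi_square`, `refit_df`).
#' @export
prune_model <- function(model, moments, threshold = 1.96, batch = FALSE,
                        options = list()) {
  log <- data.frame(removed_path = character(0), cr_at_removal = numeric(0),
                    p_at_removal = numeric(0), refit_chi_square = numeric(0),
                    refit_df = numeric(0), stringsAsFactors = FALSE)
  fit <- fit_ml(model, moments, options)
  if (!fit$converged) stop("initial fit did not converge; cannot prune")
  repeat {
    ispath <- fit$params$kind == "path"
    cr <- fit$cr[ispath]
    pv <- fit$p_value[ispath]
    weak <- which(abs(cr) < threshold)
    if (length(weak) == 0L) break
    drop_idx <- if (batch) weak[order(abs(cr[weak]))] else
      weak[which.min(abs(cr[weak]))]
    drop_lab <- names(cr)[drop_idx]
    model <- drop_paths(model, drop_lab)
    new_fit <- fit_ml(model, moments, options)
    if (!new_fit$converged)
      stop("refit after pruning did not converge; partial log:\n",
           paste(log$removed_path, collapse = ", "))
    log <- rbind(log, data.frame(
      removed_path = drop_lab,
      cr_at_removal = unname(cr[drop_idx]),
      p_at_removal = unname(pv[drop_idx]),
      refit_chi_square = new_fit$chi_square,
      refit_df = new_fit$df, stringsAsFactors = FALSE))
    fit <- new_fit
    if (batch) break
  }
  list(fit = fit, model = model, log = log)
}

# Remove free paths given as "from -> to" labels; variables keep their
# (residual) variance parameters even if orphaned.
drop_paths <- function(model, labels) {
  keys <- paste(model$edges$from, "->", model$edges$to)
  idx <- match(labels, keys)
  if (anyNA(idx)) stop("unknown path(s): ", paste(labels[is.na(idx)], collapse = ", "))
  model$edges <- model$edges[-idx, , drop = FALSE]
  endo_now <- unique(model$edges$to)
  newly_exo <- setdiff(model$endogenous, endo_now)
  if (length(newly_exo)) {
    # a variable that lost all incoming paths becomes exogenous with a
    # free variance parameter
    model$endogenous <- setdiff(model$endogenous, newly_exo)
    model$exogenous <- c(model$exogenous, newly_exo)
    model$resid_var <- model$resid_var[setdiff(names(model$resid_var), newly_exo)]
    add <- stats::setNames(rep(NA_real_, length(newly_exo)), newly_exo)
    model$exog_var <- c(model$exog_var, add)
  }
  validate_path_model(model)
  model
}
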