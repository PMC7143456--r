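# Text renderings of the standard report tables. Kept free of any
# plotting dependency: plain fixed-width blocks that drop into a log or
# a manuscript appendix.

fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")

descriptives_text <- function(desc) {
  hdr <- sprintf("%-10s %5s %8s %8s %8s %8s",
                 "variable", "n", "min", "max", "mean", "sd")
  rows <- sprintf("%-10s %5d %8s %8s %8s %8s", desc$variable, desc$n,
                  fmt(desc$min, 2), fmt(desc$max, 2),
                  fmt(desc$mean, 2), fmt(desc$sd, 2))
  c("Descriptive statistics", hdr, rows)
}

fit_index_text <- function(x, refined = NULL) {
  val <- function(v) if (is.na(v)) "n/a" else fmt(v, 3)
  idx <- c("NFI", "TLI", "CFI", "GFI", "AGFI", "RMSEA")
  crit <- c(rep("≥0.90", 5), "≤0.05")
  a <- c(val(x$nfi), val(x$tli), val(x$cfi), val(x$gfi), val(x$agfi),
         val(x$rmsea))
  if (is.null(refined)) {
    c("Model fit indices",
      sprintf("%-6s %-7s %8s", "index", "criteria", "value"),
      sprintf("%-6s %-7s %8s", idx, crit, a))
  } else {
    b <- c(val(refined$nfi), val(refined$tli), val(refined$cfi),
           val(refined$gfi), val(refined$agfi), val(refined$rmsea))
    c("Model fit indices",
      sprintf("%-6s %-7s %10s %10s", "index", "criteria", "initial",
              "refined"),
      sprintf("%-6s %-7s %10s %10s", idx, crit, a, b))
  }
}

path_table_text <- function(fit) {
  ispath <- fit$params$kind == "path"
  lab <- fit$params$label[ispath]
  std <- fit$standardized[lab]
  se <- fit$se[ispath]; cr <- fit$cr[ispath]; pv <- fit$p_value[ispath]
  c("Paths (standardized coefficient, S.E., C.R., p)",
    sprintf("%-16s %8s %8s %8s %8s", "path", "std.coef", "S.E.", "C.R.", "p"),
    sprintf("%-16s %8s %8s %8s %8s", lab, fmt(std, 2), fmt(se, 2),
            fmt(cr, 3), fmt(pmax(pv, 0.001), 3)))
}

effects_text <- function(eff) {
  blocks <- lapply(c("direct", "indirect", "total"), function(k) {
    M <- eff[[k]]
    keep <- abs(M) > 1e-12
    if (!any(keep)) return(character(0))
    ij <- which(keep, arr.ind = TRUE)
    sprintf("  %-8s -> %-8s %8s", colnames(M)[ij[, 2]],
            rownames(M)[ij[, 1]], fmt(M[keep], 3))
  })
  c("Standardized effects",
    "direct:", blocks[[1]], "indirect:", blocks[[2]], "total:", blocks[[3]])
}

#' Render an analysis report as text tables
#'
#' Emits the four standard blocks: descriptive statistics, initial vs
#' refined fit indices, the refined model's path table (standardized
#' coefficient, S.E., C.R., p) and the effect decomposition. If pruning
#' removed nothing, the two index columns are identical.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @return character vector of lines (also printed by the `print`
#'   method).
#' @export
render_tables <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  pl <- if (nrow(report$prune_log)) {
    c("Pruned paths (|C.R.| < threshold):",
      sprintf("  %-16s C.R. %7s  p %6s", report$prune_log$removed_path,
              fmt(report$prune_log$cr_at_removal, 3),
              fmt(report$prune_log$p_at_removal, 3)))
  } else "Pruned paths: none"
  c(descriptives_text(report$descriptives), "",
    fit_index_text(report$initial$indices, report$refined$indices), "",
    pl, "",
    path_table_text(report$refined$fit), "",
    effects_text(report$effects))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Deterministic for a fixed config and seed (no timestamps).
#'
#' @param report an `analysis_report`.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  fit_block <- function(b) list(
    estimates = as.list(b$fit$estimates),
    standardized = as.list(b$fit$standardized),
    se = as.list(b$fit$se), cr = as.list(b$fit$cr),
    p_value = as.list(b$fit$p_value),
    chi_square = b$fit$chi_square, df = b$fit$df,
    converged = b$fit$converged,
    indices = unclass(b$indices), criteria = b$criteria)
  obj <- list(descriptives = report$descriptives,
              normality = report$normality,
              initial = fit_block(report$initial),
              prune_log = report$prune_log,
              refined = fit_block(report$refined),
              effects = lapply(report$effects, function(m)
                as.data.frame(as.table(m), stringsAsFactors = FALSE)),
              meta = report$meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
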