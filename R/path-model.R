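#' Parse a plain-text path-model specification
#'
#' The grammar is line based:
#' \preformatted{
#'   A -> B            # free path coefficient from A to B
#'   A -> B = 0.53     # path fixed at 0.53
#'   A ~~ B            # free covariance between exogenous A and B
#'   A ~~ B = 0.2      # exogenous covariance fixed at 0.2
#'   # comment (also allowed at end of line)
#' }
#' Variable order is first-appearance order. Variables with no incoming
#' path are exogenous; each endogenous variable carries one residual
#' variance parameter (its structural error term), free by default.
#' Exogenous variances are free by default and exogenous pairs without a
#' `~~` line have covariance fixed at zero; residual covariances between
#' structural errors are fixed at zero (independent error terms).
#'
#' @param text character: the specification, as a single string or a
#'   vector of lines. A path to an existing file is also accepted.
#' @return an object of class `path_model`.
#' @examples
#' m <- parse_path_model(c("U -> Y", "X -> Y = 0.5"))
#' m$endogenous  # "Y"
#' @seealso [validate_path_model()], [fit_ml()], [lu_wq_bmi_model()]
#' @export
parse_path_model <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)

  vars <- character(0)
  edges <- data.frame(from = character(0), to = character(0),
                      fixed = logical(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  covs <- edges
  see <- function(v) {
    if (!v %in% vars) vars <<- c(vars, v)
  }
  tok <- "[A-Za-z_.][A-Za-z0-9_.]*"
  re_edge <- paste0("^(", tok, ")\\s*(->|~~)\\s*(", tok,
                    ")\\s*(=\\s*([-+0-9.eE]+))?$")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    m <- regmatches(ln, regexec(re_edge, ln))[[1]]
    if (length(m) == 0L)
      stop("parse error at line ", i, ": cannot read '", ln, "'")
    from <- m[2]; op <- m[3]; to <- m[4]
    val <- if (m[5] == "") NA_real_ else suppressWarnings(as.numeric(m[6]))
    if (m[5] != "" && is.na(val))
      stop("parse error at line ", i, ": bad numeric value in '", ln, "'")
    if (from == to)
      stop("parse error at line ", i, ": self-loop ", from, " -> ", to)
    see(from); see(to)
    row <- data.frame(from = from, to = to, fixed = !is.na(val),
                      value = val, stringsAsFactors = FALSE)
    if (op == "->") {
      if (any(edges$from == from & edges$to == to))
        stop("parse error at line ", i, ": duplicate edge ", from, " -> ", to)
      edges <- rbind(edges, row)
    } else {
      key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
      if (nrow(covs) && key(from, to) %in% mapply(key, covs$from, covs$to))
        stop("parse error at line ", i, ": duplicate covariance ",
             from, " ~~ ", to)
      covs <- rbind(covs, row)
    }
  }
  if (length(vars) == 0L) stop("empty model specification")

  endogenous <- unique(edges$to)
  exogenous <- setdiff(vars, endogenous)
  bad <- covs$from %in% endogenous | covs$to %in% endogenous
  if (any(bad))
    stop("'~~' covariances are only supported among exogenous variables: ",
         paste(unique(c(covs$from[bad], covs$to[bad])), collapse = ", "))

  model <- structure(list(
    variables = vars,
    edges = edges,
    covs = covs,
    exogenous = exogenous,
    endogenous = endogenous,
    # NA = free parameter; a number = fixed
    exog_var = stats::setNames(rep(NA_real_, length(exogenous)), exogenous),
    resid_var = stats::setNames(rep(NA_real_, length(endogenous)), endogenous)
  ), class = "path_model")
  validate_path_model(model)
  model
}

#' Validate a path model
#'
#' Checks acyclicity by topological sort, that the counting rule
#' \eqn{t \le p(p+1)/2} holds (degrees of freedom are non-negative), and
#' that every endogenous variable is reachable from its parents.
#'
#' @param model a `path_model`.
#' @return invisibly, a list with `df`, `n_free`, `order` (a topological
#'   order of the variables). Errors on a cyclic graph (the cycle is
#'   listed) or a model under-identified by the counting rule.
#' @export
validate_path_model <- function(model) {
  stopifnot(inherits(model, "path_model"))
  ord <- topological_order(model$variables, model$edges)
  p <- length(model$variables)
  t_free <- n_free_parameters(model)
  df <- p * (p + 1) / 2 - t_free
  if (df < 0)
    stop("under-identified by counting rule: ", t_free,
         " free parameters > ", p * (p + 1) / 2, " moments")
  invisible(list(df = df, n_free = t_free, order = ord))
}

topological_order <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  for (to in edges$to) indeg[to] <- indeg[to] + 1L
  queue <- vars[indeg == 0L]
  out <- character(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    kids <- edges$to[edges$from == v]
    for (k in kids) {
      indeg2[k] <- indeg2[k] - 1L
      if (indeg2[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < length(vars)) {
    cyc <- setdiff(vars, out)
    stop("model graph is cyclic; cycle involves: ",
         paste(cyc, collapse = " -> "))
  }
  out
}

n_free_parameters <- function(model) {
  nrow(model$edges[!model$edges$fixed, , drop = FALSE]) +
    sum(is.na(model$exog_var)) +
    nrow(model$covs[!model$covs$fixed, , drop = FALSE]) +
    sum(is.na(model$resid_var))
}

#' Model degrees of freedom by the counting rule
#' @param model a `path_model`.
#' @return integer: \eqn{p(p+1)/2 - t} with `t` the free-parameter count.
#' @export
model_df <- function(model) validate_path_model(model)$df

#' @export
print.path_model <- function(x, ...) {
  cat("Recursive path model:", length(x$variables), "variables,",
      nrow(x$edges), "paths, df =", model_df(x), "\n")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n", sep = "")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -> %s%s\n", e$from, e$to,
                if (e$fixed) sprintf(" = %g", e$value) else ""))
  }
  for (i in seq_len(nrow(x$covs))) {
    e <- x$covs[i, ]
    cat(sprintf("  %s ~~ %s%s\n", e$from, e$to,
                if (e$fixed) sprintf(" = %g", e$value) else ""))
  }
  invisible(x)
}

# Build the (B, Psi) matrices from a fully specified model.
# B[to, from] holds the coefficient of the path from -> to.
model_matrices <- function(model) {
  p <- length(model$variables)
  B <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  for (i in seq_len(nrow(model$edges))) {
    e <- model$edges[i, ]
    if (!e$fixed) stop("unset coefficient: ", e$from, " -> ", e$to)
    B[e$to, e$from] <- e$value
  }
  Psi <- matrix(0, p, p, dimnames = dimnames(B))
  if (anyNA(model$exog_var)) stop("unset exogenous variance")
  if (anyNA(model$resid_var)) stop("unset residual variance")
  diag(Psi)[model$exogenous] <- model$exog_var[model$exogenous]
  diag(Psi)[model$endogenous] <- model$resid_var[model$endogenous]
  for (i in seq_len(nrow(model$covs))) {
    e <- model$covs[i, ]
    if (!e$fixed) stop("unset exogenous covariance: ", e$from, " ~~ ", e$to)
    Psi[e$from, e$to] <- Psi[e$to, e$from] <- e$value
  }
  list(B = B, Psi = Psi)
}

#' Model-implied covariance matrix
#'
#' For the recursive structural system \eqn{y = B y + \zeta} with
#' \eqn{\mathrm{Cov}(\zeta) = \Psi} (exogenous variables are their own
#' "error"), the implied covariance is
#' \deqn{\Sigma = (I - B)^{-1} \Psi (I - B)^{-T}.}
#'
#' @param B square coefficient matrix, `B[t, s]` = path s -> t; must be
#'   nilpotent (acyclic system).
#' @param Psi symmetric matrix of exogenous (co)variances and residual
#'   variances.
#' @return the implied covariance matrix, symmetric; positive definite
#'   whenever `Psi` is.
#' @export
implied_covariance <- function(B, Psi) {
  stopifnot(is.matrix(B), is.matrix(Psi), nrow(B) == ncol(B),
            all(dim(B) == dim(Psi)))
  if (max(abs(Psi - t(Psi))) > 1e-8) stop("Psi must be symmetric")
  A <- solve(diag(nrow(B)) - B)
  S <- A %*% Psi %*% t(A)
  (S + t(S)) / 2
}

#' Residual variances realizing a standardized model
#'
#' Given standardized path coefficients (all variables unit variance) and
#' the correlation structure of the exogenous block, solves for the
#' residual variance of each endogenous variable so the implied covariance
#' matrix has unit diagonal: processing endogenous variables in
#' topological order, each residual variance is one minus the variance
#' explained by the variable's parents.
#'
#' @param model a `path_model` whose every path coefficient is fixed
#'   (standardized values) and whose `~~` covariances are fixed
#'   (correlations, since variances are unit).
#' @return the model with `exog_var` set to 1 and `resid_var` filled in;
#'   errors if any implied residual variance is non-positive (the
#'   standardized coefficients are inconsistent with unit variances).
#' @export
solve_unit_variance_residuals <- function(model) {
  stopifnot(inherits(model, "path_model"))
  if (any(!model$edges$fixed))
    stop("all path coefficients must be fixed to standardized values")
  if (any(!model$covs$fixed))
    stop("all exogenous covariances must be fixed")
  model$exog_var[] <- 1
  model$resid_var[] <- 0 # placeholder, overwritten in topological order
  p <- length(model$variables)
  # accumulate Sigma over the topological order; exogenous block first
  mm <- model_matrices(model)
  B <- mm$B
  Psi <- mm$Psi
  ord <- topological_order(model$variables, model$edges)
  Sigma <- Psi # correct for the exogenous block
  for (v in ord) {
    if (!v %in% model$endogenous) next
    pa <- model$edges$from[model$edges$to == v]
    b <- B[v, pa]
    explained <- as.numeric(t(b) %*% Sigma[pa, pa, drop = FALSE] %*% b)
    resid <- 1 - explained
    if (resid <= 0)
      stop("standardized coefficients inconsistent with unit variance: ",
           "residual variance of ", v, " would be ", signif(resid, 4))
    model$resid_var[v] <- resid
    Psi[v, v] <- resid
    # update implied covariances involving v
    Sigma[v, ] <- Sigma[, v] <- as.numeric(B[v, ] %*% Sigma)
    Sigma[v, v] <- explained + resid
  }
  model
}

#' Direct, indirect and total effects
#'
#' Decomposes the influence structure of a recursive system with
#' coefficient matrix `B` (typically standardized):
#' direct = \eqn{B}; total = \eqn{(I-B)^{-1} - I} (the sum of products of
#' coefficients over every directed path); indirect = total - direct.
#'
#' @param B square (standardized) coefficient matrix, `B[t, s]` = path
#'   s -> t; must describe an acyclic system.
#' @return list of matrices `direct`, `indirect`, `total`; entry `[t, s]`
#'   is the effect of `s` on `t`.
#' @export
decompose_effects <- function(B) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  p <- nrow(B)
  # acyclicity check: B nilpotent <=> B^p = 0
  Bk <- B
  for (k in seq_len(p)) Bk <- Bk %*% B
  if (max(abs(Bk)) > 1e-10) stop("coefficient matrix is cyclic")
  total <- solve(diag(p) - B) - diag(p)
  dimnames(total) <- dimnames(B)
  list(direct = B, indirect = total - B, total = total)
}
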