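#' Benthic Macroinvertebrate Index (BMI)
#'
#' Scores a stream-site macroinvertebrate assemblage on the 0--100 saprobic
#' scale. Each taxon carries a unit saprobic value \eqn{s_i \in [0,4]}
#' (0 = intolerant of organic pollution, 4 = highly tolerant), a frequency
#' (abundance) \eqn{h_i > 0} and an indicator weight \eqn{q_i > 0}. The
#' index is
#' \deqn{BMI = \left(4 - \frac{\sum_i s_i h_i q_i}{\sum_i h_i q_i}\right)
#'   \times 25,}
#' i.e. 25 times the distance of the \eqn{h q}-weighted mean saprobic value
#' from its ceiling of 4, so 100 indicates excellent and 0 poor condition.
#'
#' Frequencies and weights are accepted as positive reals (standardized
#' abundances are allowed; counts are not required). Rows sharing a
#' `taxon_id` are treated as repeated field picks of one taxon: their
#' frequencies are summed before scoring and a warning is issued.
#'
#' @param taxa a data frame with columns `s`, `h`, `q` and optionally
#'   `taxon_id` (any additional columns are ignored).
#' @return a single numeric score in \[0, 100\] at full precision; round
#'   only at the reporting layer.
#' @examples
#' compute_bmi(data.frame(s = c(1, 3), h = c(2, 2), q = c(1, 1)))  # 50
#' compute_bmi(data.frame(s = 0, h = 5, q = 2))                    # 100
#' @seealso [bmi_per_site()], [read_taxa_csv()], [simulate_taxa()]
#' @export
compute_bmi <- function(taxa) {
  taxa <- validate_taxa(taxa)
  if ("taxon_id" %in% names(taxa) && anyDuplicated(taxa$taxon_id)) {
    warning("duplicate taxon_id rows: frequencies summed before scoring")
    n_sq <- tapply(paste(taxa$s, taxa$q), taxa$taxon_id,
                   function(x) length(unique(x)))
    if (any(n_sq > 1L))
      stop("duplicate taxon_id rows disagree on s or q")
    h <- as.numeric(tapply(taxa$h, taxa$taxon_id, sum))
    s <- as.numeric(tapply(taxa$s, taxa$taxon_id, function(x) x[1L]))
    q <- as.numeric(tapply(taxa$q, taxa$taxon_id, function(x) x[1L]))
    w <- h * q
  } else {
    w <- taxa$h * taxa$q
    s <- taxa$s
  }
  score <- (4 - sum(s * w) / sum(w)) * 25
  # guard against tiny float excursions outside the closed form's range
  min(max(score, 0), 100)
}

validate_taxa <- function(taxa) {
  if (!is.data.frame(taxa)) stop("taxa must be a data frame")
  if (nrow(taxa) == 0L) stop("no taxa")
  need <- c("s", "h", "q")
  miss <- setdiff(need, names(taxa))
  if (length(miss))
    stop("taxa table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    v <- taxa[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("taxa column '", col, "' must be finite numeric")
  }
  bad_s <- which(taxa$s < 0 | taxa$s > 4)
  if (length(bad_s))
    stop("saprobic value s outside [0,4] in record(s): ",
         paste(row_label(taxa, bad_s), collapse = ", "))
  bad_h <- which(taxa$h <= 0)
  if (length(bad_h))
    stop("frequency h must be > 0 in record(s): ",
         paste(row_label(taxa, bad_h), collapse = ", "))
  bad_q <- which(taxa$q <= 0)
  if (length(bad_q))
    stop("indicator weight q must be > 0 in record(s): ",
         paste(row_label(taxa, bad_q), collapse = ", "))
  taxa
}

row_label <- function(taxa, idx) {
  if ("taxon_id" %in% names(taxa)) as.character(taxa$taxon_id[idx]) else idx
}

#' BMI scores for many sites
#'
#' Applies [compute_bmi()] per site. Sites whose taxa table is empty are
#' reported as missing (`NA`), never as zero; validation failures are
#' re-raised with the site label attached.
#'
#' @param taxa_by_site a named list of taxa data frames, or a single long
#'   data frame with a `site` column that is split first.
#' @return named numeric vector of scores, `NA` for empty sites.
#' @export
bmi_per_site <- function(taxa_by_site) {
  if (is.data.frame(taxa_by_site)) {
    if (!"site" %in% names(taxa_by_site))
      stop("long-format taxa table needs a 'site' column")
    taxa_by_site <- split(taxa_by_site, taxa_by_site$site)
  }
  if (is.null(names(taxa_by_site)) || any(names(taxa_by_site) == ""))
    stop("taxa_by_site must be a named list (one name per site)")
  vapply(names(taxa_by_site), function(site) {
    tab <- taxa_by_site[[site]]
    if (is.null(tab) || nrow(tab) == 0L) return(NA_real_)
    tryCatch(compute_bmi(tab),
             error = function(e) stop("site '", site, "': ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
}

#' Read a long-format taxa CSV
#'
#' Expected columns: `site,taxon,s,h,q` (header required, UTF-8, '.' decimal
#' separator). The `taxon` column is carried through as `taxon_id`.
#'
#' @param path path to the CSV file.
#' @return a data frame with columns `site`, `taxon_id`, `s`, `h`, `q`.
#' @export
read_taxa_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("site", "taxon", "s", "h", "q")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("taxa CSV lacks column(s): ", paste(miss, collapse = ", "))
  data.frame(site = as.character(tab$site),
             taxon_id = as.character(tab$taxon),
             s = as.numeric(tab$s), h = as.numeric(tab$h),
             q = as.numeric(tab$q), stringsAsFactors = FALSE)
}
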