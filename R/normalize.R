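#' Z-score normalization of an indicator table
#'
#' Standardizes every indicator column to mean 0, standard deviation 1
#' (sample sd, denominator N-1) over its non-missing entries:
#' \deqn{Z = (x - \mu) / \sigma.}
#' The per-column mean and sd are recorded in `normalization_params` so the
#' transform is reproducible and new areas can be scored against frozen
#' parameters. Missing entries stay missing. A constant (zero-variance)
#' column signals a data-preparation mistake and errors by default; with
#' `degenerate = "drop"` it is dropped with a warning instead.
#'
#' @param table an [indicator_table()].
#' @param degenerate `"error"` (default) or `"drop"` for zero-variance or
#'   nearly-empty columns.
#' @return an object of class `svi_zscores`: list with `area_ids`, `values`
#'   (standardized matrix), `params` (data frame: indicator_id, mu, sigma,
#'   sd_convention), `aligned` (FALSE), `flipped` (character()).
#' @export
zscore_normalize <- function(table, degenerate = c("error", "drop")) {
  stopifnot(inherits(table, "indicator_table"))
  degenerate <- match.arg(degenerate)
  v <- table$values
  mu <- colMeans(v, na.rm = TRUE)
  sigma <- apply(v, 2, stats::sd, na.rm = TRUE)
  n_obs <- colSums(!is.na(v))
  bad <- n_obs < 2L | is.na(sigma) | sigma == 0
  if (any(bad)) {
    msg <- paste0("degenerate indicator column(s) (constant or <2 observed values): ",
                  paste(colnames(v)[bad], collapse = ", "))
    if (degenerate == "error") svi_stop(msg, "svi_degenerate_error")
    warning(paste0(msg, "; dropped"), call. = FALSE)
    v <- v[, !bad, drop = FALSE]
    mu <- mu[!bad]; sigma <- sigma[!bad]
    if (!ncol(v)) svi_stop("no usable indicator columns remain", "svi_data_error")
  }
  z <- sweep(sweep(v, 2, mu, "-"), 2, sigma, "/")
  structure(
    list(area_ids = table$area_ids, values = z,
         params = data.frame(indicator_id = colnames(v), mu = unname(mu),
                             sigma = unname(sigma), sd_convention = "sample (N-1)",
                             stringsAsFactors = FALSE),
         aligned = FALSE, flipped = character()),
    class = "svi_zscores"
  )
}

#' Direction-align a z-score matrix
#'
#' After standardization, columns whose indicator is declared
#' `vulnerability_reducing` (e.g. tree cover: more greenspace dampens flood
#' or heat impacts) are negated so that larger values consistently mean
#' more vulnerability in every column. Negating z is equivalent to negating
#' the raw values, since the z-score is odd in (x - mu).
#'
#' @param z an `svi_zscores` object.
#' @param cfg the [load_hierarchy()] configuration declaring directions.
#' @return the `svi_zscores` with reducing columns negated, `aligned = TRUE`
#'   and the flipped column ids recorded in `flipped`.
#' @export
align_direction <- function(z, cfg) {
  stopifnot(inherits(z, "svi_zscores"), inherits(cfg, "svi_hierarchy"))
  cols <- colnames(z$values)
  dir <- cfg$indicators$direction[match(cols, cfg$indicators$indicator_id)]
  if (anyNA(dir))
    svi_stop(paste0("no configured direction for column(s): ",
                    paste(cols[is.na(dir)], collapse = ", ")),
             "svi_config_error")
  flip <- dir == "vulnerability_reducing"
  z$values[, flip] <- -z$values[, flip, drop = FALSE]
  z$aligned <- TRUE
  z$flipped <- cols[flip]
  z
}
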