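#' Indicator correlation matrix
#'
#' First step of the Tier 4 route: the pairwise Pearson correlation matrix
#' of the aligned indicator z-scores, used to inspect multicollinearity and
#' as the input of the principal-component decomposition.
#'
#' @param z an aligned `svi_zscores` with at least 2 indicators and 3 areas.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(z) {
  stopifnot(inherits(z, "svi_zscores"))
  v <- z$values
  if (ncol(v) < 2L)
    svi_stop("correlation matrix needs at least 2 indicators", "svi_data_error")
  if (nrow(v) < 3L)
    svi_stop("correlation matrix needs at least 3 areas", "svi_data_error")
  sds <- apply(v, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    svi_stop(paste0("degenerate column(s): ",
                    paste(colnames(v)[!is.finite(sds) | sds == 0], collapse = ", ")),
             "svi_degenerate_error")
  stats::cor(v, use = "pairwise.complete.obs")
}

#' Principal-component decomposition of the indicator correlation matrix
#'
#' Eigendecomposition of the correlation matrix (not the covariance: the
#' columns are already z-scored). Components are ordered by decreasing
#' eigenvalue; the variance proportion of component k is its eigenvalue
#' divided by the number of indicators, so the proportions sum to 1. Each
#' component's sign is arbitrary in the algebra, so retained components are
#' oriented deterministically: flipped so the sum of loadings is
#' non-negative (vulnerability-aligned columns dominate), with the first
#' nonzero loading made positive as tie-break.
#'
#' @param z an aligned `svi_zscores` (missing cells, if any, must have been
#'   handled upstream; component scores require complete rows).
#' @param var_target cumulative variance proportion at which to stop
#'   retaining components (default 0.80).
#' @param retain_all retain every component (the index is then a full
#'   variance-weighted mean).
#' @return object of class `svi_pca`: list with `loadings` (indicator x
#'   component), `variance_proportions`, `component_scores` (area x
#'   component), `retained` (integer indices), `eigenvalues`.
#' @export
pca_decompose <- function(z, var_target = 0.80, retain_all = FALSE) {
  R <- correlation_matrix(z)
  p <- ncol(R)
  eg <- tryCatch(eigen(R, symmetric = TRUE),
                 error = function(e) svi_stop(
                   paste0("eigendecomposition failed: ", conditionMessage(e)),
                   "svi_decomposition_error"))
  vals <- pmax(eg$values, 0)  # clip numerically negative eigenvalues
  vecs <- eg$vectors
  # deterministic sign orientation
  for (k in seq_len(p)) {
    s <- sum(vecs[, k])
    if (abs(s) > 1e-12) {
      if (s < 0) vecs[, k] <- -vecs[, k]
    } else {
      nz <- which(abs(vecs[, k]) > 1e-12)[1]
      if (!is.na(nz) && vecs[nz, k] < 0) vecs[, k] <- -vecs[, k]
    }
  }
  dimnames(vecs) <- list(colnames(z$values), paste0("PC", seq_len(p)))
  prop <- vals / p
  if (anyNA(z$values))
    svi_stop("component scores need complete data; impute or drop first",
             "svi_data_error")
  scores <- z$values %*% vecs
  retained <- if (retain_all) seq_len(p) else
    seq_len(which(cumsum(prop) >= var_target - 1e-12)[1])
  structure(
    list(loadings = vecs, variance_proportions = prop,
         component_scores = scores, retained = retained, eigenvalues = vals),
    class = "svi_pca"
  )
}

#' Variance-proportion-weighted principal-component index (Tier 4)
#'
#' When a whole vulnerability dimension is missing, the hierarchical
#' weighting collapses; the fallback scores each area as the sum of its
#' retained component scores weighted by their variance proportions. The
#' result ranks areas by the dominant joint variation of whatever
#' indicators are available, but covers only part of the vulnerability
#' concept: it is flagged as *not* a Social Vulnerability Index.
#'
#' @param z the aligned `svi_zscores` the decomposition was computed from.
#' @param d an `svi_pca` from [pca_decompose()].
#' @param normalize divide by the sum of retained variance proportions
#'   (a weighted mean instead of a weighted sum; the ranking is identical).
#' @return an `svi_scores` with empty `domain_scores`, the weighted index in
#'   `svi`, and attribute `not_svi = TRUE`.
#' @export
pca_index <- function(z, d, normalize = FALSE) {
  stopifnot(inherits(z, "svi_zscores"), inherits(d, "svi_pca"))
  if (nrow(d$component_scores) != length(z$area_ids) ||
      !identical(rownames(d$component_scores), z$area_ids))
    svi_stop("decomposition and z matrix cover different area sets",
             "svi_consistency_error")
  k <- d$retained
  svi <- as.numeric(d$component_scores[, k, drop = FALSE] %*%
                      d$variance_proportions[k])
  if (normalize) svi <- svi / sum(d$variance_proportions[k])
  names(svi) <- z$area_ids
  structure(
    list(area_ids = z$area_ids,
         domain_scores = matrix(numeric(), length(z$area_ids), 0,
                                dimnames = list(z$area_ids, NULL)),
         svi = svi, weights = NULL),
    not_svi = TRUE,
    class = "svi_scores"
  )
}

#' Export a principal-component decomposition as delimited text
#' @param d an `svi_pca`.
#' @param path output path (loadings; variance proportions appended as a row).
#' @return `path`, invisibly.
#' @export
write_pca <- function(d, path) {
  stopifnot(inherits(d, "svi_pca"))
  df <- data.frame(indicator_id = rownames(d$loadings), d$loadings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  extra <- data.frame(indicator_id = "variance_proportion",
                      matrix(d$variance_proportions, 1,
                             dimnames = list(NULL, colnames(d$loadings))),
                      check.names = FALSE, stringsAsFactors = FALSE)
  df <- rbind(df, extra)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
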