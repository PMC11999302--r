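#' Dimension scores from domain scores
#'
#' Each of the three vulnerability dimensions scores as the sum of its
#' domains' scores, so the three dimension maps (sensitivity, adaptive
#' capacity, enhanced exposure) partition the overall index: their row sum
#' equals the SVI. Not applicable to the Tier 4 principal-component route,
#' which has no hierarchy.
#'
#' @param st an `svi_scores` from [apply_weights()].
#' @param cfg the `svi_hierarchy` configuration.
#' @return area x dimension numeric matrix.
#' @export
dimension_scores <- function(st, cfg) {
  stopifnot(inherits(st, "svi_scores"), inherits(cfg, "svi_hierarchy"))
  if (!ncol(st$domain_scores))
    svi_stop("dimension scores are not defined for the tier 4 route",
             "svi_tier_routing_error")
  dims <- cfg$dimensions$dimension_id
  dd <- cfg$domains$dimension_id[match(colnames(st$domain_scores),
                                       cfg$domains$domain_id)]
  out <- vapply(dims, function(d) {
    cols <- which(dd == d)
    if (!length(cols)) rep(0, nrow(st$domain_scores)) else
      rowSums(st$domain_scores[, cols, drop = FALSE])
  }, numeric(nrow(st$domain_scores)))
  rownames(out) <- st$area_ids
  out
}

#' Ordinal classification scheme for vulnerability scores
#'
#' Two modes. `sd_bands` (default) standardizes the scores and cuts at
#' -2.5, -1.5, -0.5, 0.5, 1.5, 2.5 standard deviations, giving seven bands
#' from "extremely low" to "extremely high". `quantiles` cuts at the k-1
#' empirical quantiles (septiles by default), so bands are equally
#' populated in the absence of ties. Intervals are left-closed,
#' right-open, so a score exactly on a boundary falls deterministically in
#' the upper band.
#'
#' @param mode `"sd_bands"` or `"quantiles"`.
#' @param boundaries strictly increasing cut points (sd_bands only;
#'   quantile boundaries are data-driven).
#' @param labels ordered class labels, one more than the boundaries.
#' @return object of class `svi_classes`.
#' @export
classification_scheme <- function(mode = c("sd_bands", "quantiles"),
                                  boundaries = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
                                  labels = c("extremely low", "very low",
                                             "relatively low", "average",
                                             "relatively high", "very high",
                                             "extremely high")) {
  mode <- match.arg(mode)
  if (mode == "sd_bands") {
    if (length(labels) != length(boundaries) + 1L)
      svi_stop("labels must number one more than boundaries", "svi_config_error")
    if (is.unsorted(boundaries, strictly = TRUE))
      svi_stop("boundaries must be strictly increasing", "svi_config_error")
  }
  structure(list(mode = mode, boundaries = boundaries, labels = labels),
            class = "svi_classes")
}

#' Classify areas into ordinal vulnerability bands
#'
#' @param svi named numeric vector of index values.
#' @param scheme a [classification_scheme()].
#' @return ordered factor of class labels, one per area.
#' @export
classify_svi <- function(svi, scheme = classification_scheme()) {
  stopifnot(inherits(scheme, "svi_classes"))
  labels <- scheme$labels
  if (scheme$mode == "sd_bands") {
    s <- stats::sd(svi, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      svi_stop("scores are constant; standard-deviation bands undefined",
               "svi_degenerate_error")
    x <- (svi - mean(svi, na.rm = TRUE)) / s
    b <- scheme$boundaries
  } else {
    k <- length(labels)
    ok <- sum(!is.na(svi))
    if (ok < k)
      svi_stop(sprintf("quantile mode needs at least %d areas, got %d", k, ok),
               "svi_quantile_error")
    b <- stats::quantile(svi, probs = seq_len(k - 1) / k, na.rm = TRUE,
                         names = FALSE, type = 7)
    if (is.unsorted(b, strictly = TRUE))
      svi_stop("degenerate score distribution: quantile boundaries are tied",
               "svi_quantile_error")
    x <- svi
  }
  idx <- findInterval(x, b) + 1L  # left-closed, right-open bands
  out <- factor(labels[idx], levels = labels, ordered = TRUE)
  names(out) <- names(svi)
  out
}

#' Compare two area indices by rank agreement
#'
#' Joins two per-area indices on area id and reports the Spearman rank
#' correlation, an optional class cross-tabulation, and the areas with the
#' largest rank discordance — the places where the two instruments disagree
#' most (e.g. a flood vulnerability index against a general deprivation
#' index along a river).
#'
#' @param a,b named numeric vectors (names = area ids), or two-column data
#'   frames (area_id, value).
#' @param classes_a,classes_b optional per-area class labels (named vectors
#'   aligned with `a`/`b`); when both are given a cross-tabulation is
#'   included.
#' @param top number of most-discordant areas to report.
#' @return object of class `svi_comparison`: list with `n_shared`,
#'   `spearman`, `crosstab` (or NULL), `discordance` (data frame: area_id,
#'   rank_a, rank_b, rank_gap, sorted by decreasing gap).
#' @export
compare_indices <- function(a, b, classes_a = NULL, classes_b = NULL, top = 5L) {
  as_named <- function(x, nm) {
    if (is.data.frame(x)) {
      v <- stats::setNames(as.numeric(x[[2]]), canon_id(x[[1]]))
    } else {
      if (is.null(names(x)))
        svi_stop(paste0("'", nm, "' must be named by area id"), "svi_data_error")
      v <- stats::setNames(as.numeric(x), canon_id(names(x)))
    }
    v[!is.na(v)]
  }
  av <- as_named(a, "a"); bv <- as_named(b, "b")
  shared <- intersect(names(av), names(bv))
  if (length(shared) < 3L)
    svi_stop(sprintf("only %d shared area(s); need at least 3", length(shared)),
             "svi_insufficiency_error")
  av <- av[shared]; bv <- bv[shared]
  rho <- stats::cor(av, bv, method = "spearman")
  ra <- rank(av); rb <- rank(bv)
  disc <- data.frame(area_id = shared, rank_a = ra, rank_b = rb,
                     rank_gap = abs(ra - rb), stringsAsFactors = FALSE)
  disc <- disc[order(-disc$rank_gap, disc$area_id), ]
  ct <- NULL
  if (!is.null(classes_a) && !is.null(classes_b)) {
    ca <- classes_a[shared]; cb <- classes_b[shared]
    ct <- table(a = ca, b = cb)
  }
  structure(list(n_shared = length(shared), spearman = rho, crosstab = ct,
                 discordance = utils::head(disc, top)),
            class = "svi_comparison")
}

#' Assemble the full index result
#'
#' Bundles everything a user maps or exports: the stand-alone indicator
#' views (exactly the aligned z-score columns, untransformed further),
#' domain scores, dimension scores, the overall index, ordinal classes,
#' the tier and its caveats.
#'
#' @param scores an `svi_scores` (hierarchical or tier 4).
#' @param z the aligned `svi_zscores`.
#' @param cfg the `svi_hierarchy`.
#' @param tier the `svi_tier`.
#' @param scheme a [classification_scheme()].
#' @return object of class `svi_result`.
#' @export
svi_result <- function(scores, z, cfg, tier, scheme = classification_scheme()) {
  stopifnot(inherits(scores, "svi_scores"), inherits(tier, "svi_tier"))
  dims <- if (tier$tier == 4L) NULL else dimension_scores(scores, cfg)
  caveats <- tier$caveats
  if (isTRUE(attr(scores, "not_svi")))
    caveats <- union(caveats, "not a Social Vulnerability Index")
  structure(
    list(area_ids = scores$area_ids,
         indicator_views = z$values,
         domain_scores = scores$domain_scores,
         dimension_scores = dims,
         svi = scores$svi,
         class_label = classify_svi(scores$svi, scheme),
         tier = tier, caveats = caveats, weights = scores$weights,
         scheme = scheme),
    class = "svi_result"
  )
}

#' Write an index result as delimited text
#'
#' One row per area: the aligned per-indicator z-scores, domain scores,
#' dimension scores, overall index, ordinal class, tier and caveats.
#'
#' @param result an `svi_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svi_result <- function(result, path) {
  stopifnot(inherits(result, "svi_result"))
  df <- data.frame(area_id = result$area_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  add <- function(m, prefix) {
    if (is.null(m) || !ncol(m)) return()
    mm <- as.data.frame(m, check.names = FALSE)
    names(mm) <- paste0(prefix, names(mm))
    df <<- cbind(df, mm)
  }
  add(result$indicator_views, "z_")
  add(result$domain_scores, "domain_")
  add(result$dimension_scores, "dimension_")
  df$svi <- unname(result$svi)
  df$class <- as.character(result$class_label)
  df$tier <- result$tier$tier
  df$caveats <- paste(result$caveats, collapse = "; ")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.svi_result <- function(x, ...) {
  cat(sprintf("SVI result: %d areas, tier %d\n",
              length(x$area_ids), x$tier$tier))
  print(summary(unname(x$svi)))
  print(table(x$class_label))
  for (cvt in x$caveats) cat("caveat:", cvt, "\n")
  invisible(x)
}

#' @export
print.svi_comparison <- function(x, ...) {
  cat(sprintf("Index comparison over %d shared areas: Spearman rho = %.3f\n",
              x$n_shared, x$spearman))
  if (!is.null(x$crosstab)) print(x$crosstab)
  cat("Most discordant areas:\n")
  print(x$discordance, row.names = FALSE)
  invisible(x)
}
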