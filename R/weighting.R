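#' Classify the data situation into weighting tiers 1-4
#'
#' The four-tier rule set adapts the weighting to what the census actually
#' provides, with precedence 4 > 3 > 2 > 1:
#' \itemize{
#'   \item Tier 4 — at least one dimension has no available domain at all;
#'     the hierarchy collapses and the index falls back to the
#'     principal-component route ([pca_index()]), whose output should not be
#'     read as a social vulnerability index.
#'   \item Tier 3 — some dimension rests on a single available domain; the
#'     weighting is the Tier 2 rule but the index is flagged less robust.
#'   \item Tier 2 — one or more domains are depleted (missing required
#'     indicators relative to design, or reduced to a lone indicator);
#'     their weights are halved.
#'   \item Tier 1 — the ideal situation: every domain complete, at least two
#'     domains per dimension; equal within-domain weights summing to 1.
#' }
#'
#' @param profile an [availability_profile()].
#' @return an object of class `svi_tier`: list with `tier` (integer 1-4),
#'   `reasons` (character, the rule firings), `caveats` (character,
#'   non-empty for tiers 3 and 4).
#' @export
classify_tier <- function(profile) {
  stopifnot(inherits(profile, "svi_availability"))
  dims <- profile$dimensions
  empty_dims <- dims$dimension_id[dims$available_domain_count == 0L]
  single_dims <- dims$dimension_id[dims$available_domain_count == 1L]
  depleted <- profile$depleted_domains

  if (length(empty_dims)) {
    tier <- 4L
    reasons <- paste0("dimension with no available domain: ",
                      paste(empty_dims, collapse = ", "))
    caveats <- paste("whole dimension(s) missing; the principal-component",
                     "fallback output is not a Social Vulnerability Index")
  } else if (length(single_dims)) {
    tier <- 3L
    reasons <- paste0("dimension held by a single available domain: ",
                      paste(single_dims, collapse = ", "))
    caveats <- paste("index rests on single-domain dimension(s)",
                     paste0("(", paste(single_dims, collapse = ", "), ");"),
                     "less robust - interpret with caution")
  } else if (length(depleted)) {
    tier <- 2L
    reasons <- paste0("depleted domain(s): ", paste(depleted, collapse = ", "))
    caveats <- character()
  } else {
    tier <- 1L
    reasons <- "all domains complete, every dimension has >=2 domains"
    caveats <- character()
  }
  if (tier %in% c(2L, 3L) && length(depleted))
    reasons <- union(reasons,
                     paste0("halved weights applied to: ",
                            paste(depleted, collapse = ", ")))
  structure(list(tier = tier, reasons = reasons, caveats = caveats),
            class = "svi_tier")
}

#' Build the per-indicator weight scheme for tiers 1-3
#'
#' Tier 1: within each domain with m available indicators every indicator
#' weighs 1/m, so each domain contributes weight 1 in total. Tiers 2-3: in
#' depleted domains the weights are halved to 1/(2m), capping the domain's
#' total contribution at 1/2; intact domains keep 1/m. Unavailable
#' indicators get weight zero. Tier 4 has no domain weights; callers are
#' routed to [pca_decompose()]/[pca_index()].
#'
#' @param profile an [availability_profile()].
#' @param tier an `svi_tier` from [classify_tier()] (or an integer 1-3).
#' @return an object of class `svi_weights`: list with `weights` (data
#'   frame: domain_id, indicator_id, weight), `tier`, and
#'   `domain_weight_sums` (named numeric over available domains).
#' @export
build_weights <- function(profile, tier) {
  stopifnot(inherits(profile, "svi_availability"))
  if (is.numeric(tier)) tier <- structure(list(tier = as.integer(tier),
                                               reasons = character(),
                                               caveats = character()),
                                          class = "svi_tier")
  stopifnot(inherits(tier, "svi_tier"))
  if (tier$tier == 4L)
    svi_stop(paste("tier 4 has no hierarchical weights; use the",
                   "principal-component route (pca_decompose / pca_index)"),
             "svi_tier_routing_error")

  dom <- profile$domains
  map <- attr(profile, "indicator_domain")
  halve <- if (tier$tier == 1L) rep(FALSE, nrow(dom)) else dom$depleted
  rows <- lapply(seq_len(nrow(dom)), function(i) {
    d <- dom$domain_id[i]
    declared <- names(map)[map == d]
    avail <- declared %in% profile$available_indicators
    m <- sum(avail)
    w_avail <- if (m == 0L) numeric() else
      rep(if (halve[i]) 1 / (2 * m) else 1 / m, m)
    data.frame(domain_id = d,
               indicator_id = c(declared[avail], declared[!avail]),
               weight = c(w_avail, rep(0, sum(!avail))),
               stringsAsFactors = FALSE)
  })
  wdf <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  domain_sums <- tapply(wdf$weight, wdf$domain_id, sum)
  active <- dom$domain_id[dom$available_count > 0]
  structure(
    list(weights = wdf, tier = tier,
         domain_weight_sums = stats::setNames(as.numeric(domain_sums[active]),
                                              active)),
    class = "svi_weights"
  )
}

#' Aggregate weighted z-scores into domain scores and the overall index
#'
#' Computes, per area, each domain's score as the weighted sum of its
#' aligned indicator z-scores, and the overall index as the sum of the
#' domain scores:
#' \deqn{SVI = \sum_n \sum_m W_{mn} \, ind_m.}
#' Under the `renormalize_weights` missing-data policy, an area with
#' missing cells inside a domain has that domain's weights rescaled over
#' its observed indicators so the domain's total weight is preserved; an
#' area with a whole domain unobserved gets `NA` for that domain (and hence
#' for its index), never a silent zero.
#'
#' @param z an aligned `svi_zscores` (see [align_direction()]).
#' @param w an `svi_weights` scheme.
#' @param missing_policy `"renormalize_weights"` (default) or `"error"`.
#' @return an object of class `svi_scores`: list with `area_ids`,
#'   `domain_scores` (area x domain matrix), `svi` (named numeric), and
#'   `weights` (the scheme used).
#' @export
apply_weights <- function(z, w,
                          missing_policy = c("renormalize_weights", "error")) {
  stopifnot(inherits(z, "svi_zscores"), inherits(w, "svi_weights"))
  missing_policy <- match.arg(missing_policy)
  if (!isTRUE(z$aligned))
    warning("z-scores are not direction-aligned; scores may point the wrong way",
            call. = FALSE)
  wdf <- w$weights[w$weights$weight > 0, , drop = FALSE]
  absent <- setdiff(wdf$indicator_id, colnames(z$values))
  if (length(absent))
    svi_stop(paste0("weighted indicator(s) absent from the z matrix: ",
                    paste(absent, collapse = ", ")),
             "svi_consistency_error")
  if (missing_policy == "error" && anyNA(z$values[, wdf$indicator_id]))
    svi_stop("missing z-scores under policy=error", "svi_data_error")

  domains <- unique(wdf$domain_id)
  n <- length(z$area_ids)
  ds <- matrix(NA_real_, n, length(domains),
               dimnames = list(z$area_ids, domains))
  for (d in domains) {
    sub <- wdf[wdf$domain_id == d, ]
    zd <- z$values[, sub$indicator_id, drop = FALSE]
    wt <- sub$weight
    obs <- !is.na(zd)
    wmat <- matrix(wt, n, length(wt), byrow = TRUE)
    wmat[!obs] <- 0
    denom <- rowSums(wmat)
    target <- sum(wt)
    # rescale observed weights to preserve the domain's weight sum
    scale <- ifelse(denom > 0, target / denom, NA_real_)
    zd0 <- zd; zd0[!obs] <- 0
    ds[, d] <- rowSums(zd0 * wmat) * scale
  }
  svi <- rowSums(ds)
  names(svi) <- z$area_ids
  structure(list(area_ids = z$area_ids, domain_scores = ds, svi = svi,
                 weights = w),
            class = "svi_scores")
}

#' Export a weight scheme as delimited text for audit
#' @param w an `svi_weights`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "svi_weights"))
  df <- w$weights
  df$tier <- w$tier$tier
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.svi_tier <- function(x, ...) {
  cat(sprintf("Weighting tier %d\n", x$tier))
  for (r in x$reasons) cat("  -", r, "\n")
  for (cvt in x$caveats) cat("  caveat:", cvt, "\n")
  invisible(x)
}
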