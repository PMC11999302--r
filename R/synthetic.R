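#' Specification for a synthetic census-like indicator table
#'
#' The generator emulates what the index pipeline consumes: one latent
#' vulnerability factor per area, indicator columns loading on it with
#' noise, vulnerability-reducing indicators entering with flipped sign (so
#' the raw data genuinely need direction alignment), and optional logistic
#' mapping onto a 0-100 percent scale. Because the generating latent is
#' returned, recovery of its ranking by the computed index is testable end
#' to end, under every data-availability degradation scenario.
#'
#' @param n_areas number of areas (>= 10; smaller fixtures are hand-written).
#' @param hierarchy an `svi_hierarchy` (preset or custom). Only indicators
#'   with `collected = TRUE` get columns, emulating the city-shaped table.
#' @param loading correlation strength in (0, 1]: either a single value or
#'   a per-indicator named vector.
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param rate_transform `"none"` (raw latent scale) or `"logistic_percent"`
#'   (monotone map onto 0-100).
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `svi_simspec`.
#' @export
simulation_spec <- function(n_areas, hierarchy, loading = 0.8, noise_sd = 0.6,
                            rate_transform = c("none", "logistic_percent"),
                            seed = 1L) {
  stopifnot(inherits(hierarchy, "svi_hierarchy"))
  rate_transform <- match.arg(rate_transform)
  if (!is.numeric(n_areas) || n_areas < 10)
    svi_stop("n_areas must be at least 10", "svi_config_error")
  ids <- hierarchy$indicators$indicator_id
  if (length(loading) == 1L) loading <- stats::setNames(rep(loading, length(ids)), ids)
  if (!all(names(loading) %in% ids) || length(loading) != length(ids))
    loading <- stats::setNames(loading[ids], ids)
  if (any(is.na(loading)) || any(loading <= 0) || any(loading > 1))
    svi_stop("loadings must lie in (0, 1] for every indicator",
             "svi_config_error")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    svi_stop("noise_sd must be non-negative", "svi_config_error")
  structure(list(n_areas = as.integer(n_areas), hierarchy = hierarchy,
                 loading = loading, noise_sd = noise_sd,
                 rate_transform = rate_transform, seed = as.integer(seed)),
            class = "svi_simspec")
}

#' Generate a synthetic indicator table with known latent vulnerability
#'
#' Per area, latent vulnerability L ~ N(0, 1). Raw indicator j is
#' `loading_j * s_j * L + e`, `e ~ N(0, noise_sd^2)`, with `s_j = -1` for
#' vulnerability-reducing indicators and `+1` otherwise. The optional
#' logistic transform maps each column monotonically onto the 0-100 percent
#' scale of census rates (ranks, hence the recovered ordering, are
#' preserved; the scores themselves are not numerically identical since the
#' map is nonlinear).
#'
#' @param spec a [simulation_spec()].
#' @return list with `table` (an `indicator_table`), `latent` (named truth
#'   vector), and `units` (a square-grid `svi_units` with matching ids).
#' @export
simulate_indicators <- function(spec) {
  stopifnot(inherits(spec, "svi_simspec"))
  set.seed(spec$seed)
  n <- spec$n_areas
  ids <- sprintf("a%04d", seq_len(n))
  L <- stats::rnorm(n)
  ind <- spec$hierarchy$indicators
  ind <- ind[ind$collected, , drop = FALSE]
  cols <- vapply(seq_len(nrow(ind)), function(j) {
    s <- if (ind$direction[j] == "vulnerability_reducing") -1 else 1
    spec$loading[[ind$indicator_id[j]]] * s * L +
      stats::rnorm(n, 0, spec$noise_sd)
  }, numeric(n))
  colnames(cols) <- ind$indicator_id
  if (spec$rate_transform == "logistic_percent")
    cols <- 100 * stats::plogis(cols)
  list(table = indicator_table(cols, ids),
       latent = stats::setNames(L, ids),
       units = grid_units(ids))
}

#' Degrade a table to emulate a data-availability scenario
#'
#' Column deletion (not masking), so the remaining columns are byte-for-byte
#' identical to the undegraded table:
#' \itemize{
#'   \item `tier2_deplete` — drop the named indicators (required indicators
#'     of a domain, leaving it depleted);
#'   \item `tier3_single_domain_dimension` — drop every domain of the named
#'     dimension except one (`keep`);
#'   \item `tier4_drop_dimension` — drop all columns of the named dimension.
#' }
#' An empty `targets` is the identity.
#'
#' @param table an `indicator_table`.
#' @param cfg the `svi_hierarchy` the table belongs to.
#' @param scenario one of `"tier2_deplete"`, `"tier3_single_domain_dimension"`,
#'   `"tier4_drop_dimension"`.
#' @param targets indicator ids (tier2) or a dimension id (tier3/tier4).
#' @param keep domain id to retain (tier3 only; default: the dimension's
#'   first declared domain).
#' @return the degraded `indicator_table`.
#' @export
degrade_table <- function(table, cfg,
                          scenario = c("tier2_deplete",
                                       "tier3_single_domain_dimension",
                                       "tier4_drop_dimension"),
                          targets = character(), keep = NULL) {
  stopifnot(inherits(table, "indicator_table"), inherits(cfg, "svi_hierarchy"))
  scenario <- match.arg(scenario)
  if (!length(targets)) return(table)
  ind <- cfg$indicators
  dom <- cfg$domains
  drop_cols <- switch(
    scenario,
    tier2_deplete = {
      unknown <- setdiff(targets, ind$indicator_id)
      if (length(unknown))
        svi_stop(paste0("unknown indicator target(s): ",
                        paste(unknown, collapse = ", ")), "svi_config_error")
      targets
    },
    tier3_single_domain_dimension = {
      if (!targets[1] %in% cfg$dimensions$dimension_id)
        svi_stop(paste0("unknown dimension target: ", targets[1]),
                 "svi_config_error")
      doms <- dom$domain_id[dom$dimension_id == targets[1]]
      keep <- keep %||% doms[1]
      if (!keep %in% doms)
        svi_stop(paste0("domain '", keep, "' is not in dimension '",
                        targets[1], "'"), "svi_config_error")
      ind$indicator_id[ind$domain_id %in% setdiff(doms, keep)]
    },
    tier4_drop_dimension = {
      if (!targets[1] %in% cfg$dimensions$dimension_id)
        svi_stop(paste0("unknown dimension target: ", targets[1]),
                 "svi_config_error")
      doms <- dom$domain_id[dom$dimension_id == targets[1]]
      ind$indicator_id[ind$domain_id %in% doms]
    }
  )
  remaining <- setdiff(colnames(table$values), drop_cols)
  if (!length(remaining))
    svi_stop("degradation would remove every column", "svi_data_error")
  indicator_table(table$values[, remaining, drop = FALSE], table$area_ids)
}
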