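#' Run the full index pipeline
#'
#' Orchestrates load -> validate -> availability profile -> normalize ->
#' align -> tier -> weights (or principal-component fallback) -> aggregate
#' -> classify -> export, logging each stage to standard error. Fully
#' deterministic given fixed inputs (and seed, kept for interface parity;
#' no stage past generation draws random numbers).
#'
#' @param config path to a YAML hierarchy, or an `svi_hierarchy`.
#' @param indicators path to a delimited indicator table, or an
#'   `indicator_table`.
#' @param geometry optional GeoJSON path or `svi_units` for map export.
#' @param id_field geometry property holding the area id.
#' @param tier `"auto"` (derive from the availability profile) or a manual
#'   override in 1-4; a contradiction with the auto tier logs a warning.
#' @param missing_policy see [handle_missing()].
#' @param classes `"sd_bands"` or `"quantiles"`.
#' @param out_dir directory for outputs (`svi_scores.csv`, `weights.csv` or
#'   `pca.csv`, `svi.geojson`); `NULL` writes nothing.
#' @param seed optional integer seed.
#' @param quiet suppress stage logging.
#' @return (invisibly) list with `result` (an `svi_result`), `tier`,
#'   `profile`, `join_report` (or NULL), `files` (character), `status` (0).
#' @export
run_pipeline <- function(config, indicators, geometry = NULL,
                         id_field = "area_id", tier = "auto",
                         missing_policy = "renormalize_weights",
                         classes = c("sd_bands", "quantiles"),
                         out_dir = NULL, seed = NULL, quiet = FALSE) {
  classes <- match.arg(classes)
  if (!is.null(seed)) set.seed(seed)

  cfg <- if (inherits(config, "svi_hierarchy")) config else load_hierarchy(config)
  stage_log("config", sprintf("hierarchy loaded: %d dimensions, %d domains, %d indicators",
                              nrow(cfg$dimensions), nrow(cfg$domains),
                              nrow(cfg$indicators)), quiet = quiet)
  rep <- validate_hierarchy(cfg)
  errs <- rep[rep$severity == "error", ]
  if (nrow(errs))
    svi_stop(paste0("invalid configuration: ",
                    paste(errs$message, collapse = "; ")), "svi_config_error")
  for (w in rep$message[rep$severity == "warning"])
    stage_log("config", "warning: ", w, quiet = quiet)

  table <- if (inherits(indicators, "indicator_table")) indicators else
    read_indicator_table(indicators)
  stage_log("data", sprintf("%d areas x %d indicator columns",
                            length(table$area_ids), ncol(table$values)),
            quiet = quiet)

  hm <- handle_missing(table, missing_policy)
  table <- hm$table
  if (hm$report$n_missing)
    stage_log("data", sprintf("%d missing cell(s), policy=%s",
                              hm$report$n_missing, hm$report$policy),
              quiet = quiet)

  profile <- availability_profile(cfg, table)
  auto_tier <- classify_tier(profile)
  if (identical(tier, "auto") || is.null(tier)) {
    tier_asg <- auto_tier
  } else {
    tier <- as.integer(tier)
    if (tier != auto_tier$tier)
      warning(sprintf("manual tier %d contradicts auto-derived tier %d",
                      tier, auto_tier$tier), call. = FALSE)
    tier_asg <- structure(list(tier = tier,
                               reasons = c(sprintf("manual override (auto: %d)",
                                                   auto_tier$tier),
                                           auto_tier$reasons),
                               caveats = auto_tier$caveats),
                          class = "svi_tier")
  }
  stage_log("tier", sprintf("tier %d: %s", tier_asg$tier,
                            paste(tier_asg$reasons, collapse = "; ")),
            quiet = quiet)

  # keep only available (recognized, non-degenerate) columns
  keep <- profile$available_indicators
  table_av <- indicator_table(table$values[, keep, drop = FALSE], table$area_ids)
  z <- align_direction(zscore_normalize(table_av), cfg)
  stage_log("normalize", sprintf("%d columns z-scored; %d direction-flipped",
                                 ncol(z$values), length(z$flipped)),
            quiet = quiet)

  scheme <- classification_scheme(mode = classes)
  files <- character()
  pca <- NULL
  if (tier_asg$tier == 4L) {
    if (anyNA(z$values)) {
      warning("principal-component route needs complete data; missing z-scores set to 0 (column mean)",
              call. = FALSE)
      z$values[is.na(z$values)] <- 0
    }
    pca <- pca_decompose(z)
    scores <- pca_index(z, pca)
    stage_log("weights", sprintf("tier 4 principal-component index: %d of %d components retained",
                                 length(pca$retained), ncol(pca$loadings)),
              quiet = quiet)
  } else {
    wts <- build_weights(profile, tier_asg)
    scores <- apply_weights(z, wts,
                            missing_policy = if (missing_policy == "error")
                              "error" else "renormalize_weights")
    stage_log("weights", sprintf("tier %d weights over %d domains",
                                 tier_asg$tier, length(wts$domain_weight_sums)),
              quiet = quiet)
  }
  result <- svi_result(scores, z, cfg, tier_asg, scheme)
  stage_log("aggregate", sprintf("svi range [%.3f, %.3f], classes: %s",
                                 min(result$svi, na.rm = TRUE),
                                 max(result$svi, na.rm = TRUE), classes),
            quiet = quiet)

  join_report <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, "svi_scores.csv")
    write_svi_result(result, f); files <- c(files, f)
    if (tier_asg$tier == 4L) {
      f <- file.path(out_dir, "pca.csv"); write_pca(pca, f)
    } else {
      f <- file.path(out_dir, "weights.csv"); write_weights(scores$weights, f)
    }
    files <- c(files, f)
    if (!is.null(geometry)) {
      units <- if (inherits(geometry, "svi_units")) geometry else
        read_geometry(geometry, id_field = id_field)
      f <- file.path(out_dir, "svi.geojson")
      join_report <- join_and_export(result, units, f)
      files <- c(files, f)
      stage_log("geo", sprintf("%d matched, %d table-only, %d geometry-only ids",
                               length(join_report$matched),
                               length(join_report$unmatched_result_ids),
                               length(join_report$unmatched_geometry_ids)),
                quiet = quiet)
    }
    stage_log("export", paste(files, collapse = ", "), quiet = quiet)
  }
  invisible(list(result = result, tier = tier_asg, profile = profile,
                 pca = pca, join_report = join_report, files = files,
                 status = 0L))
}
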