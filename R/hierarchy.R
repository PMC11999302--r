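#' Load an indicator hierarchy configuration
#'
#' Reads a YAML document declaring the three-level structure of a social
#' vulnerability index: indicators grouped into thematic domains, domains
#' attached to one of the three vulnerability dimensions (sensitivity,
#' adaptive capacity, enhanced exposure). Each indicator carries a
#' vulnerability direction (whether larger raw values mean more or less
#' vulnerability), a `required` flag that counts toward domain completeness,
#' and optional metadata: a `sub_ability` tag (prepare/respond/recover, used
#' in reports only), hazard tags, and a `collected` flag recording whether
#' the source census actually publishes the indicator (used by the synthetic
#' generator to emulate city-shaped tables).
#'
#' @param path path to a YAML configuration file, or a single string
#'   containing YAML text.
#' @return an object of class `svi_hierarchy`: a list with elements
#'   `hazard`, `city`, `dimensions` (data frame: dimension_id, label),
#'   `domains` (data frame: domain_id, label, dimension_id, designed_size),
#'   and `indicators` (data frame: indicator_id, label, domain_id,
#'   direction, required, sub_ability, collected).
#' @seealso [svi_preset()] for the shipped configurations,
#'   [validate_hierarchy()], [availability_profile()].
#' @export
load_hierarchy <- function(path) {
  looks_like_path <- is_string(path) && !grepl("\n", path)
  if (looks_like_path && !file.exists(path))
    svi_stop(paste0("configuration file not found: ", path), "svi_config_error")
  doc <- tryCatch(
    if (looks_like_path) yaml::read_yaml(path) else yaml::yaml.load(path),
    error = function(e) svi_stop(
      paste0("configuration failed to parse: ", conditionMessage(e)),
      "svi_config_error"
    )
  )
  if (!is.list(doc))
    svi_stop("configuration is not a structured document", "svi_config_error")
  for (key in c("dimensions", "domains", "indicators")) {
    if (is.null(doc[[key]]))
      svi_stop(paste0("configuration is missing top-level key '", key, "'"),
               "svi_config_error")
  }

  dims <- data.frame(
    dimension_id = canon_id(vapply(doc$dimensions, function(d) d$id, "")),
    label = vapply(doc$dimensions, function(d) d$label %||% d$id, ""),
    stringsAsFactors = FALSE
  )
  doms <- data.frame(
    domain_id = canon_id(vapply(doc$domains, function(d) d$id, "")),
    label = vapply(doc$domains, function(d) d$label %||% d$id, ""),
    dimension_id = canon_id(vapply(doc$domains, function(d) d$dimension %||% "", "")),
    stringsAsFactors = FALSE
  )
  inds <- data.frame(
    indicator_id = canon_id(vapply(doc$indicators, function(i) i$id, "")),
    label = vapply(doc$indicators, function(i) i$label %||% i$id, ""),
    domain_id = canon_id(vapply(doc$indicators, function(i) i$domain %||% "", "")),
    direction = vapply(doc$indicators, function(i) i$direction %||% "", ""),
    required = vapply(doc$indicators, function(i) isTRUE(i$required %||% TRUE), NA),
    sub_ability = vapply(doc$indicators, function(i) i$sub_ability %||% NA_character_, ""),
    collected = vapply(doc$indicators, function(i) isTRUE(i$collected %||% TRUE), NA),
    stringsAsFactors = FALSE
  )

  # referential integrity
  dangling_dom <- setdiff(inds$domain_id, doms$domain_id)
  if (length(dangling_dom))
    svi_stop(paste0("indicators reference unknown domain(s): ",
                    paste(dangling_dom, collapse = ", ")),
             "svi_linkage_error")
  dangling_dim <- setdiff(doms$dimension_id, dims$dimension_id)
  if (length(dangling_dim))
    svi_stop(paste0("domains reference unknown dimension(s): ",
                    paste(dangling_dim, collapse = ", ")),
             "svi_linkage_error")
  bad_dir <- !inds$direction %in% c("vulnerability_increasing", "vulnerability_reducing")
  if (any(bad_dir))
    svi_stop(paste0("indicator(s) with invalid direction: ",
                    paste(inds$indicator_id[bad_dir], collapse = ", ")),
             "svi_config_error")
  bad_sub <- !is.na(inds$sub_ability) &
    !inds$sub_ability %in% c("prepare", "respond", "recover")
  if (any(bad_sub))
    svi_stop(paste0("invalid sub_ability tag on: ",
                    paste(inds$indicator_id[bad_sub], collapse = ", ")),
             "svi_config_error")
  empty <- setdiff(doms$domain_id, inds$domain_id)
  if (length(empty))
    svi_stop(paste0("domain(s) declared with no indicators: ",
                    paste(empty, collapse = ", ")),
             "svi_config_error")
  if (anyDuplicated(inds$indicator_id))
    svi_stop(paste0("duplicate indicator id(s): ",
                    paste(unique(inds$indicator_id[duplicated(inds$indicator_id)]),
                          collapse = ", ")),
             "svi_config_error")
  if (anyDuplicated(doms$domain_id))
    svi_stop("duplicate domain id(s)", "svi_config_error")
  if (anyDuplicated(dims$dimension_id))
    svi_stop("duplicate dimension id(s)", "svi_config_error")

  doms$designed_size <- as.integer(table(factor(inds$domain_id, doms$domain_id)))

  structure(
    list(hazard = doc$hazard %||% NA_character_,
         city = doc$city %||% NA_character_,
         dimensions = dims, domains = doms, indicators = inds),
    class = "svi_hierarchy"
  )
}

#' Write a hierarchy configuration back to YAML
#'
#' Inverse of [load_hierarchy()]; a loaded configuration round-trips
#' unchanged.
#'
#' @param cfg an `svi_hierarchy`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_hierarchy <- function(cfg, path) {
  stopifnot(inherits(cfg, "svi_hierarchy"))
  strip_na <- function(x) x[!vapply(x, function(v) is.null(v) ||
                                      (length(v) == 1 && is.na(v)), NA)]
  doc <- list(
    hazard = cfg$hazard, city = cfg$city,
    dimensions = lapply(seq_len(nrow(cfg$dimensions)), function(i)
      list(id = cfg$dimensions$dimension_id[i], label = cfg$dimensions$label[i])),
    domains = lapply(seq_len(nrow(cfg$domains)), function(i)
      list(id = cfg$domains$domain_id[i], label = cfg$domains$label[i],
           dimension = cfg$domains$dimension_id[i])),
    indicators = lapply(seq_len(nrow(cfg$indicators)), function(i) {
      r <- cfg$indicators[i, ]
      strip_na(list(id = r$indicator_id, label = r$label, domain = r$domain_id,
                    direction = r$direction, required = r$required,
                    sub_ability = r$sub_ability,
                    collected = if (r$collected) NULL else FALSE))
    })
  )
  yaml::write_yaml(strip_na(doc), path)
  invisible(path)
}

#' Shipped hierarchy presets
#'
#' Three worked configurations are installed with the package:
#' `"cork_flood"` (flood, Irish-style census, 11 domains / 27 indicators,
#' the ideal Tier 1 situation), `"logrono_heat"` (heat, Spanish-style
#' census, a depleted Health domain giving Tier 2) and `"milan_heat"`
#' (heat, Italian-style census, single-domain sensitivity and enhanced
#' exposure dimensions giving Tier 3).
#'
#' @param name preset name.
#' @return an `svi_hierarchy`.
#' @export
svi_preset <- function(name = c("cork_flood", "logrono_heat", "milan_heat")) {
  name <- match.arg(name)
  load_hierarchy(system.file("extdata", "presets", paste0(name, ".yaml"),
                             package = "svindex", mustWork = TRUE))
}

#' Validate a hierarchy configuration
#'
#' Checks the structural rules an index configuration must satisfy: unique
#' ids, no empty domains, and the presence of exactly the three
#' vulnerability dimensions (sensitivity, adaptive capacity, enhanced
#' exposure) — at least one indicator informing each dimension is necessary
#' for a score to count as a social vulnerability index. A dimension held
#' by a single domain is legal but reduces robustness, so it is reported as
#' a warning-severity finding rather than an error.
#'
#' @param cfg an `svi_hierarchy`.
#' @return a data frame of class `svi_validation` with columns `severity`
#'   ("error" or "warning"), `rule`, and `message`; zero rows means valid.
#' @export
validate_hierarchy <- function(cfg) {
  stopifnot(inherits(cfg, "svi_hierarchy"))
  out <- list()
  add <- function(severity, rule, msg)
    out[[length(out) + 1L]] <<- data.frame(severity = severity, rule = rule,
                                           message = msg, stringsAsFactors = FALSE)

  dup <- unique(cfg$indicators$indicator_id[duplicated(cfg$indicators$indicator_id)])
  for (d in dup) add("error", "duplicate_indicator", paste0("duplicate indicator id: ", d))

  canonical <- c("sensitivity", "adaptive_capacity", "enhanced_exposure")
  for (d in setdiff(canonical, cfg$dimensions$dimension_id))
    add("error", "dimension_absent", paste0("dimension absent: ", d))
  for (d in setdiff(cfg$dimensions$dimension_id, canonical))
    add("error", "dimension_unknown", paste0("dimension not recognised: ", d))

  empty <- setdiff(cfg$domains$domain_id, cfg$indicators$domain_id)
  for (d in empty) add("error", "empty_domain", paste0("domain has no indicators: ", d))

  per_dim <- table(factor(cfg$domains$dimension_id, cfg$dimensions$dimension_id))
  for (d in names(per_dim)[per_dim == 1L])
    add("warning", "single_domain_dimension",
        paste0("dimension '", d, "' holds a single domain; the index will be ",
               "less robust in that dimension"))

  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(severity = character(), rule = character(), message = character(),
               stringsAsFactors = FALSE)
  class(rep) <- c("svi_validation", "data.frame")
  rep
}

#' Data-availability profile of an indicator table against a configuration
#'
#' Counts, per domain, how many of its designed indicators are actually
#' available in the table (present, not all-missing, not constant) and
#' flags depleted domains: those missing required indicators relative to
#' their design, or reduced to a lone indicator although designed with
#' more. A domain *designed* with a single indicator is not depleted. The
#' profile drives tier selection in [classify_tier()].
#'
#' @param cfg an `svi_hierarchy`.
#' @param table an [indicator_table()].
#' @return an object of class `svi_availability`: list with `domains`
#'   (data frame: domain_id, dimension_id, designed_size, available_count,
#'   missing_required, depleted), `dimensions` (data frame: dimension_id,
#'   available_domain_count), `depleted_domains` (character), and
#'   `available_indicators` (character).
#' @export
availability_profile <- function(cfg, table) {
  stopifnot(inherits(cfg, "svi_hierarchy"), inherits(table, "indicator_table"))
  cols <- colnames(table$values)
  unknown <- setdiff(cols, cfg$indicators$indicator_id)
  if (length(unknown))
    svi_stop(paste0("table column(s) not declared in the configuration: ",
                    paste(unknown, collapse = ", ")),
             "svi_consistency_error")
  recognized <- intersect(cols, cfg$indicators$indicator_id)
  if (!length(recognized))
    svi_stop("table contains no recognized indicator columns",
             "svi_data_error")

  usable <- vapply(recognized, function(j) {
    x <- table$values[, j]
    x <- x[!is.na(x)]
    length(x) >= 2L && stats::sd(x) > 0
  }, NA)
  available <- recognized[usable]

  ind <- cfg$indicators
  dom <- cfg$domains
  avail_by_dom <- vapply(dom$domain_id, function(d)
    sum(ind$domain_id == d & ind$indicator_id %in% available), 0L)
  missing_req <- vapply(dom$domain_id, function(d) {
    req <- ind$indicator_id[ind$domain_id == d & ind$required]
    any(!req %in% available)
  }, NA)
  depleted <- (avail_by_dom < dom$designed_size & missing_req) |
    (avail_by_dom == 1L & dom$designed_size > 1L)

  domains <- data.frame(
    domain_id = dom$domain_id, dimension_id = dom$dimension_id,
    designed_size = dom$designed_size,
    available_count = as.integer(avail_by_dom),
    missing_required = missing_req, depleted = depleted,
    stringsAsFactors = FALSE
  )
  dims <- data.frame(
    dimension_id = cfg$dimensions$dimension_id,
    available_domain_count = vapply(cfg$dimensions$dimension_id, function(dd)
      sum(domains$available_count > 0L & domains$dimension_id == dd), 0L),
    stringsAsFactors = FALSE
  )
  map <- stats::setNames(ind$domain_id, ind$indicator_id)
  structure(
    list(domains = domains, dimensions = dims,
         depleted_domains = domains$domain_id[domains$depleted],
         available_indicators = available),
    indicator_domain = map,
    class = "svi_availability"
  )
}

#' @export
print.svi_hierarchy <- function(x, ...) {
  cat(sprintf("SVI hierarchy: %s (%s)\n", x$city %||% "?", x$hazard %||% "?"))
  cat(sprintf("  %d dimensions, %d domains, %d indicators\n",
              nrow(x$dimensions), nrow(x$domains), nrow(x$indicators)))
  invisible(x)
}

#' @export
print.svi_availability <- function(x, ...) {
  cat("Availability profile\n")
  print(x$domains, row.names = FALSE)
  if (length(x$depleted_domains))
    cat("Depleted domains:", paste(x$depleted_domains, collapse = ", "), "\n")
  else cat("No depleted domains.\n")
  invisible(x)
}
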