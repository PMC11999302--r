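#' Read area geometries from GeoJSON
#'
#' Loads polygon/multipolygon features keyed by an area identifier, for
#' joining index results onto a map. Identifiers are coerced to trimmed
#' text; the CRS member, if present, is passed through unmodified (the
#' package computes no areas or distances, so no reprojection is done).
#' Only GeoJSON is supported: it is the one text-based interchange format,
#' and the ids, not the projection, carry the join.
#'
#' @param path path to a GeoJSON FeatureCollection.
#' @param id_field property holding the area identifier.
#' @param on_invalid `"reject"` (error on structurally invalid geometry:
#'   empty coordinates, unclosed rings, rings with fewer than 4 positions)
#'   or `"warn"`.
#' @return object of class `svi_units`: list with `area_ids`, `features`
#'   (list of geometry objects in GeoJSON structure), `crs`.
#' @export
read_geometry <- function(path, id_field = "area_id",
                          on_invalid = c("reject", "warn")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path))
    svi_stop(paste0("geometry file not found: ", path), "svi_geo_error")
  if (grepl("\\.(gpkg|shp)$", tolower(path)))
    svi_stop(paste0("only GeoJSON geometry is supported; convert '",
                    basename(path), "' with e.g. ogr2ogr first"),
             "svi_geo_error")
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) svi_stop(
                    paste0("unreadable GeoJSON: ", conditionMessage(e)),
                    "svi_geo_error"))
  if (!identical(doc$type, "FeatureCollection") || is.null(doc$features))
    svi_stop("GeoJSON must be a FeatureCollection", "svi_geo_error")

  ids <- vapply(doc$features, function(f) {
    v <- f$properties[[id_field]]
    if (is.null(v)) NA_character_ else canon_id(v)
  }, "")
  if (anyNA(ids))
    svi_stop(paste0("id field '", id_field, "' missing on ",
                    sum(is.na(ids)), " feature(s)"), "svi_geo_error")
  if (anyDuplicated(ids))
    svi_stop(paste0("duplicate area id(s) in geometry: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "svi_geo_error")

  geoms <- lapply(doc$features, `[[`, "geometry")
  bad <- !vapply(geoms, geometry_structurally_valid, NA)
  if (any(bad)) {
    msg <- paste0("invalid geometry for area(s): ",
                  paste(ids[bad], collapse = ", "))
    if (on_invalid == "reject") svi_stop(msg, "svi_geo_error")
    warning(msg, call. = FALSE)
  }
  structure(list(area_ids = ids, features = geoms, crs = doc$crs),
            class = "svi_units")
}

# structural GeoJSON polygon validity: non-empty, closed rings, >=4 positions
geometry_structurally_valid <- function(g) {
  if (is.null(g) || is.null(g$type) || is.null(g$coordinates)) return(FALSE)
  ring_ok <- function(r) {
    length(r) >= 4L &&
      isTRUE(all.equal(unlist(r[[1]]), unlist(r[[length(r)]])))
  }
  if (g$type == "Polygon") {
    length(g$coordinates) > 0 && all(vapply(g$coordinates, ring_ok, NA))
  } else if (g$type == "MultiPolygon") {
    length(g$coordinates) > 0 &&
      all(vapply(g$coordinates, function(poly)
        length(poly) > 0 && all(vapply(poly, ring_ok, NA)), NA))
  } else FALSE
}

#' Join an index result onto area geometries and write GeoJSON
#'
#' One output feature per matched area, carrying the overall index, ordinal
#' class, tier and per-dimension scores as properties. Ids present on only
#' one side are reported, never silently dropped: the join report conserves
#' both id sets (matched + unmatched = all).
#'
#' @param result an `svi_result`.
#' @param units an `svi_units` from [read_geometry()].
#' @param out_path output GeoJSON path.
#' @return (invisibly) a `svi_join_report`: list with `matched`,
#'   `unmatched_result_ids`, `unmatched_geometry_ids`, `path`.
#' @export
join_and_export <- function(result, units, out_path) {
  stopifnot(inherits(result, "svi_result"), inherits(units, "svi_units"))
  matched <- intersect(result$area_ids, units$area_ids)
  if (!length(matched))
    svi_stop("no overlap between result and geometry area ids",
             "svi_join_error")
  features <- lapply(matched, function(id) {
    i <- match(id, result$area_ids)
    props <- list(area_id = id,
                  svi = unname(result$svi[i]),
                  class = as.character(result$class_label[i]),
                  tier = result$tier$tier)
    if (!is.null(result$dimension_scores))
      for (d in colnames(result$dimension_scores))
        props[[paste0("dimension_", d)]] <- unname(result$dimension_scores[i, d])
    list(type = "Feature", properties = props,
         geometry = units$features[[match(id, units$area_ids)]])
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(units$crs)) fc$crs <- units$crs
  jsonlite::write_json(fc, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  report <- structure(
    list(matched = matched,
         unmatched_result_ids = setdiff(result$area_ids, matched),
         unmatched_geometry_ids = setdiff(units$area_ids, matched),
         path = out_path),
    class = "svi_join_report"
  )
  invisible(report)
}

#' Square-grid area geometries for synthetic fixtures
#'
#' A unit-square grid of `n` cells (row-major, in the smallest enclosing
#' square), with ids matching the synthetic indicator tables.
#'
#' @param area_ids area identifiers, one cell each.
#' @return an `svi_units`.
#' @export
grid_units <- function(area_ids) {
  n <- length(area_ids)
  side <- ceiling(sqrt(n))
  feats <- lapply(seq_len(n) - 1L, function(i) {
    r <- i %/% side; c <- i %% side
    ring <- list(c(c, r), c(c + 1, r), c(c + 1, r + 1), c(c, r + 1), c(c, r))
    list(type = "Polygon", coordinates = list(ring))
  })
  structure(list(area_ids = canon_id(area_ids), features = feats, crs = NULL),
            class = "svi_units")
}

#' Write area geometries as a GeoJSON FeatureCollection
#' @param units an `svi_units`.
#' @param path output path.
#' @param id_field property name for the area identifier.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(units, path, id_field = "area_id") {
  stopifnot(inherits(units, "svi_units"))
  features <- lapply(seq_along(units$area_ids), function(i) {
    props <- list(); props[[id_field]] <- units$area_ids[i]
    list(type = "Feature", properties = props, geometry = units$features[[i]])
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(units$crs)) fc$crs <- units$crs
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
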