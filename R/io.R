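# GeoJSON and scene serialization. All coordinates are in one projected
# CRS; the scene manifest records the generating config and truth.

featureCollection <- function(features) {
  list(type = "FeatureCollection", features = features)
}

pointFeature <- function(x, y, properties) {
  list(type = "Feature",
       geometry = list(type = "Point", coordinates = c(x, y)),
       properties = properties)
}

lineFeature <- function(coords, properties) {
  list(type = "Feature",
       geometry = list(type = "LineString",
                       coordinates = lapply(seq_len(nrow(coords)),
                                            function(i) coords[i, ])),
       properties = properties)
}

writeGeoJson <- function(fc, path) {
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write road segments as GeoJSON
#'
#' LineString features with properties \code{segment_id},
#' \code{road_class}, \code{cell_id} plus any extra columns supplied.
#'
#' @param segments segment set from \code{\link{splitRoadsByGrid}}.
#' @param path output file.
#' @param extra optional data.frame of additional per-segment properties
#'   (matched by row).
#' @return the path, invisibly.
#' @export
writeSegmentsGeoJson <- function(segments, path, extra = NULL) {
  tab <- segments$table
  if (!is.null(extra)) tab <- cbind(tab, extra)
  feats <- lapply(seq_len(nrow(tab)), function(i)
    lineFeature(segments$geometry[[i]], as.list(tab[i, , drop = FALSE])))
  writeGeoJson(featureCollection(feats), path)
}

#' Read road segments from GeoJSON
#'
#' Inverse of \code{\link{writeSegmentsGeoJson}}.
#'
#' @param path GeoJSON file of LineString features.
#' @return a list with \code{table} and \code{geometry}.
#' @export
readSegmentsGeoJson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- lapply(fc$features, function(f)
    do.call(rbind, lapply(f$geometry$coordinates, unlist)))
  tab <- do.call(rbind, lapply(fc$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  list(table = tab, geometry = geoms)
}

writePointsGeoJson <- function(df, path) {
  props <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i)
    pointFeature(df$x[i], df$y[i],
                 if (length(props)) as.list(df[i, props, drop = FALSE])
                 else structure(list(), names = character(0))))
  writeGeoJson(featureCollection(feats), path)
}

#' Write a synthetic scene to a directory
#'
#' Rasters as ESRI ASCII grids, the network and point sets as GeoJSON,
#' the segment and traffic tables as CSV, and a JSON manifest recording
#' the config, truth and seed.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in scene@rasters)
    writeAsciiGrid(r, file.path(dir, paste0(r@name, ".asc")))
  writeAsciiGrid(scene@popdens, file.path(dir, "POPDENS.asc"))
  netFeats <- lapply(seq_along(scene@network@coords), function(i)
    lineFeature(scene@network@coords[[i]],
                list(road_id = i, road_class = scene@network@roadClass[i])))
  writeGeoJson(featureCollection(netFeats), file.path(dir, "network.geojson"))
  writeSegmentsGeoJson(scene@segments, file.path(dir, "segments.geojson"))
  writePointsGeoJson(scene@presences, file.path(dir, "presences.geojson"))
  writePointsGeoJson(scene@background, file.path(dir, "background.geojson"))
  writePointsGeoJson(scene@collisionRecords,
                     file.path(dir, "collision_records.geojson"))
  write.csv(scene@segmentTable, file.path(dir, "segments.csv"),
            row.names = FALSE)
  write.csv(scene@trafficObs, file.path(dir, "traffic_obs.csv"),
            row.names = FALSE)
  cfg <- scene@config
  manifest <- list(
    crs = "projected-meters (synthetic)",
    config = list(extent = cfg@extent, cell_size = cfg@cellSize,
                  covariates = cfg@covariateNames,
                  smoothing_scale = cfg@smoothingScale,
                  n_roads = cfg@nRoads,
                  road_class_mix = as.list(cfg@roadClassMix),
                  seed = cfg@seed),
    truth = list(occ_coefs = as.list(scene@truth@occCoefs),
                 vol_coefs = as.list(scene@truth@volCoefs),
                 vol_sigma = scene@truth@volSigma,
                 speed_by_class = as.list(scene@truth@speedByClass),
                 risk_coefs = as.list(riskBetas(scene@truth@riskCoefs))))
  jsonlite::write_json(manifest, file.path(dir, "scene_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Export the per-segment risk map
#'
#' Writes every segment's predicted collision probability together with its
#' inputs (O, V, S) as GeoJSON feature properties and as a flat CSV.
#' Values survive a write/read round trip to better than 1e-9.
#'
#' @param segments segment set from \code{\link{splitRoadsByGrid}}.
#' @param risk data.frame with columns \code{segment_id}, \code{O},
#'   \code{V}, \code{S}, \code{prob} (matched to segments by id).
#' @param pathGeoJson,pathCsv output files (either may be NULL to skip).
#' @return list of written paths, invisibly.
#' @export
exportRiskMap <- function(segments, risk, pathGeoJson = NULL,
                          pathCsv = NULL) {
  stopIfNot(!is.null(risk$prob), "missing predictions: risk$prob required")
  stopIfNot(all(risk$prob >= 0 & risk$prob < 1),
            "probabilities must lie in [0, 1)")
  i <- match(segments$table$segment_id, risk$segment_id)
  stopIfNot(!anyNA(i), "every segment needs a prediction")
  extra <- risk[i, c("O", "V", "S", "prob"), drop = FALSE]
  rownames(extra) <- NULL
  out <- list()
  if (!is.null(pathGeoJson))
    out$geojson <- writeSegmentsGeoJson(segments, pathGeoJson, extra)
  if (!is.null(pathCsv)) {
    write.csv(cbind(segments$table, extra), pathCsv, row.names = FALSE)
    out$csv <- pathCsv
  }
  invisible(out)
}

#' @rdname exportRiskMap
#' @param path a GeoJSON file written by \code{exportRiskMap}.
#' @return \code{readRiskMap} returns the segment table with risk columns.
#' @export
readRiskMap <- function(path) {
  readSegmentsGeoJson(path)$table
}
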