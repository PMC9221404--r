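# File formats: multi-page TIFF channel stacks, 16-bit label maps, GeoJSON
# polygons, CSV event/truth tables, YAML configs.

CHANNEL_ORDER <- c("dapi", "pe", "apc", "spare")

#' Write a channel stack as a multi-page TIFF
#'
#' One 16-bit page per channel in the order DAPI, PE, APC, spare.
#'
#' @param stack A `ChannelStack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ChannelStack"))
  pages <- lapply(CHANNEL_ORDER, function(ch) stack[[ch]] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read a channel stack from a multi-page TIFF
#'
#' Pages are interpreted in the order DAPI, PE, APC, spare; a missing spare
#' page is filled with zeros.
#'
#' @param path TIFF file with at least 3 pages of identical dimensions.
#' @param bit_depth Bit depth recorded on the returned stack.
#' @return A `ChannelStack`.
#' @export
read_channel_stack <- function(path, bit_depth = 12) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) {
    stop(sprintf("format error in '%s': expected >= 3 pages, found %d",
                 path, length(pages)), call. = FALSE)
  }
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop(sprintf("format error in '%s': pages differ in shape", path),
         call. = FALSE)
  }
  ch <- lapply(pages[seq_len(min(4, length(pages)))], function(m)
    matrix(round(m * 65535), nrow(m), ncol(m)))
  if (length(ch) < 4) {
    ch[[4]] <- matrix(0, nrow(ch[[1]]), ncol(ch[[1]]))
  }
  names(ch) <- CHANNEL_ORDER
  structure(c(ch, list(bit_depth = as.integer(bit_depth))),
            class = "ChannelStack")
}

#' Write / read a label map as 16-bit single-page TIFF
#'
#' Lossless round trip for label values up to 65,535.
#'
#' @param labels Integer label matrix.
#' @param path File path.
#' @return `path` invisibly (write); integer matrix (read).
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  if (max(labels) > 65535) {
    stop("label map exceeds 16-bit range (> 65,535 labels)", call. = FALSE)
  }
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path, all = FALSE)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Serialize star polygons to GeoJSON
#'
#' A FeatureCollection with one polygon feature per star polygon (exterior
#' ring = the K ray endpoints, closed; GeoJSON x = image column, y = image
#' row) and properties score, label and frame.
#'
#' @param polygons List of [star_polygon()] objects.
#' @param path Output `.geojson` path.
#' @param frame Frame index stored in the properties.
#' @param labels Label ids (default `seq_along(polygons)`).
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path, frame = 1L,
                                   labels = seq_along(polygons)) {
  features <- lapply(seq_along(polygons), function(i) {
    v <- poly_vertices(polygons[[i]])
    ring <- cbind(v[, "col"], v[, "row"])
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, identity,
                                                  simplify = FALSE))),
         properties = list(score = polygons[[i]]$score,
                           label = labels[i], frame = frame,
                           center_row = polygons[[i]]$center[1],
                           center_col = polygons[[i]]$center[2]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read star polygons from GeoJSON written by [write_polygons_geojson()]
#'
#' @param path `.geojson` path.
#' @return List of [star_polygon()] objects with attribute `labels`.
#' @export
read_polygons_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  stopifnot(identical(g$type, "FeatureCollection"))
  labs <- integer(length(g$features))
  polys <- lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    ring <- f$geometry$coordinates[[1]]
    ring <- ring[-length(ring)]  # drop closing vertex
    ctr <- c(f$properties$center_row, f$properties$center_col)
    v_row <- vapply(ring, function(p) p[[2]], numeric(1))
    v_col <- vapply(ring, function(p) p[[1]], numeric(1))
    labs[i] <<- f$properties$label
    star_polygon(ctr, sqrt((v_row - ctr[1])^2 + (v_col - ctr[2])^2),
                 f$properties$score)
  })
  attr(polys, "labels") <- labs
  polys
}

#' Write an event or candidate table as CSV
#'
#' Fixed column order (id, frame, row, col, area_px, dapi_mean, dapi_max,
#' pe_mean, pe_max, apc_mean, stained_pe_area_px, then gate columns if
#' present).
#'
#' @param events Event table.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  cols <- c("id", "frame", "row", "col", "area_px", "dapi_mean", "dapi_max",
            "pe_mean", "pe_max", "apc_mean", "stained_pe_area_px",
            "gate_pass", "failed_criteria")
  cols <- cols[cols %in% names(events)]
  utils::write.csv(events[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Write a heatmap grid as a PNG rendering
#'
#' @param counts Bin-count matrix (as from [edge_heatmap()]).
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(counts, path) {
  grDevices::png(path, width = 620, height = 500)
  on.exit(grDevices::dev.off())
  graphics::image(t(counts)[, nrow(counts):1],
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = "event positions per bin")
  invisible(path)
}
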