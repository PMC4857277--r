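# Contour exchange formats: long-format CSV (one row per vertex) and a
# GeoJSON FeatureCollection dialect (one Feature per contour).

component_of <- function(cs, comp, ring) {
  switch(comp, lumen = cs$lumen, intima = cs$intima_outer,
         media = cs$media_outer, adventitia = cs$adventitia_outer,
         nc = cs$ncs[[ring]])
}

#' Write cross-sections to a long-format contour CSV
#'
#' Columns: section_id, patient_id, artery_id, component, ring_index,
#' vertex_index, x_mm, y_mm; vertex order defines each polygon.
#'
#' @param sections a `cross_section` or list of them.
#' @param path output file.
#' @export
write_contours_csv <- function(sections, path) {
  if (inherits(sections, "cross_section")) sections <- list(sections)
  rows <- lapply(sections, function(cs) {
    blocks <- c(list(c("lumen", 1L), c("intima", 1L), c("media", 1L),
                     c("adventitia", 1L)),
                lapply(seq_along(cs$ncs), function(k) c("nc", k)))
    do.call(rbind, lapply(blocks, function(b) {
      xy <- component_of(cs, b[[1]], as.integer(b[[2]]))$xy
      data.frame(section_id = cs$section_id, patient_id = cs$patient_id,
                 artery_id = cs$artery_id, component = b[[1]],
                 ring_index = as.integer(b[[2]]),
                 vertex_index = seq_len(nrow(xy)),
                 x_mm = xy[, 1], y_mm = xy[, 2])
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read cross-sections from a contour CSV
#'
#' @param path file written in the dialect of [write_contours_csv()].
#' @param check validate nesting invariants per section.
#' @return list of `cross_section` objects.
#' @export
read_contours_csv <- function(path, check = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "patient_id", "artery_id", "component",
            "ring_index", "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, df$section_id), function(d) {
    poly <- function(comp, ring = 1L) {
      sub <- d[d$component == comp & d$ring_index == ring, ]
      sub <- sub[order(sub$vertex_index), ]
      contour(cbind(sub$x_mm, sub$y_mm),
              component = if (comp %in% c("intima", "media", "adventitia")) comp else comp,
              check = FALSE)
    }
    ncs <- lapply(sort(unique(d$ring_index[d$component == "nc"])),
                  function(k) poly("nc", k))
    cross_section(poly("lumen"), poly("intima"), poly("media"),
                  poly("adventitia"), ncs,
                  section_id = d$section_id[1], artery_id = d$artery_id[1],
                  patient_id = d$patient_id[1], check = check)
  })
}

#' Write cross-sections as a GeoJSON FeatureCollection
#'
#' One Feature per contour with properties section_id, patient_id, artery_id,
#' component, ring_index; coordinates in mm.
#'
#' @inheritParams write_contours_csv
#' @export
write_contours_geojson <- function(sections, path) {
  if (inherits(sections, "cross_section")) sections <- list(sections)
  feats <- list()
  for (cs in sections) {
    blocks <- c(list(c("lumen", 1L), c("intima", 1L), c("media", 1L),
                     c("adventitia", 1L)),
                lapply(seq_along(cs$ncs), function(k) c("nc", k)))
    for (b in blocks) {
      xy <- component_of(cs, b[[1]], as.integer(b[[2]]))$xy
      ring <- rbind(xy, xy[1, ])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(section_id = cs$section_id,
                          patient_id = cs$patient_id,
                          artery_id = cs$artery_id, component = b[[1]],
                          ring_index = as.integer(b[[2]])),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(i) ring[i, ]))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cross-sections from the GeoJSON dialect
#' @param path file written by [write_contours_geojson()].
#' @param check validate nesting invariants.
#' @return list of `cross_section` objects.
#' @export
read_contours_geojson <- function(path, check = TRUE) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  tab <- lapply(j$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                function(p) c(p[[1]], p[[2]])))
    if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    list(props = f$properties, xy = xy)
  })
  ids <- vapply(tab, function(x) x$props$section_id, character(1))
  lapply(split(tab, ids), function(fs) {
    get <- function(comp, ring = 1L) {
      hit <- Filter(function(x) x$props$component == comp &&
                      (x$props$ring_index %||% 1L) == ring, fs)
      contour(hit[[1]]$xy, comp, check = FALSE)
    }
    nrings <- sum(vapply(fs, function(x) x$props$component == "nc", logical(1)))
    p <- fs[[1]]$props
    cross_section(get("lumen"), get("intima"), get("media"), get("adventitia"),
                  lapply(seq_len(nrings), function(k) get("nc", k)),
                  section_id = p$section_id, artery_id = p$artery_id,
                  patient_id = p$patient_id, check = check)
  })
}
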