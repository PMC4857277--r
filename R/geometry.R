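#' @useDynLib plaqrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median coef lm pnorm quantile rnorm runif sd setNames var
#' @importFrom utils head tail write.csv read.csv
NULL

# ---- polygon primitives ----------------------------------------------------

#' Signed polygon area (shoelace)
#'
#' @param xy two-column matrix of vertices (closed implicitly; do not repeat
#'   the first vertex). Positive for counter-clockwise orientation.
#' @return signed area in the square of the coordinate unit (mm^2 here).
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area centroid
#'
#' @inheritParams polygon_area
#' @return numeric c(x, y).
#' @export
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon: area is zero")
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Force counter-clockwise orientation
#' @inheritParams polygon_area
#' @export
ensure_ccw <- function(xy) {
  if (polygon_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Simplicity check via Clipper: a simple polygon survives polysimplify with
# the same absolute area (to discretization tolerance).
polygon_is_simple <- function(xy, tol = 1e-6) {
  ps <- polyclip::polysimplify(list(list(x = xy[, 1], y = xy[, 2])))
  if (length(ps) != 1L) return(FALSE)
  a0 <- abs(polygon_area(xy))
  a1 <- abs(polygon_area(cbind(ps[[1]]$x, ps[[1]]$y)))
  abs(a1 - a0) <= tol * max(a0, 1e-12)
}

points_in_polygon <- function(px, py, xy) {
  sp::point.in.polygon(px, py, xy[, 1], xy[, 2]) > 0
}

# ---- contours and cross-sections -------------------------------------------

#' Construct a plaque contour
#'
#' A contour is a simple closed polygon (counter-clockwise) tagged with the
#' wall component it delineates.
#'
#' @param xy two-column matrix of vertex coordinates in mm.
#' @param component one of "lumen", "intima", "media", "adventitia", "nc".
#' @param check validate simplicity and area (disable for dense trusted input).
#' @return an object of class `plaque_contour`.
#' @export
contour <- function(xy, component = c("lumen", "intima", "media", "adventitia", "nc"),
                    check = TRUE) {
  component <- match.arg(component)
  xy <- as.matrix(xy)
  dimnames(xy) <- list(NULL, c("x", "y"))
  if (nrow(xy) < 3L) stop("contour needs at least 3 vertices")
  if (!all(is.finite(xy))) stop("contour has non-finite coordinates")
  xy <- ensure_ccw(xy)
  if (check) {
    if (polygon_area(xy) <= 0) stop("contour must have positive area")
    if (!polygon_is_simple(xy)) stop("contour is self-intersecting")
  }
  structure(list(xy = xy, component = component), class = "plaque_contour")
}

#' Assemble a plaque cross-section
#'
#' One histology-style slice: nested wall contours (lumen, outer intima,
#' outer media, outer adventitia) and 1-2 necrotic core polygons, with
#' identifiers for clustering (sections within artery within patient).
#'
#' @param lumen,intima_outer,media_outer,adventitia_outer `plaque_contour`s.
#' @param ncs list of 1-2 necrotic-core `plaque_contour`s.
#' @param section_id,artery_id,patient_id identifiers.
#' @param check run nesting/disjointness validation.
#' @return object of class `cross_section`.
#' @export
cross_section <- function(lumen, intima_outer, media_outer, adventitia_outer,
                          ncs, section_id = "s1", artery_id = "a1",
                          patient_id = "p1", check = TRUE) {
  if (inherits(ncs, "plaque_contour")) ncs <- list(ncs)
  cs <- structure(list(section_id = section_id, artery_id = artery_id,
                       patient_id = patient_id, lumen = lumen,
                       intima_outer = intima_outer, media_outer = media_outer,
                       adventitia_outer = adventitia_outer, ncs = ncs),
                  class = "cross_section")
  if (check) validate_cross_section(cs)
  cs
}

#' Validate cross-section nesting invariants
#'
#' Checks lumen < intima_outer < media_outer < adventitia_outer nesting,
#' necrotic cores inside the intima ring, and pairwise NC disjointness.
#' @param cs a `cross_section`.
#' @return invisibly TRUE; stops on violation.
#' @export
validate_cross_section <- function(cs) {
  inside <- function(a, b) # all vertices of a strictly inside polygon b
    all(sp::point.in.polygon(a$xy[, 1], a$xy[, 2], b$xy[, 1], b$xy[, 2]) == 1)
  if (!inside(cs$lumen, cs$intima_outer)) stop("lumen not inside intima_outer")
  if (!inside(cs$intima_outer, cs$media_outer)) stop("intima_outer not inside media_outer")
  if (!inside(cs$media_outer, cs$adventitia_outer)) stop("media_outer not inside adventitia_outer")
  if (length(cs$ncs) < 1L || length(cs$ncs) > 2L) stop("expected 1 or 2 necrotic cores")
  for (nc in cs$ncs) {
    if (!inside(nc, cs$intima_outer)) stop("necrotic core not inside intima_outer")
    if (any(sp::point.in.polygon(nc$xy[, 1], nc$xy[, 2],
                                 cs$lumen$xy[, 1], cs$lumen$xy[, 2]) == 1))
      stop("necrotic core overlaps the lumen")
  }
  if (length(cs$ncs) == 2L) {
    ov <- polyclip::polyclip(list(list(x = cs$ncs[[1]]$xy[, 1], y = cs$ncs[[1]]$xy[, 2])),
                             list(list(x = cs$ncs[[2]]$xy[, 1], y = cs$ncs[[2]]$xy[, 2])),
                             op = "intersection")
    if (length(ov) > 0) stop("necrotic cores overlap")
  }
  invisible(TRUE)
}

# ---- ray casting -----------------------------------------------------------

#' Lumen center of a cross-section
#'
#' The perspective point for all visibility and thickness measurements:
#' the area centroid of the lumen polygon.
#' @param cs a `cross_section`.
#' @return numeric c(x, y) in mm.
#' @export
lumen_center <- function(cs) {
  if (polygon_area(cs$lumen$xy) <= 0) stop("invalid geometry: lumen area <= 0")
  polygon_centroid(cs$lumen$xy)
}

# All intersections of the ray origin + t*(cos a, sin a), t > 0, with the
# edges of a polygon (closed = TRUE) or polyline (closed = FALSE).
# Intersections closer than merge_tol apart (vertex grazing) are merged.
ray_hits <- function(origin, angle, xy, closed = TRUE, merge_tol = 1e-9) {
  d <- c(cos(angle), sin(angle))
  x1 <- xy[, 1]; y1 <- xy[, 2]
  if (closed) { x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1]) }
  else { x2 <- x1[-1]; y2 <- y1[-1]; x1 <- x1[-length(x1)]; y1 <- y1[-length(y1)] }
  ex <- x2 - x1; ey <- y2 - y1
  # solve origin + t d = p1 + s e
  den <- d[1] * ey - d[2] * ex
  ok <- abs(den) > 1e-14
  t <- (( (x1 - origin[1]) * ey - (y1 - origin[2]) * ex ) / den)[ok]
  s <- (( (x1 - origin[1]) * d[2] - (y1 - origin[2]) * d[1] ) / den)[ok]
  keep <- t > 1e-12 & s >= -1e-12 & s < 1 - 1e-12
  t <- sort(t[keep])
  if (length(t) > 1L) t <- t[c(TRUE, diff(t) > merge_tol)]
  t
}

#' First intersection of a ray with a contour
#'
#' Casts a ray from `origin` at `angle` (radians, CCW from +x) and returns the
#' nearest boundary intersection plus the full ordered intersection list,
#' which downstream code uses to separate front from back side.
#'
#' @param origin numeric c(x, y).
#' @param angle radians.
#' @param contour a `plaque_contour` or a two-column matrix.
#' @return list(point, distance, all_distances); `distance` is NA on a miss.
#' @export
ray_first_hit <- function(origin, angle, contour) {
  xy <- if (inherits(contour, "plaque_contour")) contour$xy else contour
  t <- ray_hits(origin, angle, xy, closed = TRUE)
  if (length(t) == 0L)
    return(list(point = c(NA_real_, NA_real_), distance = NA_real_,
                all_distances = numeric(0)))
  list(point = origin + t[1] * c(cos(angle), sin(angle)),
       distance = t[1], all_distances = t)
}

# wrap angle difference to (-pi, pi]
ang_wrap <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Front side of a necrotic core as seen from the lumen center
#'
#' For every NC boundary vertex a ray is drawn from the lumen center; the
#' vertex is retained only when it is the first intersection of that ray with
#' the NC boundary. Retained vertices, ordered by ray angle, form the front
#' polyline; their angular extent is the NC angle.
#'
#' @param cs a `cross_section`.
#' @param nc one of `cs$ncs` (a `plaque_contour`), or a two-column matrix.
#' @param tol visibility tolerance in mm.
#' @param closed treat `nc` as a closed polygon (TRUE, the NC boundary) or as
#'   an open polyline (FALSE, e.g. a previously extracted front).
#' @return list with `polyline` (matrix, ordered by angle), `angles`
#'   (per-vertex ray angles), `span` c(min, max) in unwrapped radians,
#'   `nc_angle` (span width, rad), and `center`.
#' @export
nc_front_side <- function(cs, nc, tol = 1e-7, closed = TRUE) {
  xy <- if (inherits(nc, "plaque_contour")) nc$xy else nc
  ctr <- lumen_center(cs)
  dx <- xy[, 1] - ctr[1]; dy <- xy[, 2] - ctr[2]
  th <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  vis <- vapply(seq_len(nrow(xy)), function(i) {
    t <- ray_hits(ctr, th[i], xy, closed = closed)
    # a grazing ray that records no edge hit leaves the vertex itself as the
    # only boundary point on the ray: trivially first
    length(t) == 0L || r[i] <= t[1] + tol
  }, logical(1))
  if (sum(vis) < 3L) stop("reconstruction impossible: fewer than 3 visible vertices")
  # unwrap angles about the circular mean direction of visible vertices
  mu <- atan2(mean(sin(th[vis])), mean(cos(th[vis])))
  dth <- ang_wrap(th - mu)
  o <- order(dth[vis], r[vis]) # ties at identical angle: nearer vertex first
  poly <- xy[vis, , drop = FALSE][o, , drop = FALSE]
  a <- (mu + dth[vis][o])
  rv <- r[vis][o]
  # vertices sharing a ray (e.g. radial end edges): keep only the nearest
  dup <- duplicated(round(a, 9))
  if (any(dup)) { poly <- poly[!dup, , drop = FALSE]; a <- a[!dup]; rv <- rv[!dup] }
  if (nrow(poly) < 3L) stop("reconstruction impossible: fewer than 3 visible vertices")
  list(polyline = poly, angles = a, span = range(a),
       nc_angle = diff(range(a)), center = ctr)
}

# distance from lumen center to the front polyline along a ray; NA on miss
front_hit_dist <- function(front, angle) {
  t <- ray_hits(front$center, angle, front$polyline, closed = FALSE)
  if (length(t) == 0L) NA_real_ else t[1]
}

#' Thickness measurements at midcap and sidecap rays
#'
#' Measures cap thickness (capT), intima-media thickness (IMT), necrotic core
#' thickness (NCt) and the relative NC thickness rNCt = NCt / IMT along rays
#' at 25%, 50% and 75% of the NC angle from the lumen center.
#'
#' @param cs a `cross_section`.
#' @param nc NC contour, or NULL when only the front polyline exists (then
#'   NCt = 0, as for a reconstructed-input geometry with no backside).
#' @param front result of [nc_front_side()]; computed from `nc` when missing.
#' @return data.frame with one row per site (minus_sidecap, midcap,
#'   plus_sidecap): ray_angle, capT, IMT, NCt, rNCt (mm, rad).
#' @export
site_measurements <- function(cs, nc = NULL, front = NULL) {
  if (is.null(front)) {
    if (is.null(nc)) stop("need an NC contour or a front polyline")
    front <- nc_front_side(cs, nc)
  }
  ctr <- front$center
  fr <- front$span[1] + c(0.25, 0.5, 0.75) * front$nc_angle
  site <- c("minus_sidecap", "midcap", "plus_sidecap")
  out <- lapply(seq_along(fr), function(i) {
    a <- fr[i]
    t_lum <- ray_hits(ctr, a, cs$lumen$xy)
    t_med <- ray_hits(ctr, a, cs$media_outer$xy)
    t_fro <- front_hit_dist(front, a)
    if (length(t_lum) == 0L || length(t_med) == 0L || is.na(t_fro))
      stop("invalid geometry: site ray misses a required contour")
    nct <- 0
    if (!is.null(nc)) {
      xy <- if (inherits(nc, "plaque_contour")) nc$xy else nc
      t_nc <- ray_hits(ctr, a, xy, closed = TRUE)
      if (length(t_nc) >= 2L) nct <- max(t_nc) - min(t_nc)
    }
    imt <- t_med[1] - t_lum[1]
    data.frame(site = site[i], ray_angle = a, capT = t_fro - t_lum[1],
               IMT = imt, NCt = nct, rNCt = nct / imt)
  })
  do.call(rbind, out)
}

#' Minimum cap thickness over the NC front span
#'
#' Searches a dense angular sampling (default step 0.25 degrees) of the NC
#' front span for the smallest radial distance from the lumen boundary to the
#' NC front.
#'
#' @inheritParams site_measurements
#' @param step_deg angular search step in degrees.
#' @return list(min_capT, location, angle).
#' @export
min_cap_thickness <- function(cs, nc = NULL, front = NULL, step_deg = 0.25) {
  if (is.null(front)) front <- nc_front_side(cs, nc)
  ctr <- front$center
  n <- max(3L, ceiling(front$nc_angle / (step_deg * pi / 180)))
  as <- seq(front$span[1], front$span[2], length.out = n + 1L)
  capt <- vapply(as, function(a) {
    t_lum <- ray_hits(ctr, a, cs$lumen$xy)
    tf <- front_hit_dist(front, a)
    if (length(t_lum) == 0L || is.na(tf)) NA_real_ else tf - t_lum[1]
  }, numeric(1))
  i <- which.min(capt)
  tf <- front_hit_dist(front, as[i])
  list(min_capT = capt[i],
       location = ctr + tf * c(cos(as[i]), sin(as[i])),
       angle = as[i])
}

#' Full morphometric characterization of a cross-section
#'
#' Runs front-side extraction, site measurements and minimum cap thickness
#' for every necrotic core in the section.
#'
#' @param cs a `cross_section`.
#' @return list of per-NC feature sets (class `plaque_features`): min_capT,
#'   nc_angle (rad), sites data.frame, lumen_center, section/artery/patient
#'   ids, nc_index.
#' @export
characterize <- function(cs) {
  lapply(seq_along(cs$ncs), function(k) {
    front <- nc_front_side(cs, cs$ncs[[k]])
    mc <- min_cap_thickness(cs, front = front)
    structure(list(section_id = cs$section_id, artery_id = cs$artery_id,
                   patient_id = cs$patient_id, nc_index = k,
                   min_capT = mc$min_capT, min_capT_location = mc$location,
                   nc_angle = front$nc_angle,
                   sites = site_measurements(cs, cs$ncs[[k]], front),
                   lumen_center = front$center, front = front),
              class = "plaque_features")
  })
}

#' Flatten characterization output to a feature table
#'
#' @param features list of `plaque_features` (possibly nested per section).
#' @return data.frame, one row per (section, NC): ids, min_capT_mm,
#'   nc_angle_deg, and capT/IMT/NCt/rNCt at midcap and both sidecaps.
#' @export
features_table <- function(features) {
  if (inherits(features, "plaque_features")) features <- list(features)
  features <- unlist_features(features)
  rows <- lapply(features, function(f) {
    s <- f$sites
    g <- function(col, site) s[[col]][s$site == site]
    data.frame(section_id = f$section_id, artery_id = f$artery_id,
               patient_id = f$patient_id, nc_index = f$nc_index,
               min_capT_mm = f$min_capT, nc_angle_deg = f$nc_angle * 180 / pi,
               capT_mid = g("capT", "midcap"), IMT_mid = g("IMT", "midcap"),
               NCt_mid = g("NCt", "midcap"), rNCt_mid = g("rNCt", "midcap"),
               capT_side = mean(c(g("capT", "minus_sidecap"), g("capT", "plus_sidecap"))),
               IMT_side = mean(c(g("IMT", "minus_sidecap"), g("IMT", "plus_sidecap"))),
               NCt_side = mean(c(g("NCt", "minus_sidecap"), g("NCt", "plus_sidecap"))),
               rNCt_side = mean(c(g("rNCt", "minus_sidecap"), g("rNCt", "plus_sidecap"))))
  })
  do.call(rbind, rows)
}

unlist_features <- function(x) {
  if (inherits(x, "plaque_features")) return(list(x))
  out <- list()
  for (el in x) out <- c(out, if (inherits(el, "plaque_features")) list(el) else unlist_features(el))
  out
}
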