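# Backside reconstruction of a necrotic core from its front polyline:
# back points from rNCt estimates at the three measurement rays, rounded
# edge arcs (30 deg extent, radius 0.14 mm/rad x NC angle), polynomial
# closure of the backside, and clipping to the intima with a 10 um clearance.

#' Reconstruction parameters
#'
#' @param arc_angle angular extent of the edge arcs, rad (default 30 deg).
#' @param arc_radius_coeff edge-arc radius per radian of NC angle, mm/rad.
#' @param media_clearance minimum clearance kept between the reconstructed NC
#'   and the outer intima border, mm (default 10 um).
#' @param closure_degree degree of the backside closure polynomial; 4 fits
#'   the five closure points exactly.
#' @param circle1_radius radius of the construction circles used to locate
#'   the edge-arc center; NULL uses the final arc radius.
#' @param backside_samples vertices sampled along the closure polynomial.
#' @return object of class `reconstruction_params`.
#' @export
reconstruction_params <- function(arc_angle = 30 * pi / 180,
                                  arc_radius_coeff = 0.14,
                                  media_clearance = 0.010,
                                  closure_degree = 4L,
                                  circle1_radius = NULL,
                                  backside_samples = 80L) {
  stopifnot(arc_angle > 0, arc_radius_coeff > 0, media_clearance >= 0)
  structure(as.list(environment()), class = "reconstruction_params")
}

#' Place backside points on the measurement rays
#'
#' Converts relative NC thickness estimates to absolute thickness (rNCt x IMT)
#' and places one back point on each site ray, radially behind the front hit.
#'
#' @param cs the `cross_section` (front-only: its wall contours are used, the
#'   NC backside is not).
#' @param front result of [nc_front_side()].
#' @param rnct length-2 c(mid, side) or length-3 c(minus_side, mid, plus_side)
#'   relative NC thickness estimates.
#' @return list(points = 3x2 matrix (minus_side, mid, plus_side rows),
#'   sites = site measurement data.frame, nct = absolute thicknesses mm).
#' @export
back_points <- function(cs, front, rnct) {
  sites <- site_measurements(cs, nc = NULL, front = front)
  r3 <- if (length(rnct) == 2L) c(rnct[2], rnct[1], rnct[2]) else rnct
  stopifnot(length(r3) == 3L)
  ctr <- front$center
  pts <- t(vapply(1:3, function(i) {
    a <- sites$ray_angle[i]
    t_lum <- ray_hits(ctr, a, cs$lumen$xy)[1]
    t_front <- t_lum + sites$capT[i]
    nct <- r3[i] * sites$IMT[i]
    ctr + (t_front + nct) * c(cos(a), sin(a))
  }, numeric(2)))
  list(points = pts, sites = sites,
       nct = r3 * sites$IMT)
}

# circle (center c0, radius r) intersections with an open polyline;
# returns matrix of points (possibly 0 rows)
circle_polyline_hits <- function(c0, r, poly) {
  out <- NULL
  for (i in seq_len(nrow(poly) - 1L)) {
    p1 <- poly[i, ]; d <- poly[i + 1L, ] - p1
    f <- p1 - c0
    a <- sum(d * d); b <- 2 * sum(f * d); cc <- sum(f * f) - r^2
    disc <- b^2 - 4 * a * cc
    if (a < 1e-20 || disc < 0) next
    for (s in (-b + c(-1, 1) * sqrt(disc)) / (2 * a))
      if (s >= -1e-9 && s <= 1 + 1e-9) out <- rbind(out, p1 + s * d)
  }
  out
}

#' Construct one rounded edge arc of the reconstructed NC
#'
#' Implements the published circle construction: circle 1 is centered on the
#' NC front edge vertex; its intersection with the cap (the front polyline
#' extended to the lumen along the edge ray) is the center of circle 2; of
#' the two intersection points of circles 1 and 2, the one most distant from
#' the lumen center is the center of the final arc. The arc has radius
#' `arc_radius_coeff x NC angle` and the configured angular extent, starts at
#' the edge vertex, and sweeps around the NC end toward the backside.
#'
#' @param cs the `cross_section`.
#' @param front result of [nc_front_side()].
#' @param which "left" (span minimum side) or "right" (span maximum side).
#' @param params [reconstruction_params()].
#' @return list(arc = polyline from the edge vertex to the free end,
#'   center, radius, fallback = logical).
#' @export
edge_arc <- function(cs, front, which = c("left", "right"),
                     params = reconstruction_params()) {
  which <- match.arg(which)
  ctr <- front$center
  R <- params$arc_radius_coeff * front$nc_angle
  r1 <- params$circle1_radius %||% R
  n <- nrow(front$polyline)
  E <- if (which == "left") front$polyline[1, ] else front$polyline[n, ]
  a_edge <- if (which == "left") front$span[1] else front$span[2]
  fallback <- FALSE
  O <- NULL
  # the cap boundary circle 1 intersects: primarily the NC front polyline
  # (the back of the cap); the radial extension from the edge vertex to the
  # lumen boundary is the fallback when the front is shorter than the radius
  t_lum <- ray_hits(ctr, a_edge, cs$lumen$xy)[1]
  lum_pt <- ctr + t_lum * c(cos(a_edge), sin(a_edge))
  hits <- circle_polyline_hits(E, r1, front$polyline)
  if (is.null(hits) || nrow(hits) == 0L)
    hits <- circle_polyline_hits(E, r1, rbind(lum_pt, E))
  if (!is.null(hits) && nrow(hits) > 0L) {
    # circle-2 center: the first crossing encountered walking the cap
    # boundary away from the edge vertex
    P <- if (which == "left") hits[1L, ] else hits[nrow(hits), ]
    # circles 1 and 2 (radius r1 each, centers r1 apart) intersect at two
    # points; keep the one farther from the lumen center
    d12 <- sqrt(sum((P - E)^2))
    if (d12 > 1e-12 && d12 < 2 * r1) {
      mid <- (E + P) / 2
      h <- sqrt(r1^2 - (d12 / 2)^2)
      u <- (P - E) / d12
      perp <- c(-u[2], u[1])
      cand <- rbind(mid + h * perp, mid - h * perp)
      dc <- sqrt(rowSums((cand - matrix(ctr, 2, 2, byrow = TRUE))^2))
      O <- cand[which.max(dc), ]
    }
  }
  sweep <- params$arc_angle
  if (is.null(O)) {
    # degenerate edge: quarter-arc about a center placed radially outward
    fallback <- TRUE
    u <- (E - ctr) / sqrt(sum((E - ctr)^2))
    O <- E + R * u
    sweep <- pi / 2
  }
  phi0 <- atan2(E[2] - O[2], E[1] - O[1])
  r_arc <- sqrt(sum((E - O)^2))
  if (r_arc < 1e-9) r_arc <- R
  arc_pts <- function(sgn) {
    ph <- phi0 + sgn * seq(0, sweep, length.out = 12L)
    cbind(O[1] + r_arc * cos(ph), O[2] + r_arc * sin(ph))
  }
  # sweep around the NC end: the arc must move angularly beyond the span
  score <- function(a) {
    end <- a[nrow(a), ]
    ang <- atan2(end[2] - ctr[2], end[1] - ctr[1])
    off <- ang_wrap(ang - a_edge)
    if (which == "left") -off else off
  }
  cand <- list(arc_pts(1), arc_pts(-1))
  arc <- cand[[which.max(vapply(cand, score, numeric(1)))]]
  arc[1, ] <- E  # exact attachment
  list(arc = arc, center = O, radius = r_arc, fallback = fallback)
}

#' Close the backside with a polynomial through the closure points
#'
#' In a local frame whose abscissa is the chord between the two arc free
#' ends, fits the unique degree-4 polynomial through the five closure points
#' (two arc free ends + three back points), samples it densely, and
#' assembles the closed NC polygon front + right arc + backside + left arc.
#' If the polygon self-intersects, degree 2 (least squares through the back
#' points, exact at the arc ends) is retried.
#'
#' @param front result of [nc_front_side()].
#' @param arc_left,arc_right results of [edge_arc()].
#' @param bpts 3x2 matrix of back points.
#' @param params [reconstruction_params()].
#' @return list(xy = closed CCW polygon matrix, degree_used).
#' @export
close_backside <- function(front, arc_left, arc_right, bpts,
                           params = reconstruction_params()) {
  pL <- arc_left$arc[nrow(arc_left$arc), ]
  pR <- arc_right$arc[nrow(arc_right$arc), ]
  chord <- pR - pL
  len <- sqrt(sum(chord^2))
  if (len < 1e-9) stop("reconstruction failed: arc free ends coincide")
  u <- chord / len; v <- c(-u[2], u[1])
  to_local <- function(p) c(sum((p - pL) * u), sum((p - pL) * v))
  pts <- rbind(to_local(pL), t(apply(bpts, 1, to_local)), to_local(pR))
  o <- order(pts[, 1])
  pts <- pts[o, ]
  backside_world <- function(degree) {
    xs <- seq(0, len, length.out = params$backside_samples)
    if (degree >= 4L && !anyDuplicated(round(pts[, 1], 9))) {
      Vm <- outer(pts[, 1], 0:4, `^`)
      cf <- solve(Vm, pts[, 2])
      ys <- drop(outer(xs, 0:4, `^`) %*% cf)
    } else {
      # quadratic exact at the chord ends, least squares over the back points
      lin <- function(x) pts[1, 2] + (pts[nrow(pts), 2] - pts[1, 2]) * x / len
      q <- function(x) x * (x - len)
      mid <- pts[2:(nrow(pts) - 1L), , drop = FALSE]
      cc <- sum(q(mid[, 1]) * (mid[, 2] - lin(mid[, 1]))) / sum(q(mid[, 1])^2)
      ys <- lin(xs) + cc * q(xs)
    }
    cbind(pL[1] + xs * u[1] + ys * v[1], pL[2] + xs * u[2] + ys * v[2])
  }
  assemble <- function(degree) {
    back <- backside_world(degree)
    # walk: front left->right, right arc out, backside right->left, left arc in
    xy <- rbind(front$polyline,
                arc_right$arc[-1, , drop = FALSE],
                back[rev(seq_len(nrow(back))), ],
                arc_left$arc[rev(seq_len(nrow(arc_left$arc)))[-nrow(arc_left$arc)], , drop = FALSE])
    xy <- xy[c(TRUE, rowSums(abs(diff(xy))) > 1e-12), , drop = FALSE]
    if (sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2)) < 1e-12) xy <- xy[-nrow(xy), ]
    ensure_ccw(xy)
  }
  for (deg in unique(c(params$closure_degree, 2L))) {
    xy <- assemble(deg)
    if (polygon_area(xy) > 0 && polygon_is_simple(xy, tol = 1e-4))
      return(list(xy = xy, degree_used = deg))
  }
  # last resort for strongly curved fronts with a thin core: fit the closure
  # polynomial as radius vs angle about the lumen center and keep the backside
  # strictly behind the front, which guarantees a simple polygon
  ctr <- front$center
  mid <- mean(front$span)
  p5 <- rbind(pL, bpts, pR)
  a5 <- ang_wrap(atan2(p5[, 2] - ctr[2], p5[, 1] - ctr[1]) - mid)
  r5 <- sqrt(rowSums((p5 - matrix(ctr, 5, 2, byrow = TRUE))^2))
  o <- order(a5); a5 <- a5[o]; r5 <- r5[o]
  if (!anyDuplicated(round(a5, 9))) {
    cf <- try(solve(outer(a5, 0:4, `^`), r5), silent = TRUE)
    if (!inherits(cf, "try-error")) {
      aa <- seq(a5[1], a5[5], length.out = params$backside_samples)
      rr <- drop(outer(aa, 0:4, `^`) %*% cf)
      r_ends <- sqrt(rowSums((front$polyline[c(1L, nrow(front$polyline)), ] -
                              matrix(ctr, 2, 2, byrow = TRUE))^2))
      floor_r <- vapply(aa, function(da) {
        fh <- front_hit_dist(front, mid + da)
        if (!is.na(fh)) return(fh + 0.005)
        # beyond the span: guard the front corners
        (if (da < 0) r_ends[1] else r_ends[2]) + 0.005
      }, numeric(1))
      rr <- pmax(rr, floor_r)
      back <- cbind(ctr[1] + rr * cos(mid + aa), ctr[2] + rr * sin(mid + aa))
      xy <- rbind(front$polyline,
                  arc_right$arc[-1, , drop = FALSE],
                  back[rev(seq_len(nrow(back))), ],
                  arc_left$arc[rev(seq_len(nrow(arc_left$arc)))[-nrow(arc_left$arc)], , drop = FALSE])
      xy <- xy[c(TRUE, rowSums(abs(diff(xy))) > 1e-12), , drop = FALSE]
      if (sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2)) < 1e-12) xy <- xy[-nrow(xy), ]
      xy <- ensure_ccw(xy)
      if (polygon_area(xy) > 0 && polygon_is_simple(xy, tol = 1e-4))
        return(list(xy = xy, degree_used = NA_integer_))
    }
  }
  # final repair: resolve the self-intersection with Clipper and keep the
  # dominant piece when the crossings only clip small corner slivers
  xy <- assemble(params$closure_degree)
  ps <- polyclip::polysimplify(list(list(x = xy[, 1], y = xy[, 2])))
  if (length(ps) >= 1L) {
    areas <- vapply(ps, function(p) abs(polygon_area(cbind(p$x, p$y))), numeric(1))
    if (max(areas) >= 0.8 * sum(areas)) {
      best <- ps[[which.max(areas)]]
      return(list(xy = ensure_ccw(cbind(best$x, best$y)),
                  degree_used = NA_integer_))
    }
  }
  stop("reconstruction failed: closure polygon self-intersects at all degrees")
}

#' Clip a reconstructed NC to the intima with a clearance layer
#'
#' Intersects the NC polygon with the outer intima region shrunk inward by
#' `clearance`; an NC that never reaches the boundary is returned unchanged.
#'
#' @param nc_xy NC polygon matrix.
#' @param intima_outer_xy outer intima border polygon matrix.
#' @param clearance clearance in mm (default 10 um).
#' @return list(xy, clipped = logical).
#' @export
clip_media <- function(nc_xy, intima_outer_xy, clearance = 0.010) {
  shrunk <- polyclip::polyoffset(list(list(x = intima_outer_xy[, 1],
                                           y = intima_outer_xy[, 2])),
                                 -clearance, jointype = "round")
  if (length(shrunk) == 0L) stop("reconstruction failed: clearance exceeds intima")
  sh <- lapply(shrunk, function(p) cbind(p$x, p$y))
  inside <- all(vapply(seq_len(nrow(nc_xy)), function(i)
    any(vapply(sh, function(p) points_in_polygon(nc_xy[i, 1], nc_xy[i, 2], p),
               logical(1))), logical(1)))
  if (inside) return(list(xy = nc_xy, clipped = FALSE))
  out <- polyclip::polyclip(list(list(x = nc_xy[, 1], y = nc_xy[, 2])),
                            shrunk, op = "intersection")
  if (length(out) == 0L) stop("reconstruction failed: NC entirely outside intima")
  areas <- vapply(out, function(p) abs(polygon_area(cbind(p$x, p$y))), numeric(1))
  best <- out[[which.max(areas)]]
  list(xy = ensure_ccw(cbind(best$x, best$y)), clipped = TRUE)
}

#' Reconstruct the backside of a necrotic core
#'
#' Orchestrates rNCt lookup/prediction, back-point placement, edge arcs,
#' polynomial closure and media clipping for one NC front.
#'
#' @param cs the `cross_section` supplying wall contours.
#' @param front result of [nc_front_side()] for the NC being reconstructed.
#' @param method "group_average" (uses `averages` = list(rnct_mid,
#'   rnct_side)), "plaque_specific" (uses `coeffs` = `gee_coefficients`
#'   pair list(mid =, side =)), or "oracle" (uses `rnct` directly).
#' @param averages,coeffs,rnct method inputs; see `method`.
#' @param params [reconstruction_params()].
#' @return object of class `reconstruction_result`: nc_polygon (`plaque_contour`),
#'   method, rnct_used, clipped_to_media, arc_fallback, degree_used, params.
#' @export
reconstruct <- function(cs, front,
                        method = c("group_average", "plaque_specific", "oracle"),
                        averages = NULL, coeffs = NULL, rnct = NULL,
                        params = reconstruction_params()) {
  method <- match.arg(method)
  sites <- site_measurements(cs, nc = NULL, front = front)
  rnct_used <- switch(method,
    group_average = {
      if (is.null(averages)) stop("group_average needs `averages`")
      c(averages$rnct_side, averages$rnct_mid, averages$rnct_side)
    },
    plaque_specific = {
      if (is.null(coeffs)) stop("plaque_specific needs `coeffs` = list(mid=, side=)")
      ang <- front$nc_angle
      p_of <- function(cf, i) predict_rnct(cf, ang, sites$IMT[i] * 1000,
                                           sites$capT[i] * 1000)
      c(p_of(coeffs$side, 1L), p_of(coeffs$mid, 2L), p_of(coeffs$side, 3L))
    },
    oracle = {
      if (is.null(rnct)) stop("oracle needs `rnct`")
      if (length(rnct) == 2L) c(rnct[2], rnct[1], rnct[2]) else rnct
    })
  bp <- back_points(cs, front, rnct_used)
  # a core much thinner than the edge arc cannot be wrapped by it; retry with
  # a reduced construction radius before giving up (flagged in provenance)
  shrink <- 1
  cl <- aL <- aR <- NULL
  for (s in c(1, 0.5, 0.25)) {
    pr <- params
    R0 <- params$arc_radius_coeff * front$nc_angle
    pr$circle1_radius <- (params$circle1_radius %||% R0) * s
    pr$arc_radius_coeff <- params$arc_radius_coeff * s
    aL <- edge_arc(cs, front, "left", pr)
    aR <- edge_arc(cs, front, "right", pr)
    cl <- tryCatch(close_backside(front, aL, aR, bp$points, pr),
                   error = function(e) NULL)
    if (!is.null(cl)) { shrink <- s; break }
  }
  if (is.null(cl))
    stop("reconstruction failed: closure polygon self-intersects at all degrees")
  clip <- clip_media(cl$xy, cs$intima_outer$xy, params$media_clearance)
  structure(list(nc_polygon = contour(clip$xy, "nc", check = FALSE),
                 method = method, rnct_used = rnct_used,
                 clipped_to_media = clip$clipped,
                 arc_fallback = c(left = aL$fallback, right = aR$fallback),
                 arc_shrink = shrink,
                 degree_used = cl$degree_used, params = params),
            class = "reconstruction_result")
}
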