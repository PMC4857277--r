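# Geometry agreement scores between ground-truth and reconstructed NCs, and
# classification of peak-cap-stress location shifts.

#' Dice-type similarity index and area mismatch between two polygons
#'
#' SI = 2|A_GT intersect A_rec| / (|A_GT| + |A_rec|); the area mismatch is
#' normalized by the ground-truth area: dA% = |A_rec - A_GT| / A_GT x 100.
#'
#' @param gt ground-truth polygon (`plaque_contour` or matrix).
#' @param rec reconstructed polygon.
#' @return list(si, delta_a_pct, a_gt, a_rec, overlap) in mm^2 where
#'   applicable.
#' @export
similarity_index <- function(gt, rec) {
  g <- if (inherits(gt, "plaque_contour")) gt$xy else gt
  r <- if (inherits(rec, "plaque_contour")) rec$xy else rec
  a_gt <- abs(polygon_area(g)); a_rec <- abs(polygon_area(r))
  if (a_gt + a_rec <= 0) stop("zero total area")
  ov <- polyclip::polyclip(list(list(x = g[, 1], y = g[, 2])),
                           list(list(x = r[, 1], y = r[, 2])),
                           op = "intersection")
  overlap <- if (length(ov) == 0L) 0 else
    sum(vapply(ov, function(p) abs(polygon_area(cbind(p$x, p$y))), numeric(1)))
  list(si = 2 * overlap / (a_gt + a_rec),
       delta_a_pct = abs(a_rec - a_gt) / a_gt * 100,
       a_gt = a_gt, a_rec = a_rec, overlap = overlap)
}

#' Classify the shift between two peak-cap-stress locations
#'
#' Categories follow the published taxonomy: colocalized (below threshold),
#' shift from one side of the NC to the other, shift on the same side, or
#' radial translocation between the lumen border and the NC front.
#'
#' @param loc_gt,loc_rec c(x, y) peak stress locations (ground truth,
#'   reconstruction).
#' @param cs the `cross_section`.
#' @param front [nc_front_side()] result for the NC concerned.
#' @param threshold_mm colocalization distance threshold (default 0.05 mm).
#' @param shoulder_deg angular half-width of the shoulder regions beyond the
#'   NC span, degrees.
#' @return list(distance, category).
#' @export
classify_pcs_shift <- function(loc_gt, loc_rec, cs, front, threshold_mm = 0.05,
                               shoulder_deg = 15) {
  ctr <- front$center
  mid <- mean(front$span)
  ext <- shoulder_deg * pi / 180
  info <- function(p) {
    a <- atan2(p[2] - ctr[2], p[1] - ctr[1])
    off <- ang_wrap(a - mid)
    if (abs(off) > front$nc_angle / 2 + ext + 1e-9)
      stop("PCS location outside the cap + shoulder span")
    r <- sqrt(sum((p - ctr)^2))
    t_lum <- ray_hits(ctr, a, cs$lumen$xy)[1]
    tf <- front_hit_dist(front, a)
    capt <- if (is.na(tf)) NA_real_ else tf - t_lum
    # radial position within the cap: 0 at lumen border, 1 at NC front
    frac <- if (is.na(capt) || capt <= 0) NA_real_ else (r - t_lum) / capt
    list(off = off, frac = frac)
  }
  d <- sqrt(sum((loc_gt - loc_rec)^2))
  if (d <= threshold_mm)
    return(list(distance = d, category = "colocalized"))
  i1 <- info(loc_gt); i2 <- info(loc_rec)
  category <- if (sign(i1$off) != sign(i2$off) &&
                  abs(i1$off - i2$off) > front$nc_angle / 4) {
    "side_to_side"
  } else if (!is.na(i1$frac) && !is.na(i2$frac) &&
             ((i1$frac < 0.25 && i2$frac > 0.75) ||
              (i2$frac < 0.25 && i1$frac > 0.75))) {
    "lumen_nc_translocation"
  } else "same_side"
  list(distance = d, category = category)
}
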