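# Synthetic plaque cross-sections emulating the published cohort morphometry:
# min cap thickness 0.20 mm (IQR 0.09-0.40), NC angle 54 deg (35-75),
# midcap capT/IMT/NCt 0.30/1.05/0.46 mm, sidecap 0.31/1.03/0.36 mm,
# 1-2 NCs per section, sections clustered within arteries.

#' Idealized plaque specification
#'
#' Parameterizes one deterministic cross-section: a circular lumen, wall rings
#' whose thickness follows a smooth angular profile peaking at the plaque, and
#' a necrotic core built as an annular band with elliptically rounded ends.
#'
#' @param lumen_radius lumen radius, mm.
#' @param nc_angle angular span of the NC front, rad (must be in (10, 170) deg).
#' @param nc_center_angle direction of the NC center from the lumen center, rad.
#' @param capT_mid,capT_side cap thickness at the midcap / sidecap rays, mm.
#' @param imt_mid,imt_side intima-media thickness at those rays, mm.
#' @param nct_mid,nct_side NC thickness at those rays, mm.
#' @param imt_bg background (plaque-free) IMT, mm.
#' @param wall_ecc background wall eccentricity in [0, 1): fractional thinning
#'   of the wall opposite the plaque.
#' @param media_th,adventitia_th media and adventitia thickness, mm.
#' @param dip_capT optional local minimum cap thickness (mm): a narrow
#'   inward bulge of the NC front placed between midcap and +sidecap;
#'   NA for no dip.
#' @param n_ncs 1 or 2 necrotic cores (the second is a scaled copy placed
#'   on the opposite side).
#' @param vertex_density vertices per full-circle contour.
#' @return object of class `plaque_spec`.
#' @export
plaque_spec <- function(lumen_radius = 1.5, nc_angle = 54 * pi / 180,
                        nc_center_angle = 0,
                        capT_mid = 0.30, capT_side = 0.31,
                        imt_mid = 1.05, imt_side = 1.03,
                        nct_mid = 0.46, nct_side = 0.36,
                        imt_bg = 0.45, wall_ecc = 0.15,
                        media_th = 0.15, adventitia_th = 0.25,
                        dip_capT = NA_real_, n_ncs = 1L,
                        vertex_density = 512L) {
  if (nc_angle <= 10 * pi / 180 || nc_angle >= 170 * pi / 180)
    stop("spec error: nc_angle outside (10, 170) degrees")
  sp <- as.list(environment())
  class(sp) <- "plaque_spec"
  # feasibility: cap + NC must fit inside the intima ring with margin
  if (capT_mid + nct_mid >= imt_mid - media_th ||
      capT_side + nct_side >= imt_side - media_th)
    stop("spec error: NC exceeds the intima ring (capT + NCt >= IMT - media)")
  sp
}

# Smooth angular thickness profile through the three measurement sites.
# off: angular offset from the NC center; values exact at 0 and +/- span/4.
profile_fun <- function(off, span, v_mid, v_side, v_edge, v_bg_fun) {
  x <- c(-span / 2, -span / 4, 0, span / 4, span / 2)
  y <- c(v_edge, v_side, v_mid, v_side, v_edge)
  inside <- abs(off) <= span / 2
  out <- numeric(length(off))
  if (any(inside))
    out[inside] <- stats::spline(x, y, xout = off[inside], method = "fmm")$y
  if (any(!inside)) {
    o <- off[!inside]
    bg <- v_bg_fun(o)
    # cosine blend from the edge value to background over another half-span
    w <- pmin(1, (abs(o) - span / 2) / (span / 2))
    blend <- (1 - cos(pi * w)) / 2
    out[!inside] <- v_edge * (1 - blend) + bg * blend
  }
  out
}

#' Build a deterministic idealized cross-section
#'
#' All boundaries are radial functions of angle about the lumen center, so
#' the morphometric characterization recovers the specified profiles exactly
#' up to vertex discretization.
#'
#' @param spec a [plaque_spec()].
#' @param section_id,artery_id,patient_id identifiers.
#' @return a `cross_section`.
#' @export
make_idealized <- function(spec, section_id = "s1", artery_id = "a1",
                           patient_id = "p1") {
  n <- spec$vertex_density
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  span <- spec$nc_angle
  span2 <- 0.7 * span                    # second NC, when present
  ctr2 <- spec$nc_center_angle + pi
  bg_fun <- function(o) spec$imt_bg * (1 - spec$wall_ecc * (1 - cos(o)) / 2)
  imt_edge <- 0.5 * (spec$imt_side + spec$imt_bg)
  imt_of <- function(th_abs) {
    o1 <- ang_wrap(th_abs - spec$nc_center_angle)
    v <- profile_fun(o1, span, spec$imt_mid, spec$imt_side, imt_edge, bg_fun)
    if (spec$n_ncs == 2L) {
      o2 <- ang_wrap(th_abs - ctr2)
      m2 <- spec$imt_bg + 0.85 * (spec$imt_mid - spec$imt_bg)
      s2 <- spec$imt_bg + 0.85 * (spec$imt_side - spec$imt_bg)
      v2 <- profile_fun(o2, span2, m2, s2, 0.5 * (s2 + spec$imt_bg), bg_fun)
      v <- pmax(v, v2)
    }
    v
  }
  capt_of <- function(o, sp_loc = span, dip = spec$dip_capT) {
    v <- profile_fun(o, sp_loc, spec$capT_mid, spec$capT_side,
                     1.05 * spec$capT_side, function(x) 1.05 * spec$capT_side)
    if (is.finite(dip)) {
      o_dip <- 0.125 * sp_loc          # between midcap and +sidecap
      sig <- sp_loc / 40               # narrow: no effect at the site rays
      base <- profile_fun(o_dip, sp_loc, spec$capT_mid, spec$capT_side,
                          1.05 * spec$capT_side, function(x) 1.05 * spec$capT_side)
      v <- v - (base - dip) * exp(-((o - o_dip) / sig)^2)
    }
    v
  }
  imt <- imt_of(th)
  rl <- spec$lumen_radius
  lumen <- contour(cbind(rl * cos(th), rl * sin(th)), "lumen", check = FALSE)
  intima_outer <- contour(cbind((rl + imt - spec$media_th) * cos(th),
                                (rl + imt - spec$media_th) * sin(th)),
                          "intima", check = FALSE)
  media_outer <- contour(cbind((rl + imt) * cos(th), (rl + imt) * sin(th)),
                         "media", check = FALSE)
  adventitia_outer <- contour(cbind((rl + imt + spec$adventitia_th) * cos(th),
                                    (rl + imt + spec$adventitia_th) * sin(th)),
                              "adventitia", check = FALSE)
  nc_poly <- function(center_angle, scale_nct = 1, sp_loc = span,
                      dip = spec$dip_capT) {
    m <- max(48L, round(spec$vertex_density * sp_loc / (2 * pi)))
    # cosine-clustered sampling: dense near the rounded ends so trimming the
    # zero-thickness tips costs a negligible fraction of the NC angle
    o <- (sp_loc / 2) * sin(pi / 2 * seq(-1, 1, length.out = m))
    a <- center_angle + o
    f <- rl + capt_of(o, sp_loc, dip)
    # NC thickness: quadratic-in-offset base scaled by an elliptic end taper
    b_side <- spec$nct_side * scale_nct / sqrt(1 - 0.25)
    b_mid <- spec$nct_mid * scale_nct
    base <- b_mid + (b_side - b_mid) * (o / (sp_loc / 4))^2
    taper <- sqrt(pmax(0, 1 - (2 * o / sp_loc)^2))
    nct <- pmax(0, base) * taper
    # clamp inside the intima ring with a safety margin
    lim <- imt_of(a) - spec$media_th - (f - rl) - 0.03
    nct <- pmin(nct, pmax(lim, 0))
    # trim to the span where the core has usable thickness; a 20 um floor
    # keeps the back polyline from grazing the front after clamping
    keep <- which(nct > 0.02)
    if (length(keep) < 5L) return(NULL)
    idx <- keep[1]:keep[length(keep)]
    a <- a[idx]; f <- f[idx]
    nct <- pmax(nct[idx], 0.02)
    m2 <- length(idx)
    front <- cbind(f * cos(a), f * sin(a))
    back <- cbind((f + nct) * cos(a), (f + nct) * sin(a))
    xy <- rbind(front, back[rev(seq_len(m2)), , drop = FALSE])
    xy <- xy[!duplicated(round(xy, 10)), , drop = FALSE]
    contour(xy, "nc", check = FALSE)
  }
  nc1 <- nc_poly(spec$nc_center_angle)
  if (is.null(nc1)) stop("spec error: necrotic core collapses inside the wall")
  ncs <- list(nc1)
  if (spec$n_ncs == 2L) {
    nc2 <- nc_poly(ctr2, 0.6, span2, NA_real_)
    # the wall clamp can collapse the secondary core to a sliver; drop it then
    if (!is.null(nc2) && nrow(nc2$xy) >= 8L && polygon_area(nc2$xy) > 0.02)
      ncs <- c(ncs, list(nc2))
  }
  cross_section(lumen, intima_outer, media_outer, adventitia_outer, ncs,
                section_id = section_id, artery_id = artery_id,
                patient_id = patient_id, check = FALSE)
}

# lognormal sdlog from a median and printed IQR
sdlog_from_iqr <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))

#' Population specification for cohort sampling
#'
#' Marginals are log-normal with location/scale solved from the published
#' median and IQR of each feature; features within an artery share a latent
#' Gaussian effect giving intraclass correlation `rho` on the log scale.
#'
#' @param n_patients,arteries_per_patient,sections_per_artery cohort layout.
#' @param rho within-artery correlation of log-features, in [0, 1).
#' @param p_two_ncs probability a section carries two NCs.
#' @param targets named list of median targets (mm / rad); see defaults.
#' @param iqrs named list of c(q1, q3) per feature.
#' @param vertex_density contour resolution for generated sections.
#' @param seed integer seed recorded with the cohort.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_patients = 7L, arteries_per_patient = 2L,
                            sections_per_artery = 4L, rho = 0.3,
                            p_two_ncs = 21 / 52,
                            targets = list(nc_angle = 54 * pi / 180,
                                           capT_mid = 0.30, imt_mid = 1.05,
                                           nct_mid = 0.46, capT_side = 0.31,
                                           imt_side = 1.03, nct_side = 0.36,
                                           min_capT = 0.20, lumen_radius = 1.5),
                            iqrs = list(nc_angle = c(35, 75) * pi / 180,
                                        capT_mid = c(0.13, 0.53),
                                        imt_mid = c(0.89, 1.29),
                                        nct_mid = c(0.27, 0.54),
                                        min_capT = c(0.09, 0.40)),
                            vertex_density = 256L, seed = 1L) {
  structure(as.list(environment()), class = "population_spec")
}

#' Sample a synthetic plaque cohort
#'
#' Draws per-NC geometric features from the calibrated log-normal marginals
#' (shared artery-level latent effect), builds each section with
#' [make_idealized()], and returns the sections together with the generating
#' ground-truth parameters.
#'
#' @param pop a [population_spec()].
#' @param n_sections optionally cap the number of sections (takes the first n).
#' @param truth_only skip contour construction and return only the generating
#'   parameter table (fast path for calibration checks).
#' @return list with `sections` (list of `cross_section`; NULL when
#'   `truth_only`), `truth` (data.frame of generating parameters, one row per
#'   section) and `seed`.
#' @export
sample_population <- function(pop, n_sections = NULL, truth_only = FALSE) {
  set.seed(pop$seed)
  tg <- pop$targets; iq <- pop$iqrs
  sd_angle <- sdlog_from_iqr(iq$nc_angle[1], iq$nc_angle[2])
  sd_capt <- sdlog_from_iqr(iq$capT_mid[1], iq$capT_mid[2])
  sd_imt <- sdlog_from_iqr(iq$imt_mid[1], iq$imt_mid[2])
  sd_nct <- sdlog_from_iqr(iq$nct_mid[1], iq$nct_mid[2])
  layout <- expand.grid(sec = seq_len(pop$sections_per_artery),
                        art = seq_len(pop$arteries_per_patient),
                        pat = seq_len(pop$n_patients))
  if (!is.null(n_sections)) layout <- layout[seq_len(min(n_sections, nrow(layout))), ]
  n <- nrow(layout)
  art_key <- paste0("p", layout$pat, "_a", layout$art)
  z_art <- stats::setNames(rnorm(length(unique(art_key))), unique(art_key))
  z_a <- z_art[art_key]
  # cap thickness and wall thickness share individual-level noise (lambda):
  # a thick cap is part of a thick intima, as in real plaques
  lam <- 0.8
  w_i <- rnorm(n); v_i <- rnorm(n); u_i <- rnorm(n); a_i <- rnorm(n)
  lat <- function(ind) sqrt(pop$rho) * z_a + sqrt(1 - pop$rho) * ind
  angle <- pmin(pmax(tg$nc_angle * exp(sd_angle * lat(a_i)), 15 * pi / 180),
                160 * pi / 180)
  capt_raw <- pmin(pmax(tg$capT_mid * exp(sd_capt * lat(w_i)), 0.06), 1.0)
  imt_raw <- pmin(pmax(tg$imt_mid *
                         exp(sd_imt * lat(lam * w_i + sqrt(1 - lam^2) * v_i)),
                       0.55), 2.4)
  nct_raw <- pmin(pmax(tg$nct_mid * exp(sd_nct * lat(u_i)), 0.08), 1.2)
  # feasibility: cap + core + media must fit inside the wall; split any
  # deficit between thickening the wall and shrinking the core
  media_th <- 0.12; marg <- media_th + 0.03
  deficit <- pmax(0, capt_raw + nct_raw + marg - imt_raw)
  capt_m <- capt_raw
  imt_m <- imt_raw + 0.7 * deficit
  nct_m <- pmax(nct_raw - 0.3 * deficit, 0.08)
  imt_m <- pmax(imt_m, capt_m + nct_m + marg)
  side_ratio <- function(r0) r0 * exp(0.08 * rnorm(n))
  capt_s <- capt_m * side_ratio(tg$capT_side / tg$capT_mid)
  imt_s <- imt_m * side_ratio(tg$imt_side / tg$imt_mid)
  nct_s <- pmin(nct_m * side_ratio(tg$nct_side / tg$nct_mid),
                pmax(imt_s - capt_s - marg, 0.05))
  imt_s <- pmax(imt_s, capt_s + nct_s + marg)
  rl <- pmin(pmax(tg$lumen_radius * exp(0.12 * rnorm(n)), 0.9), 2.4)
  # min cap thickness: fraction of the smallest site capT, calibrated so the
  # cohort median tracks the 0.20 mm target given the capT marginals
  r_dip <- tg$min_capT / (0.97 * min(tg$capT_mid, tg$capT_side))
  dip_frac <- pmin(r_dip * exp(0.45 * rnorm(n)), 0.98)
  two <- runif(n) < pop$p_two_ncs
  sections <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    dip <- dip_frac[i] * min(capt_m[i], capt_s[i])
    spc <- plaque_spec(lumen_radius = rl[i], nc_angle = angle[i],
                       nc_center_angle = runif(1, 0, 2 * pi),
                       capT_mid = capt_m[i], capT_side = capt_s[i],
                       imt_mid = imt_m[i], imt_side = imt_s[i],
                       nct_mid = nct_m[i], nct_side = nct_s[i],
                       imt_bg = max(0.35, 0.45 * imt_m[i] / 1.05),
                       media_th = media_th, dip_capT = dip,
                       n_ncs = if (two[i] && angle[i] < 120 * pi / 180) 2L else 1L,
                       vertex_density = pop$vertex_density)
    sid <- sprintf("%s_s%d", art_key[i], layout$sec[i])
    if (!truth_only)
      sections[[i]] <- make_idealized(spc, section_id = sid,
                                      artery_id = art_key[i],
                                      patient_id = paste0("p", layout$pat[i]))
    truth[[i]] <- data.frame(section_id = sid, artery_id = art_key[i],
                             patient_id = paste0("p", layout$pat[i]),
                             lumen_radius = rl[i], nc_angle = angle[i],
                             capT_mid = capt_m[i], capT_side = capt_s[i],
                             imt_mid = imt_m[i], imt_side = imt_s[i],
                             nct_mid = nct_m[i], nct_side = nct_s[i],
                             capT_raw = capt_raw[i], imt_raw = imt_raw[i],
                             nct_raw = nct_raw[i],
                             rnct_mid = nct_m[i] / imt_m[i],
                             rnct_side = nct_s[i] / imt_s[i],
                             min_capT = dip, n_ncs = spc$n_ncs)
  }
  list(sections = if (truth_only) NULL else sections,
       truth = do.call(rbind, truth), seed = pop$seed)
}

#' Simulate a clustered rNCt regression dataset
#'
#' Covariates are taken from a sampled cohort's ground truth; responses follow
#' the linear relation rNCt = b0 + b_angle*angle[rad] + b_IMT*IMT[um] +
#' b_capT*capT[um] plus exchangeable Gaussian noise within arteries.
#'
#' @param coeffs a `gee_coefficients` object (see [published_coefficients()]).
#' @param residual_sd residual standard deviation of rNCt.
#' @param pop a [population_spec()] (drives covariates and clustering).
#' @param rho_resid within-artery correlation of the residuals.
#' @param n_sections optional cap on cohort size.
#' @return data.frame: rnct, nc_angle (rad), imt (um), capt (um), artery_id,
#'   plus the noiseless linear predictor `eta`.
#' @export
simulate_gee_dataset <- function(coeffs, residual_sd = 0.05, pop = population_spec(),
                                 rho_resid = 0.3, n_sections = NULL) {
  cohort <- sample_population(pop, n_sections = n_sections, truth_only = TRUE)
  tr <- cohort$truth
  side <- coeffs$site == "sidecap"
  if (side) {
    base <- tr[rep(seq_len(nrow(tr)), each = 2L), ]
    ang <- base$nc_angle; imt <- base$imt_side * 1000; capt <- base$capT_side * 1000
  } else {
    base <- tr
    ang <- base$nc_angle; imt <- base$imt_mid * 1000; capt <- base$capT_mid * 1000
  }
  eta <- coeffs$beta[1] + coeffs$beta[2] * ang + coeffs$beta[3] * imt +
    coeffs$beta[4] * capt
  art <- base$artery_id
  z_art <- stats::setNames(rnorm(length(unique(art))), unique(art))
  noise <- residual_sd * (sqrt(rho_resid) * z_art[art] +
                          sqrt(1 - rho_resid) * rnorm(length(eta)))
  data.frame(rnct = eta + noise, nc_angle = ang, imt = imt, capt = capt,
             artery_id = art, eta = eta, row.names = NULL)
}
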