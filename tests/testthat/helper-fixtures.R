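# Analytic fixtures shared across the suite.

circle_poly <- function(r, n = 256, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# annular-sector NC spanning radii [r1, r2] and angles [a1, a2]
sector_poly <- function(r1, r2, a1, a2, n = 121) {
  a <- seq(a1, a2, length.out = n)
  rbind(cbind(r1 * cos(a), r1 * sin(a)),
        cbind(r2 * cos(rev(a)), r2 * sin(rev(a))))
}

# concentric fixture: lumen 1.5, NC band 2.0-2.5 over +/-30 deg,
# intima_outer 2.8, media_outer 3.0, adventitia_outer 3.3 (mm)
concentric_cs <- function(nc_r = c(2.0, 2.5), nc_a = c(-pi / 6, pi / 6),
                          n = 256) {
  cross_section(
    contour(circle_poly(1.5, n), "lumen", check = FALSE),
    contour(circle_poly(2.8, n), "intima", check = FALSE),
    contour(circle_poly(3.0, n), "media", check = FALSE),
    contour(circle_poly(3.3, n), "adventitia", check = FALSE),
    list(contour(sector_poly(nc_r[1], nc_r[2], nc_a[1], nc_a[2]), "nc",
                 check = FALSE)),
    check = FALSE)
}

# homogeneous thick-wall ring 1.5-3.0 mm (the media/adventitia shells are
# given the same material by the caller)
ring_cs <- function(n = 192) {
  cross_section(
    contour(circle_poly(1.5, n), "lumen", check = FALSE),
    contour(circle_poly(2.90, n), "intima", check = FALSE),
    contour(circle_poly(2.95, n), "media", check = FALSE),
    contour(circle_poly(3.0, n), "adventitia", check = FALSE),
    list(), check = FALSE)
}

homogeneous_materials <- function() {
  m <- material_table()
  m$C10[m$name == "media_adventitia"] <- m$C10[m$name == "intima"]
  m$D1[m$name == "media_adventitia"] <- m$D1[m$name == "intima"]
  m
}

ring_model <- function(n_theta = 64) {
  m <- build_model(ring_cs(), ncs = list(), materials = homogeneous_materials(),
                   buffer_thickness = 0, constraints = "symmetry",
                   mesh = mesh_options(n_theta = n_theta, n_cap = 5, n_nc = 5,
                                       n_behind = 4, n_media = 1,
                                       n_adventitia = 1))
  generate_mesh(m)
}

# polar stress components at element centroids
polar_stress <- function(model, field) {
  cen <- (model$nodes[model$tri[, 1], ] + model$nodes[model$tri[, 2], ] +
          model$nodes[model$tri[, 3], ]) / 3
  r <- sqrt(rowSums(cen^2)); a <- atan2(cen[, 2], cen[, 1])
  S <- field$stress
  list(r = r,
       hoop = S[, 1] * sin(a)^2 + S[, 2] * cos(a)^2 - 2 * S[, 3] * sin(a) * cos(a),
       radial = S[, 1] * cos(a)^2 + S[, 2] * sin(a)^2 + 2 * S[, 3] * sin(a) * cos(a))
}

fast_mesh <- function(n_theta = 72)
  mesh_options(n_theta = n_theta, n_nc = 3, n_behind = 1, n_media = 2,
               n_adventitia = 1, n_buffer = 2)
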