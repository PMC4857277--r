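# Plane-strain neo-Hookean solver: material conversions, meshing,
# verification against closed forms, prestress, and PCS extraction.

test_that("neo-Hookean constants follow the published conversion", {
  expect_equal(neo_hookean_from_linear(1000)$C10, 166.7, tolerance = 1e-3)
  expect_equal(neo_hookean_from_linear(1500)$C10, 250)
  expect_equal(neo_hookean_from_linear(6)$C10, 1)
  cc <- neo_hookean_from_linear(60, incompressible = FALSE, nu = 0.45)
  expect_equal(cc$C10, 60 / (4 * 1.45))
  expect_equal(cc$D1, 3 * 0.1 / 60)
  expect_error(neo_hookean_from_linear(60, incompressible = FALSE, nu = 0.5),
               "compressible")
  m <- material_table()
  expect_equal(2 * m$C10[m$name == "intima"], 1000 / 3, tolerance = 2e-3)
  expect_equal(1 / m$D1[m$name == "nc"], 1e5)
})

test_that("mesh regions reproduce analytic areas and labels", {
  cs <- concentric_cs()
  m <- generate_mesh(build_model(cs, mesh = mesh_options(n_theta = 96)))
  area_of <- function(reg) sum(m$elem_area[m$region == reg])
  a_nc <- 0.5 * (2.5^2 - 2.0^2) * (pi / 3)
  a_int <- pi * (2.8^2 - 1.5^2) - a_nc
  a_med <- pi * (3.3^2 - 2.8^2)
  expect_equal(area_of("nc"), a_nc, tolerance = 0.01)
  expect_equal(area_of("intima"), a_int, tolerance = 0.01)
  expect_equal(area_of("media_adventitia"), a_med, tolerance = 0.01)
  # element labels agree with point-in-polygon tests at centroids
  cen <- (m$nodes[m$tri[, 1], ] + m$nodes[m$tri[, 2], ] +
          m$nodes[m$tri[, 3], ]) / 3
  in_nc <- sp::point.in.polygon(cen[, 1], cen[, 2],
                                cs$ncs[[1]]$xy[, 1], cs$ncs[[1]]$xy[, 2]) > 0
  mismatch <- mean(in_nc != (m$region == "nc"))
  expect_lt(mismatch, 0.005)
  # radial transect through the cap crosses >= 7 elements
  expect_gte(sum(m$band == "cap") / 4 / 96, 7 - 1e-9)
})

test_that("two cores are meshed as disjoint NC regions; none is also fine", {
  cs2 <- make_idealized(plaque_spec(n_ncs = 2L, vertex_density = 192L))
  m2 <- generate_mesh(build_model(cs2, mesh = fast_mesh(48)))
  expect_setequal(unique(m2$elem_nc[m2$region == "nc"]), c(1L, 2L))
  m0 <- generate_mesh(build_model(ring_cs(), ncs = list(),
                                  mesh = fast_mesh(48)))
  expect_false(any(m0$region == "nc"))
  expect_true(all(c("intima", "media_adventitia", "buffer") %in% m0$region))
})

test_that("zero pressure gives zero displacement and stress", {
  m <- ring_model(32)
  sol <- solve_pressurized(m, 0)
  expect_equal(max(abs(sol$u)), 0)
  f <- stress_field(m, sol$u)
  expect_equal(max(abs(f$von_mises)), 0, tolerance = 1e-12)
})

test_that("pressurized ring matches the Lame thick-wall solution within 2%", {
  m <- ring_model(64)
  sol <- solve_pressurized(m, 1)
  fld <- stress_field(m, sol$u)
  ps <- polar_stress(m, fld)
  ri <- 1.5; ro <- 3.0; p <- 1
  lame_t <- p * ri^2 / (ro^2 - ri^2) * (1 + ro^2 / ps$r^2)
  lame_r <- p * ri^2 / (ro^2 - ri^2) * (1 - ro^2 / ps$r^2)
  expect_lt(max(abs(ps$hoop - lame_t)) / max(abs(lame_t)), 0.02)
  expect_lt(max(abs(ps$radial - lame_r)) / max(abs(lame_t)), 0.04)
  # inner-wall circumferential stress ~ p (ri^2 + ro^2) / (ro^2 - ri^2):
  # extrapolate the a + b / r^2 profile to r = ri
  near <- ps$r < 1.9
  cf <- coef(lm(ps$hoop[near] ~ I(1 / ps$r[near]^2)))
  expect_equal(unname(cf[1] + cf[2] / ri^2), 1.667, tolerance = 0.02)
  # von Mises against the plane-strain closed form
  vm_lame <- sqrt(3) * p * ri^2 * ro^2 / ((ro^2 - ri^2) * ps$r^2)
  expect_lt(max(abs(fld$von_mises - vm_lame)) / max(vm_lame), 0.025)
})

test_that("solution is linear in the small-load limit when stiffness doubles", {
  m <- ring_model(32)
  sol1 <- solve_pressurized(m, 0.2)
  m2 <- m; m2$C10 <- 2 * m$C10; m2$kpen <- 2 * m$kpen
  sol2 <- solve_pressurized(m2, 0.2)
  expect_equal(max(abs(sol2$u)) / max(abs(sol1$u)), 0.5, tolerance = 0.01)
})

test_that("peak stress is mesh-convergent on the ring fixture", {
  vm_at <- function(nt) {
    m <- ring_model(nt)
    max(stress_field(m, solve_pressurized(m, 1)$u)$von_mises)
  }
  expect_equal(vm_at(64), vm_at(32), tolerance = 0.02)
})

test_that("net reaction on the fixed boundary balances the closed-loop load", {
  cs <- make_idealized(plaque_spec(vertex_density = 160L))
  m <- generate_mesh(build_model(cs, mesh = fast_mesh(48)))
  sol <- solve_pressurized(m, 5)
  asm <- plaqrecon:::fe_assemble(m$nodes, m$tri, sol$u, m$C10, m$kpen, FALSE)
  x <- m$nodes + matrix(sol$u, ncol = 2, byrow = TRUE)
  load <- plaqrecon:::pressure_load(m, x, 5)
  react <- asm$f[m$fixed_dofs] - load$f[m$fixed_dofs]
  net <- c(sum(react[seq(1, length(react), 2)]),
           sum(react[seq(2, length(react), 2)]))
  # pressure on a closed lumen loop has zero resultant; so must the reactions
  scale <- sum(abs(load$f))
  expect_lt(sqrt(sum(net^2)) / scale, 1e-3)
})

test_that("rigid rotation leaves von Mises unchanged", {
  th0 <- 25 * pi / 180
  R <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2)
  sp <- plaque_spec(vertex_density = 160L)
  cs1 <- make_idealized(sp)
  rot <- function(ct) contour(ct$xy %*% t(R), ct$component, check = FALSE)
  cs2 <- cross_section(rot(cs1$lumen), rot(cs1$intima_outer),
                       rot(cs1$media_outer), rot(cs1$adventitia_outer),
                       lapply(cs1$ncs, rot), check = FALSE)
  msh <- fast_mesh(48)
  m1 <- generate_mesh(build_model(cs1, mesh = msh))
  m2 <- generate_mesh(build_model(cs2, mesh = msh))
  f1 <- stress_field(m1, solve_pressurized(m1, 5)$u)
  f2 <- stress_field(m2, solve_pressurized(m2, 5)$u)
  # same mesh topology rotated by a multiple of the angular step would be
  # exactly equal; 25 deg is generic, so compare the peak and the quantiles
  expect_equal(max(f2$von_mises), max(f1$von_mises), tolerance = 0.02)
  expect_equal(quantile(f2$von_mises, c(0.5, 0.9, 0.99)),
               quantile(f1$von_mises, c(0.5, 0.9, 0.99)), tolerance = 0.02)
})

test_that("backward-incremental prestress round-trips the imaged geometry", {
  cs <- make_idealized(plaque_spec(vertex_density = 160L))
  m <- generate_mesh(build_model(cs, mesh = fast_mesh(48)))
  mp <- prestress_backward_incremental(m, 100)
  expect_true(mp$prestressed)
  expect_lt(mp$prestress_info$resid, 1e-3)   # < 1 um
  # explicit round trip: pressurize the unloaded configuration to 100 mmHg
  sol <- solve_pressurized(mp, 100 * plaqrecon:::kPa_per_mmHg,
                           u0 = as.numeric(t(mp$imaged_nodes - mp$nodes)))
  x <- mp$nodes + matrix(sol$u, ncol = 2, byrow = TRUE)
  expect_lt(max(sqrt(rowSums((x - mp$imaged_nodes)^2))), 1e-3)
  # unloaded lumen is smaller than the imaged lumen
  lum <- m$lumen_edges[, 1]
  r_unl <- mean(sqrt(rowSums(mp$nodes[lum, ]^2)))
  r_img <- mean(sqrt(rowSums(mp$imaged_nodes[lum, ]^2)))
  expect_lt(r_unl, r_img)
  # zero imaging pressure: identity
  m0 <- prestress_backward_incremental(m, 0)
  expect_equal(m0$nodes, m0$imaged_nodes)
})

test_that("thinner caps concentrate more peak cap stress", {
  msh <- fast_mesh(48)
  pcs_of <- function(capt) {
    cs <- make_idealized(plaque_spec(capT_mid = capt, capT_side = capt + 0.01,
                                     vertex_density = 160L))
    compute_pcs(cs, prestress = FALSE, mesh = msh)$pcs[[1]]$pcs
  }
  expect_gt(pcs_of(0.15), pcs_of(0.30))
})

test_that("the PCS search region is the cap plus 15 degree shoulders", {
  cs <- concentric_cs()
  m <- generate_mesh(build_model(cs, mesh = fast_mesh(48)))
  # fabricate a field with the global max far outside the shoulders
  vm <- rep(1, nrow(m$tri))
  off <- abs(plaqrecon:::ang_wrap(m$elem_angle - m$nc_spans[[1]]["mid"]))
  outside <- which(m$region == "intima" &
                   off > (30 + 16) * pi / 180 & off < (30 + 40) * pi / 180)
  vm[outside] <- 100
  fld <- list(von_mises = vm, u = numeric(2 * nrow(m$nodes)))
  pk <- peak_cap_stress(fld, m)
  expect_equal(pk$pcs, 1)                    # the 16-deg-out peak is excluded
  # a hot element inside the cap is found and located
  inside <- which(m$region == "intima" & m$band == "cap" &
                  off < 20 * pi / 180)[1]
  vm2 <- vm; vm2[inside] <- 50
  pk2 <- peak_cap_stress(list(von_mises = vm2), m)
  expect_equal(pk2$pcs, 50)
  expect_equal(pk2$region, "cap")
  expect_equal(pk2$element, inside)
  # uniform field: the peak equals the uniform value, location in-region
  pk3 <- peak_cap_stress(list(von_mises = rep(3, nrow(m$tri))), m)
  expect_equal(pk3$pcs, 3)
  expect_lte(abs(plaqrecon:::ang_wrap(
    atan2(pk3$location[2], pk3$location[1]))), (30 + 15.5) * pi / 180)
})

test_that("prestressed and non-prestressed runs are distinct and recorded", {
  cs <- make_idealized(plaque_spec(vertex_density = 160L))
  msh <- fast_mesh(48)
  a <- compute_pcs(cs, prestress = FALSE, mesh = msh)
  b <- compute_pcs(cs, prestress = TRUE, mesh = msh)
  expect_false(a$prestress); expect_true(b$prestress)
  expect_true(b$model$prestressed)
  expect_false(isTRUE(all.equal(a$pcs[[1]]$pcs, b$pcs[[1]]$pcs)))
})

test_that("VTK export writes a parsable unstructured grid", {
  m <- ring_model(16)
  sol <- solve_pressurized(m, 0.5)
  path <- tempfile(fileext = ".vtk")
  write_vtk(m, stress_field(m, sol$u), path)
  lines <- readLines(path)
  expect_true(any(grepl("^POINTS", lines)))
  np <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  expect_equal(np, nrow(m$nodes))
  expect_true(any(grepl("von_mises", lines)))
})
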