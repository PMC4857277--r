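# Backside reconstruction: back points, edge arcs, closure, clipping.

test_that("back points sit at front hit + rNCt x IMT on the site rays", {
  cs <- concentric_cs()
  f <- nc_front_side(cs, cs$ncs[[1]])
  bp <- back_points(cs, f, c(1 / 3, 1 / 3))
  r <- sqrt(rowSums(bp$points^2))
  expect_equal(r, rep(2.5, 3), tolerance = 2e-3)   # 2.0 + (1/3) * 1.5
  # zero rNCt: back points coincide with the front hits
  bp0 <- back_points(cs, f, c(0, 0))
  expect_equal(sqrt(rowSums(bp0$points^2)), rep(2.0, 3), tolerance = 2e-3)
  # published medians: 0.40 x 1.05 mm = 0.42 mm behind the front at midcap
  expect_equal(bp$nct, (1 / 3) * bp$sites$IMT, tolerance = 1e-9)
})

test_that("edge arc follows the published radius and extent", {
  cs <- concentric_cs()  # NC angle 60 deg
  f <- nc_front_side(cs, cs$ncs[[1]])
  aL <- edge_arc(cs, f, "left")
  expect_false(aL$fallback)
  expect_equal(aL$radius, 0.14 * pi / 3, tolerance = 0.05)
  # at the published median angle: 0.14 x 0.9425 = 0.132 mm
  expect_equal(0.14 * 0.9425, 0.132, tolerance = 1e-3)
  # arc spans 30 degrees about its center
  ang <- atan2(aL$arc[, 2] - aL$center[2], aL$arc[, 1] - aL$center[1])
  sweep <- abs(plaqrecon:::ang_wrap(ang[length(ang)] - ang[1]))
  expect_equal(sweep, pi / 6, tolerance = 1e-6)
  # arc starts on the front edge vertex
  expect_equal(unname(aL$arc[1, ]), unname(f$polyline[1, ]), tolerance = 1e-12)
})

test_that("left and right arcs of a symmetric plaque are mirror images", {
  cs <- concentric_cs()
  f <- nc_front_side(cs, cs$ncs[[1]])
  aL <- edge_arc(cs, f, "left"); aR <- edge_arc(cs, f, "right")
  # fixture is symmetric about the x-axis: mirror y -> -y
  mir <- aR$arc; mir[, 2] <- -mir[, 2]
  expect_equal(aL$arc, mir, tolerance = 1e-6)
})

test_that("the chosen arc center is the circle intersection farthest from the lumen", {
  cs <- concentric_cs()
  f <- nc_front_side(cs, cs$ncs[[1]])
  for (side in c("left", "right")) {
    a <- edge_arc(cs, f, side)
    E <- if (side == "left") f$polyline[1, ] else f$polyline[nrow(f$polyline), ]
    r1 <- a$radius
    # oracle: recompute both circle-circle intersection candidates
    hits <- plaqrecon:::circle_polyline_hits(E, r1, f$polyline)
    P <- if (side == "left") hits[1, ] else hits[nrow(hits), ]
    d12 <- sqrt(sum((P - E)^2))
    mid <- (E + P) / 2; h <- sqrt(r1^2 - (d12 / 2)^2)
    u <- (P - E) / d12; perp <- c(-u[2], u[1])
    cand <- rbind(mid + h * perp, mid - h * perp)
    dc <- sqrt(rowSums(cand^2))        # lumen center is the origin
    expect_equal(a$center, cand[which.max(dc), ], tolerance = 1e-9)
    expect_gt(max(dc), min(dc))        # the choice is strict
  }
})

test_that("collinear closure points degenerate to a straight backside", {
  f <- list(polyline = cbind(c(-1, 0, 1), c(0, 0, 0)),
            angles = c(0, 0, 0), span = c(0, 0), nc_angle = 0.5,
            center = c(0, -5))
  arcs <- list(l = list(arc = rbind(c(-1, 0), c(-1.2, 0.1))),
               r = list(arc = rbind(c(1, 0), c(1.2, 0.1))))
  # the five closure points are collinear on y = 0.1
  bpts <- cbind(c(-0.6, 0, 0.6), 0.1)
  cl <- close_backside(f, arcs$l, arcs$r, bpts,
                       reconstruction_params(backside_samples = 20L))
  # backside samples lie on y = 0.1
  back_rows <- cl$xy[cl$xy[, 2] > 0.05, ]
  expect_true(all(abs(back_rows[, 2] - 0.1) < 1e-9))
})

test_that("clipping obeys the 10 um clearance rule", {
  # protruding rectangle: 1 x 1 mm with 0.3 mm beyond a straight boundary
  boundary <- cbind(c(-5, 0.7, 0.7, -5), c(-5, -5, 5, 5))
  rect <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  out <- clip_media(rect, boundary, clearance = 0.010)
  expect_true(out$clipped)
  expect_equal(abs(polygon_area(out$xy)), 0.69, tolerance = 1e-6)
  # fully inside with margin: identity
  inner <- cbind(c(0, 0.3, 0.3, 0), c(0, 0, 0.3, 0.3))
  out2 <- clip_media(inner, boundary, clearance = 0.010)
  expect_false(out2$clipped)
  expect_identical(out2$xy, inner)
  # clipped NC keeps >= clearance distance to the true boundary
  d <- 0.7 - max(out$xy[, 1])
  expect_gte(d, 0.010 - 1e-9)
  expect_error(clip_media(rect + 10, boundary, 0.01), "outside")
})

test_that("round-trip reconstruction with true rNCt scores SI >= 0.9", {
  for (vd in c(256L, 512L)) {
    sp <- plaque_spec(vertex_density = vd)
    cs <- make_idealized(sp)
    tr <- features_table(characterize(cs))
    f <- nc_front_side(cs, cs$ncs[[1]])
    rr <- reconstruct(cs, f, "oracle",
                      rnct = c(tr$rNCt_side, tr$rNCt_mid, tr$rNCt_side))
    sc <- similarity_index(cs$ncs[[1]], rr$nc_polygon)
    expect_gte(sc$si, 0.9)
    expect_lte(sc$delta_a_pct, 10)
    # the front polyline is preserved on the reconstructed boundary
    idx <- seq(1, nrow(f$polyline), by = 7)
    for (i in idx) {
      dmin <- min(sqrt(rowSums((rr$nc_polygon$xy -
        matrix(f$polyline[i, ], nrow(rr$nc_polygon$xy), 2, byrow = TRUE))^2)))
      expect_lt(dmin, 1e-9)
    }
  }
})

test_that("NC area grows monotonically with the midcap rNCt", {
  cs <- make_idealized(plaque_spec())
  f <- nc_front_side(cs, cs$ncs[[1]])
  areas <- vapply(c(0.25, 0.35, 0.45, 0.55), function(rm) {
    rr <- reconstruct(cs, f, "oracle", rnct = c(0.35, rm, 0.35))
    abs(polygon_area(rr$nc_polygon$xy))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("mirror-symmetric inputs give mirror-symmetric reconstructions", {
  cs <- concentric_cs()
  f <- nc_front_side(cs, cs$ncs[[1]])
  rr <- reconstruct(cs, f, "group_average",
                    averages = list(rnct_mid = 0.40, rnct_side = 0.35))
  xy <- rr$nc_polygon$xy
  mir <- xy; mir[, 2] <- -mir[, 2]
  # every vertex of the mirrored polygon lies on the original boundary
  d <- vapply(seq(1, nrow(mir), by = 5), function(i) {
    min(sqrt(rowSums((xy - matrix(mir[i, ], nrow(xy), 2, byrow = TRUE))^2)))
  }, numeric(1))
  expect_lt(max(d), 5e-3)
})

test_that("reconstruction output is simple, CCW, and respects clipping flags", {
  pop <- population_spec(n_patients = 5L, seed = 31L, vertex_density = 160L)
  cohort <- sample_population(pop)
  n_done <- 0
  for (i in seq_along(cohort$sections)) {
    cs <- cohort$sections[[i]]; tr <- cohort$truth[i, ]
    f <- nc_front_side(cs, cs$ncs[[1]])
    rr <- tryCatch(reconstruct(cs, f, "oracle",
                               rnct = c(tr$rnct_side, tr$rnct_mid, tr$rnct_side)),
                   error = function(e) NULL)
    if (is.null(rr)) next
    n_done <- n_done + 1
    expect_gt(polygon_area(rr$nc_polygon$xy), 0)
    expect_true(plaqrecon:::polygon_is_simple(rr$nc_polygon$xy, tol = 1e-3))
  }
  expect_gte(n_done, 30)
})

test_that("rNCt beyond the wall is clipped and flagged", {
  cs <- make_idealized(plaque_spec())
  f <- nc_front_side(cs, cs$ncs[[1]])
  rr <- reconstruct(cs, f, "oracle", rnct = c(0.9, 0.95, 0.9))
  expect_true(rr$clipped_to_media)
  # clipped polygon stays >= ~10 um inside the outer intima border
  gap <- vapply(seq_len(nrow(rr$nc_polygon$xy)), function(i) {
    p <- rr$nc_polygon$xy[i, ]
    a <- atan2(p[2], p[1])
    ti <- plaqrecon:::ray_hits(c(0, 0), a, cs$intima_outer$xy)[1]
    ti - sqrt(sum(p^2))
  }, numeric(1))
  expect_gte(min(gap), 0.010 - 2e-3)
})
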