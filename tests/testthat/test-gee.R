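# GEE estimation of the rNCt relation and the packaged coefficient sets.

test_that("packaged coefficients predict the published cohort medians", {
  # midcap at NC angle 54 deg, IMT 1.05 mm, capT 0.30 mm
  p_mid <- predict_rnct(published_coefficients("midcap"), 54 * pi / 180, 1050, 300)
  expect_equal(as.numeric(p_mid), 0.398, tolerance = 0.002)
  p_side <- predict_rnct(published_coefficients("sidecap"), 54 * pi / 180, 1030, 310)
  expect_equal(as.numeric(p_side), 0.353, tolerance = 0.002)
})

test_that("prediction clamps out-of-range values and flags them", {
  cf <- gee_coefficients(c(2, 0, 0, 0), "midcap")
  expect_warning(p <- predict_rnct(cf, 1, 1000, 300), "clamped")
  expect_equal(as.numeric(p), 0.95)
  expect_true(attr(p, "clamped"))
  cf0 <- gee_coefficients(c(0.187, 0, 0, 0), "midcap")
  expect_equal(as.numeric(predict_rnct(cf0, 1e-9, 1e-9, 1e-9)), 0.187,
               tolerance = 1e-6)
})

test_that("prediction is affine in the covariates", {
  cf <- published_coefficients("midcap")
  x1 <- c(0.8, 900, 250); x2 <- c(1.2, 1200, 400)
  a <- 0.3; b <- 0.9
  mix <- a * x1 + b * x2
  lhs <- predict_rnct(cf, mix[1], mix[2], mix[3])
  rhs <- a * predict_rnct(cf, x1[1], x1[2], x1[3]) +
    b * predict_rnct(cf, x2[1], x2[2], x2[3]) - (a + b - 1) * cf$beta[1]
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-12)
})

sim_table <- function(beta, n_cl, per_cl, sd = 0.05, rho = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_cl * per_cl
  id <- rep(seq_len(n_cl), each = per_cl)
  ang <- runif(n, 0.5, 1.6); imt <- runif(n, 800, 1400); capt <- runif(n, 100, 600)
  eta <- beta[1] + beta[2] * ang + beta[3] * imt + beta[4] * capt
  z <- rnorm(n_cl)
  y <- eta + sd * (sqrt(rho) * z[id] + sqrt(1 - rho) * rnorm(n))
  data.frame(rnct = y, nc_angle = ang, imt = imt, capt = capt, artery_id = id)
}

test_that("independence GEE reduces exactly to ordinary least squares", {
  d <- sim_table(published_coefficients("midcap")$beta, 20, 5, seed = 3)
  g <- fit_gee(d, "midcap", corstr = "independence")
  ols <- lm(rnct ~ nc_angle + imt + capt, data = d)
  expect_equal(unname(g$beta), unname(coef(ols)), tolerance = 1e-10)
  # one observation per cluster: exchangeable alpha is empty -> OLS as well
  d1 <- sim_table(published_coefficients("midcap")$beta, 60, 1, seed = 4)
  g1 <- fit_gee(d1, "midcap")
  ols1 <- lm(rnct ~ nc_angle + imt + capt, data = d1)
  expect_equal(unname(g1$beta), unname(coef(ols1)), tolerance = 1e-10)
})

test_that("exchangeable GEE approaches OLS when clustering is absent", {
  d <- sim_table(published_coefficients("midcap")$beta, 60, 4, rho = 0, seed = 5)
  g <- fit_gee(d, "midcap")
  ols <- lm(rnct ~ nc_angle + imt + capt, data = d)
  expect_lt(abs(g$alpha), 0.1)
  expect_equal(unname(g$beta), unname(coef(ols)), tolerance = 0.02)
})

test_that("robust covariance matches the reference cluster sandwich", {
  skip_if_not_installed("sandwich")
  d <- sim_table(published_coefficients("midcap")$beta, 25, 4, seed = 6)
  g <- fit_gee(d, "midcap", corstr = "independence")
  ols <- lm(rnct ~ nc_angle + imt + capt, data = d)
  Vref <- sandwich::vcovCL(ols, cluster = d$artery_id, type = "HC0",
                           cadjust = FALSE)
  expect_equal(unname(g$covariance), unname(as.matrix(Vref)), tolerance = 1e-8)
})

test_that("sandwich covariance is invariant to cluster relabeling", {
  d <- sim_table(published_coefficients("midcap")$beta, 15, 5, seed = 7)
  g1 <- fit_gee(d, "midcap")
  d2 <- d[sample(nrow(d)), ]
  d2$artery_id <- paste0("c", d2$artery_id)
  g2 <- fit_gee(d2, "midcap")
  expect_equal(g1$beta, g2$beta, tolerance = 1e-9)
  expect_equal(g1$covariance, g2$covariance, tolerance = 1e-8)
})

test_that("coefficients are recovered within 2 robust SE on clustered data", {
  beta <- published_coefficients("midcap")$beta
  hits <- matrix(FALSE, 100, 4)
  for (r in 1:100) {
    d <- sim_table(beta, 50, 5, sd = 0.05, seed = 100 + r)
    g <- fit_gee(d, "midcap")
    se <- sqrt(diag(g$covariance))
    hits[r, ] <- abs(g$beta - beta) <= 2 * se
  }
  expect_true(all(colMeans(hits) >= 0.90))
})

test_that("estimator bias shrinks as clusters grow", {
  beta <- published_coefficients("midcap")$beta
  bias_at <- function(n_cl) {
    b <- vapply(1:12, function(r) {
      d <- sim_table(beta, n_cl, 5, seed = 500 + 13 * n_cl + r)
      fit_gee(d, "midcap")$beta[2]
    }, numeric(1))
    abs(median(b) - beta[2])
  }
  b <- c(bias_at(20), bias_at(200))
  expect_lt(b[2], b[1] + 1e-3)
})

test_that("Wald tests reproduce printed significance and null behavior", {
  cf <- gee_coefficients(c(0.1, 0, 0.29e-3, 0), "midcap",
                         covariance = diag(c(1e-4, 1e-4, (0.07e-3)^2, 1e-8)))
  w <- wald_tests(cf)
  expect_equal(w$z[3], 0.29 / 0.07, tolerance = 1e-6)   # ~4.14
  expect_lt(w$p[3], 0.05)
  expect_equal(w$p[w$estimate == 0], c(1, 1))
})

test_that("type-I error of the Wald test is near nominal", {
  set.seed(11)
  rej <- vapply(1:400, function(r) {
    d <- sim_table(c(0.3, 0.05, 2e-4, -4e-4), 40, 4, sd = 0.05,
                   seed = 2000 + r)
    d$null_cov <- rnorm(nrow(d))      # independent of the response
    g <- fit_gee(data.frame(rnct = d$rnct, nc_angle = d$null_cov,
                            imt = d$imt, capt = d$capt,
                            artery_id = d$artery_id), "midcap")
    wald_tests(g)$p[2] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.10)
})

test_that("degenerate designs raise informative errors", {
  d <- sim_table(published_coefficients("midcap")$beta, 10, 4, seed = 8)
  d$capt <- d$imt            # collinear
  expect_error(fit_gee(d, "midcap"), "collinear")
  d2 <- sim_table(published_coefficients("midcap")$beta, 1, 10, seed = 9)
  expect_error(fit_gee(d2, "midcap"), "clusters")
})

test_that("group averages pool sidecaps and use the cohort median", {
  cs <- concentric_cs()
  f3 <- characterize(cs)
  ga <- group_average_rnct(f3)
  expect_equal(ga$rnct_mid, 1 / 3, tolerance = 2e-3)
  expect_equal(ga$rnct_side, 1 / 3, tolerance = 2e-3)
  # three plaques with midcap rNCt 0.2 / 0.4 / 0.6 -> median 0.4
  fake <- lapply(c(0.2, 0.4, 0.6), function(v) {
    f <- f3[[1]]
    f$sites$rNCt <- c(v - 0.05, v, v + 0.05)
    f
  })
  expect_equal(group_average_rnct(fake)$rnct_mid, 0.4)
  expect_error(group_average_rnct(list()), "no features")
})

test_that("coefficient JSON round-trips", {
  d <- sim_table(published_coefficients("midcap")$beta, 12, 4, seed = 10)
  g <- fit_gee(d, "midcap")
  path <- tempfile(fileext = ".json")
  write_coefficients_json(g, path)
  g2 <- read_coefficients_json(path)
  expect_equal(g2$beta, g$beta, tolerance = 1e-12)
  expect_equal(g2$covariance, unname(g$covariance), tolerance = 1e-12)
  expect_equal(g2$r_squared, g$r_squared)
})
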