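# Plaque-specific relative NC thickness model:
#   rNCt_i = b0 + b_angle * NC angle [rad] + b_IMT * IMT [um] + b_capT * capT [um]
# fitted per site (midcap, pooled sidecaps) by generalized estimating
# equations with artery-level clustering and a robust sandwich covariance.

#' Construct a GEE coefficient set
#'
#' @param beta length-4 numeric: intercept, per-rad NC-angle slope, per-um IMT
#'   slope, per-um capT slope (natural scale, not the x1000 printed scale).
#' @param site "midcap" or "sidecap".
#' @param covariance 4x4 robust covariance (natural scale); may be NA.
#' @param r_squared squared Pearson correlation of fitted vs observed.
#' @param n_obs,n_clusters sample sizes; NA for packaged values.
#' @param alpha exchangeable working correlation estimate.
#' @return object of class `gee_coefficients`.
#' @export
gee_coefficients <- function(beta, site = c("midcap", "sidecap"),
                             covariance = matrix(NA_real_, 4, 4),
                             r_squared = NA_real_, n_obs = NA_integer_,
                             n_clusters = NA_integer_, alpha = NA_real_) {
  site <- match.arg(site)
  stopifnot(length(beta) == 4L)
  names(beta) <- c("beta0", "beta_angle", "beta_IMT", "beta_capT")
  structure(list(site = site, beta = beta, covariance = covariance,
                 r_squared = r_squared, n_obs = n_obs,
                 n_clusters = n_clusters, alpha = alpha),
            class = "gee_coefficients")
}

#' Packaged published coefficient sets
#'
#' The published model coefficients (printed x1000 with standard errors, here
#' de-scaled to natural units): midcap (187, 63.3, 0.29, -0.51) and sidecap
#' (175, 130, 0.18, -0.42), with r^2 0.47 and 0.44.
#'
#' @param site "midcap" or "sidecap".
#' @return a `gee_coefficients` object with a diagonal covariance built from
#'   the printed standard errors.
#' @export
published_coefficients <- function(site = c("midcap", "sidecap")) {
  site <- match.arg(site)
  if (site == "midcap") {
    beta <- c(187, 63.3, 0.29, -0.51) / 1000
    se <- c(55.4, 26.6, 0.07, 0.08) / 1000
    r2 <- 0.47
  } else {
    beta <- c(175, 130, 0.18, -0.42) / 1000
    se <- c(46.4, 19.8, 0.05, 0.06) / 1000
    r2 <- 0.44
  }
  gee_coefficients(beta, site, covariance = diag(se^2), r_squared = r2,
                   n_obs = 73L, n_clusters = 13L)
}

#' Predict relative NC thickness from plaque features
#'
#' Evaluates the linear relation at the given covariates. Predictions outside
#' (0, 1) are clamped to [0.01, 0.95] and flagged.
#'
#' @param coeffs a `gee_coefficients`.
#' @param nc_angle NC angle in radians.
#' @param imt intima-media thickness in micrometres.
#' @param capt cap thickness in micrometres.
#' @return numeric vector of rNCt predictions with attribute `clamped`
#'   (logical vector).
#' @export
predict_rnct <- function(coeffs, nc_angle, imt, capt) {
  stopifnot(all(imt > 0), all(capt > 0))
  eta <- coeffs$beta[1] + coeffs$beta[2] * nc_angle + coeffs$beta[3] * imt +
    coeffs$beta[4] * capt
  clamped <- eta < 0 | eta > 1
  if (any(clamped)) warning("rNCt prediction outside (0,1); clamped to [0.01, 0.95]")
  out <- unname(pmin(pmax(eta, 0.01), 0.95))
  attr(out, "clamped") <- unname(clamped)
  out
}

#' Fit the rNCt relation by generalized estimating equations
#'
#' Gaussian family, identity link, exchangeable working correlation across
#' cross-sections within an artery, iterated to convergence; the coefficient
#' covariance is the robust (sandwich) estimator of Liang and Zeger.
#'
#' @param data data.frame with columns rnct, nc_angle (rad), imt (um),
#'   capt (um), artery_id.
#' @param site label stored on the result ("midcap" or "sidecap").
#' @param corstr "exchangeable" (default) or "independence".
#' @param tol relative coefficient-change convergence tolerance.
#' @param maxit maximum iterations.
#' @return a `gee_coefficients` with covariance, r^2, alpha and sizes filled.
#' @export
fit_gee <- function(data, site = c("midcap", "sidecap"),
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-8, maxit = 100L) {
  site <- match.arg(site)
  corstr <- match.arg(corstr)
  X <- cbind(1, data$nc_angle, data$imt, data$capt)
  colnames(X) <- c("beta0", "beta_angle", "beta_IMT", "beta_capT")
  y <- data$rnct
  id <- as.character(data$artery_id)
  if (length(unique(id)) < 2L) stop("need at least 2 clusters")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "))
  }
  groups <- split(seq_along(y), id)
  beta <- qr.coef(qrX, y)           # OLS start
  alpha <- 0
  for (it in seq_len(maxit)) {
    res <- y - X %*% beta
    phi <- sum(res^2) / (length(y) - ncol(X))
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (g in groups) {
        ni <- length(g)
        if (ni > 1L) {
          s <- sum(res[g])^2 - sum(res[g]^2)
          num <- num + s / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      alpha <- if (den > 0) max(min(num / (den * phi), 0.99), -0.49) else 0
    }
    A <- matrix(0, ncol(X), ncol(X)); b <- numeric(ncol(X))
    for (g in groups) {
      ni <- length(g)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Wi <- solve(Ri) / phi
      Xg <- X[g, , drop = FALSE]
      A <- A + crossprod(Xg, Wi %*% Xg)
      b <- b + crossprod(Xg, Wi %*% y[g])
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta)) / max(max(abs(beta_new)), 1e-12)
    beta <- beta_new
    if (delta < tol) break
    if (it == maxit) stop("GEE did not converge in ", maxit,
                          " iterations (last rel. change ", signif(delta, 3), ")")
  }
  # sandwich covariance: B^-1 M B^-1
  res <- y - X %*% beta
  phi <- sum(res^2) / (length(y) - ncol(X))
  B <- matrix(0, ncol(X), ncol(X)); M <- matrix(0, ncol(X), ncol(X))
  for (g in groups) {
    ni <- length(g)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Wi <- solve(Ri) / phi
    Xg <- X[g, , drop = FALSE]
    B <- B + crossprod(Xg, Wi %*% Xg)
    u <- crossprod(Xg, Wi %*% res[g])
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  V <- (V + t(V)) / 2
  fitted <- as.numeric(X %*% beta)
  r2 <- stats::cor(fitted, y)^2
  gee_coefficients(as.numeric(beta), site, covariance = V, r_squared = r2,
                   n_obs = length(y), n_clusters = length(groups),
                   alpha = alpha)
}

#' Wald tests for fitted GEE coefficients
#'
#' @param coeffs a fitted `gee_coefficients` (covariance required).
#' @return data.frame: term, estimate, robust_se, z, p (two-sided normal).
#' @export
wald_tests <- function(coeffs) {
  se <- sqrt(diag(coeffs$covariance))
  z <- coeffs$beta / se
  z[coeffs$beta == 0] <- 0
  data.frame(term = names(coeffs$beta), estimate = as.numeric(coeffs$beta),
             robust_se = se, z = as.numeric(z),
             p = 2 * stats::pnorm(-abs(as.numeric(z))), row.names = NULL)
}

#' Group-averaged rNCt estimates from a characterized cohort
#'
#' The group-average reconstruction input: the cohort median of midcap rNCt
#' and the median of the pooled plus/minus sidecap rNCt.
#'
#' @param features list of `plaque_features` (or nested lists thereof).
#' @return list(rnct_mid, rnct_side).
#' @export
group_average_rnct <- function(features) {
  features <- unlist_features(features)
  if (length(features) == 0L) stop("no features supplied")
  mids <- vapply(features, function(f) f$sites$rNCt[f$sites$site == "midcap"],
                 numeric(1))
  sides <- unlist(lapply(features, function(f)
    f$sites$rNCt[f$sites$site %in% c("minus_sidecap", "plus_sidecap")]))
  list(rnct_mid = stats::median(mids), rnct_side = stats::median(sides))
}

#' Export/import GEE coefficients as JSON
#' @param coeffs a `gee_coefficients`.
#' @param path file path.
#' @return `read_coefficients_json` returns a `gee_coefficients`.
#' @export
write_coefficients_json <- function(coeffs, path) {
  jsonlite::write_json(list(site = coeffs$site, beta = as.numeric(coeffs$beta),
                            covariance = coeffs$covariance,
                            r_squared = coeffs$r_squared, n_obs = coeffs$n_obs,
                            n_clusters = coeffs$n_clusters, alpha = coeffs$alpha),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients_json
#' @export
read_coefficients_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gee_coefficients(j$beta, j$site, covariance = as.matrix(j$covariance),
                   r_squared = j$r_squared, n_obs = j$n_obs,
                   n_clusters = j$n_clusters, alpha = j$alpha %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
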