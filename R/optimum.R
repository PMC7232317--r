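#' Stationary point of a fitted quadratic surface
#'
#' Writes the fitted polynomial as \eqn{\hat Y = b_0 + b'x + x'Bx} with the
#' symmetric curvature matrix \eqn{B} (diagonal = pure quadratic
#' coefficients, off-diagonal = half the interaction coefficients), solves
#' \eqn{x_s = -\tfrac12 B^{-1} b} where the gradient vanishes, and
#' classifies the curvature from the eigenvalues of \eqn{B}.
#'
#' @param fit A \code{quad_fit}.
#' @param region_radius Radius (coded units) used for the
#'   \code{inside_region} flag; defaults to the design's axial distance.
#' @return Object of class \code{stationary_point}: coded and real
#'   coordinates, predicted response, eigenvalues, classification
#'   (\code{"maximum"}, \code{"minimum"}, \code{"saddle"} or
#'   \code{"ridge"} when some eigenvalue is numerically zero), and an
#'   inside-region flag.  A numerically singular curvature matrix triggers a
#'   warning and a pseudo-inverse (ridge) solution flagged in the result.
#' @examples
#' fit <- fit_quadratic(allethrin_ccd())
#' stationary_point(fit)
#' @export
stationary_point <- function(fit, region_radius = NULL) {
  stopifnot(inherits(fit, "quad_fit"))
  k <- fit$k
  B <- curvature_matrix(fit)
  b <- unname(fit$linear)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  singular <- any(abs(ev) < 1e-10 * max(abs(ev), 1))
  if (singular) {
    warning("curvature matrix is numerically singular; ",
            "reporting a pseudo-inverse (ridge system) solution")
    xs <- -0.5 * drop(pseudo_solve(B, b))
  } else {
    xs <- -0.5 * drop(solve(B, b))
  }
  classification <- classify_curvature(ev)
  if (is.null(region_radius))
    region_radius <- attr(fit$design, "alpha") %||% 1
  real <- if (!is.null(fit$factors)) {
    vapply(seq_len(k), function(i) decode_value(xs[i], fit$factors[[i]]),
           0)
  } else rep(NA_real_, k)
  structure(
    list(
      coded = stats::setNames(xs, fit$factor_names),
      real = stats::setNames(real, fit$factor_names),
      predicted = unname(predict(fit, xs)),
      eigenvalues = ev,
      classification = classification,
      inside_region = sqrt(sum(xs^2)) <= region_radius,
      singular = singular
    ),
    class = "stationary_point"
  )
}

curvature_matrix <- function(fit) {
  k <- fit$k
  B <- diag(unname(fit$quadratic), k)
  if (k >= 2L) {
    idx <- 1L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      B[i, j] <- B[j, i] <- unname(fit$interaction[idx]) / 2
      idx <- idx + 1L
    }
  }
  B
}

classify_curvature <- function(ev, tol = 1e-10) {
  scale <- max(abs(ev), 1)
  if (any(abs(ev) < tol * scale)) "ridge"
  else if (all(ev < 0)) "maximum"
  else if (all(ev > 0)) "minimum"
  else "saddle"
}

pseudo_solve <- function(A, b) {
  s <- svd(A)
  pos <- s$d > 1e-12 * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% b) / s$d[pos])
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("Stationary point (%s%s): predicted response %.2f\n",
              x$classification,
              if (x$inside_region) ", inside design region" else
                ", OUTSIDE design region",
              x$predicted))
  cat("coded:", paste(sprintf("%s = %.4f", names(x$coded), x$coded),
                      collapse = ", "), "\n")
  if (!any(is.na(x$real)))
    cat("real: ", paste(sprintf("%s = %.4g", names(x$real), x$real),
                        collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Constrained optimum of the fitted surface
#'
#' Maximizes the fitted quadratic inside the design region — either the
#' coded cube \eqn{[-r, r]^k} or the sphere \eqn{\|x\| \le r}.  If the
#' stationary point is an interior maximum it is returned directly.  The
#' cube search uses multi-start quasi-Newton optimization (corners, center
#' and seeded random starts); the sphere search solves the trust-region
#' secular equation exactly from the eigendecomposition of the curvature
#' matrix.
#'
#' @param fit A \code{quad_fit}.
#' @param bounds \code{"cube"} or \code{"sphere"}.
#' @param radius Half-width / radius \eqn{r} in coded units; defaults to the
#'   design's axial distance.
#' @param n_starts Random multi-starts for the cube search.
#' @param seed Seed for the random starts (deterministic search).
#' @return List with \code{coded}, \code{real}, \code{predicted} and
#'   \code{bounds}.
#' @export
constrained_optimum <- function(fit, bounds = c("cube", "sphere"),
                                radius = NULL, n_starts = 20L, seed = 1L) {
  bounds <- match.arg(bounds)
  stopifnot(inherits(fit, "quad_fit"))
  k <- fit$k
  if (is.null(radius)) radius <- attr(fit$design, "alpha") %||% 1
  if (radius < 0) stop("'radius' must be >= 0", call. = FALSE)
  B <- curvature_matrix(fit)
  bl <- unname(fit$linear)

  if (radius == 0) {
    xb <- rep(0, k)
  } else if (bounds == "sphere") {
    xb <- sphere_max_quadratic(B, bl, radius)
  } else {
    negf <- function(x) -drop(predict(fit, x))
    neggrad <- function(x) -(bl + 2 * drop(B %*% x))
    corners <- as.matrix(expand.grid(rep(list(c(-radius, radius)), k)))
    starts <- rbind(rep(0, k), corners,
                    local_seed(seed, matrix(stats::runif(n_starts * k,
                                                         -radius, radius),
                                            ncol = k)))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ], negf, neggrad, method = "L-BFGS-B",
                        lower = rep(-radius, k), upper = rep(radius, k))
      if (is.null(best) || o$value < best$value) best <- o
    }
    xb <- best$par
  }
  real <- if (!is.null(fit$factors)) {
    vapply(seq_len(k), function(i) decode_value(xb[i], fit$factors[[i]]), 0)
  } else rep(NA_real_, k)
  list(
    coded = stats::setNames(xb, fit$factor_names),
    real = stats::setNames(real, fit$factor_names),
    predicted = unname(predict(fit, xb)),
    bounds = bounds, radius = radius
  )
}

# exact maximization of b'x + x'Bx subject to ||x|| <= r
# (trust-region secular equation on the eigenbasis of B)
sphere_max_quadratic <- function(B, b, r) {
  k <- length(b)
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values                      # descending
  bt <- drop(t(e$vectors) %*% b) / 2   # gradient of b'x is b; stationarity:
  # (B - mu I) x = -b/2  with mu >= lam_max for a boundary maximum
  interior <- all(lam < 0)
  if (interior) {
    xs <- -0.5 * drop(solve(B, b))
    if (sqrt(sum(xs^2)) <= r) return(xs)
  }
  normx <- function(mu) sqrt(sum((bt / (mu - lam))^2))
  lo <- max(lam) + 1e-10
  # handle the "hard case": component along the top eigenvector vanishes
  if (abs(bt[1]) < 1e-14 && normx(lo + 1e-8) < r) {
    mu <- max(lam)
    xpart <- ifelse(abs(mu - lam) < 1e-12, 0, bt / (mu - lam))
    tau <- sqrt(max(r^2 - sum(xpart^2), 0))
    x <- drop(e$vectors %*% xpart) + tau * e$vectors[, 1L]
    return(x)
  }
  hi <- max(lam) + sqrt(sum(bt^2)) / r + 1
  while (normx(hi) > r) hi <- hi * 2
  mu <- stats::uniroot(function(m) normx(m) - r, c(lo, hi),
                       tol = 1e-12)$root
  drop(e$vectors %*% (bt / (mu - lam)))
}

#' Box-Cox transformation scan for the quadratic model
#'
#' Profiles the Box-Cox log-likelihood of the quadratic response-surface
#' model over a grid of power parameters \eqn{\lambda}, using the
#' geometric-mean-scaled transform
#' \eqn{z(\lambda) = (y^\lambda - 1) / (\lambda \dot{y}^{\lambda - 1})}
#' (with the \eqn{\log} limit at \eqn{\lambda = 0}), and reports the best
#' \eqn{\lambda} with a profile-likelihood confidence interval at cutoff
#' \eqn{\chi^2_1(level)/2} below the maximum.
#'
#' @param design A \code{ccd_design} with strictly positive responses.
#' @param lambda Grid of lambda values to scan.
#' @param level Confidence level for the interval (default 0.95).
#' @return Object of class \code{boxcox_scan}: \code{lambda},
#'   \code{loglik}, \code{best}, \code{ci} (interval bounds on the grid),
#'   \code{level}, and \code{inconclusive} (flat-profile flag for
#'   degenerate data).
#' @examples
#' bc <- boxcox_scan(allethrin_ccd())
#' bc$best          # 1.72 on the bundled allethrin table
#' @export
boxcox_scan <- function(design, lambda = seq(-3, 5, by = 0.01),
                        level = 0.95) {
  stopifnot(inherits(design, "ccd_design"))
  y <- design$y_mean
  if (is.null(y)) stop("design carries no responses", call. = FALSE)
  if (any(y <= 0))
    stop("Box-Cox requires strictly positive responses", call. = FALSE)
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    # no response variation: every transform fits perfectly
    return(structure(list(lambda = lambda, loglik = rep(Inf, length(lambda)),
                          best = NA_real_, ci = c(NA_real_, NA_real_),
                          level = level, inconclusive = TRUE),
                     class = "boxcox_scan"))
  }
  xm <- coded_matrix(design)
  mm <- quad_model_matrix(xm)
  qrx <- qr(mm)
  n <- length(y)
  gm <- exp(mean(log(y)))
  loglik <- vapply(lambda, function(l) {
    z <- if (abs(l) < 1e-9) gm * log(y) else (y^l - 1) / (l * gm^(l - 1))
    rss <- sum(qr.resid(qrx, z)^2)
    if (rss <= 0) return(Inf)
    -n / 2 * log(rss / n)
  }, 0)
  if (!any(is.finite(loglik)) || diff(range(loglik)) < 1e-12) {
    return(structure(list(lambda = lambda, loglik = loglik,
                          best = NA_real_, ci = c(NA_real_, NA_real_),
                          level = level, inconclusive = TRUE),
                     class = "boxcox_scan"))
  }
  best <- lambda[which.max(loglik)]
  cut <- max(loglik) - stats::qchisq(level, 1) / 2
  inside <- lambda[loglik > cut]
  structure(
    list(lambda = lambda, loglik = loglik, best = best,
         ci = range(inside), level = level, inconclusive = FALSE),
    class = "boxcox_scan"
  )
}

#' @export
print.boxcox_scan <- function(x, ...) {
  if (x$inconclusive) {
    cat("Box-Cox scan: flat profile, inconclusive\n")
  } else {
    cat(sprintf("Box-Cox scan: best lambda = %.2f, %d%% interval (%.2f, %.2f)\n",
                x$best, round(100 * x$level), x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Prediction grid over two factors
#'
#' Evaluates the fitted surface on a regular coded grid over one factor
#' pair, holding the remaining factors at fixed coded values — the numeric
#' backbone of contour and 3-D response-surface plots.
#'
#' @param fit A \code{quad_fit}.
#' @param pair Length-2 vector of factor names or indices (distinct).
#' @param fixed Coded values for the remaining factors (recycled;
#'   default 0 = center).
#' @param resolution Grid points per axis (>= 2).
#' @param limit Half-width of the coded grid; defaults to the axial
#'   distance.
#' @return Data frame in long format: the two varied coordinates (named
#'   after the factors), the fixed coordinates, and \code{y_pred}; the grid
#'   vectors are attached as attributes \code{"g1"} and \code{"g2"}.
#' @export
surface_grid <- function(fit, pair, fixed = 0, resolution = 41L,
                         limit = NULL) {
  stopifnot(inherits(fit, "quad_fit"))
  k <- fit$k
  if (is.character(pair)) pair <- match(pair, fit$factor_names)
  pair <- as.integer(pair)
  if (length(pair) != 2L || any(is.na(pair)) || pair[1] == pair[2] ||
      any(pair < 1L) || any(pair > k))
    stop("'pair' must name two distinct factors of the fit", call. = FALSE)
  resolution <- as.integer(resolution)
  if (resolution < 2L) stop("'resolution' must be >= 2", call. = FALSE)
  if (is.null(limit)) limit <- attr(fit$design, "alpha") %||% 1
  others <- setdiff(seq_len(k), pair)
  fixed <- rep_len(fixed, length(others))
  g <- seq(-limit, limit, length.out = resolution)
  grid <- expand.grid(g1 = g, g2 = g)
  pts <- matrix(0, nrow(grid), k)
  pts[, pair[1]] <- grid$g1
  pts[, pair[2]] <- grid$g2
  for (i in seq_along(others)) pts[, others[i]] <- fixed[i]
  out <- as.data.frame(pts)
  names(out) <- fit$factor_names
  out$y_pred <- predict(fit, pts)
  attr(out, "g1") <- g
  attr(out, "g2") <- g
  attr(out, "pair") <- fit$factor_names[pair]
  out
}
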