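#' Simulate replicate responses from a true quadratic surface
#'
#' Draws, for every design run, \code{n_rep} replicate responses equal to
#' the true polynomial value plus independent homoscedastic Gaussian noise,
#' then records the replicate mean and standard error per run — the same
#' structure as a replicated degradation experiment (percent responses are
#' clipped to [0, 100]; the number of clipped draws is reported).
#'
#' @param design A \code{ccd_design}.
#' @param coef Named true coefficient vector in the layout of a
#'   [fit_quadratic()] coefficient set (\code{(Intercept)}, linear terms
#'   named after the factors, \code{a:b} interactions, \code{a^2}
#'   quadratics).  Missing terms default to 0.  The default is the
#'   coefficient set refitted from the bundled allethrin table.
#' @param sd Replicate noise standard deviation in response units
#'   (default 0.6, matching the replicate scatter of the bundled table).
#' @param n_rep Replicates per run (default 3).
#' @param seed Integer seed; the generator is bit-reproducible per seed.
#' @param clip Clip range for the response (default \code{c(0, 100)} for
#'   percentages; use \code{NULL} to disable).
#' @return The design with \code{y_mean}, \code{y_se}, \code{n_rep} columns
#'   attached; attributes \code{"replicates"} (runs x n_rep matrix),
#'   \code{"truth"} (full named truth vector) and \code{"n_clipped"}.
#' @examples
#' des <- ccd_design(3, n_center = 10)
#' sim <- simulate_response_surface(des, seed = 42)
#' head(sim$y_mean)
#' @export
simulate_response_surface <- function(design, coef = NULL, sd = 0.6,
                                      n_rep = 3L, seed = 1L,
                                      clip = c(0, 100)) {
  stopifnot(inherits(design, "ccd_design"))
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  n_rep <- as.integer(n_rep)
  if (n_rep < 1L) stop("'n_rep' must be >= 1", call. = FALSE)
  xm <- coded_matrix(design)
  mm <- quad_model_matrix(xm)
  if (is.null(coef)) coef <- stats::coef(fit_quadratic(allethrin_ccd()))
  full <- stats::setNames(numeric(ncol(mm)), colnames(mm))
  if (is.null(names(coef)) || !all(names(coef) %in% names(full))) {
    # a full-length vector (e.g. taken from a fit on differently named
    # factors) is matched positionally: the term layout is identical
    if (length(coef) != length(full))
      stop("unknown coefficient name(s): ",
           paste(setdiff(names(coef), names(full)), collapse = ", "),
           call. = FALSE)
    full[] <- coef
  } else {
    full[names(coef)] <- coef
  }
  truth <- drop(mm %*% full)

  reps <- local_seed(seed, {
    matrix(stats::rnorm(nrow(mm) * n_rep, mean = rep(truth, each = n_rep),
                        sd = sd),
           nrow = nrow(mm), byrow = TRUE)
  })
  n_clipped <- 0L
  if (!is.null(clip)) {
    n_clipped <- sum(reps < clip[1L] | reps > clip[2L])
    reps <- pmin(pmax(reps, clip[1L]), clip[2L])
  }
  m <- rowMeans(reps)
  se <- if (n_rep > 1L) apply(reps, 1L, stats::sd) / sqrt(n_rep)
        else rep(0, nrow(reps))
  out <- set_response(design, m, se, n_rep)
  attr(out, "replicates") <- reps
  attr(out, "truth") <- full
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Simulate a noisy exponential decay curve
#'
#' Generates \eqn{C_0 e^{-kt}} plus additive Gaussian noise; values below
#' the detection floor are recorded as 0 (non-detect), and negative draws
#' are truncated at 0.  Deterministic per seed.
#'
#' @param C0 True initial concentration (mg/L, > 0); default 50, a typical
#'   spike level for pesticide dissipation assays.
#' @param k True rate constant (1/h, >= 0); default 0.0193.
#' @param times Sampling times in hours; default 0-144 h at 24 h intervals.
#' @param sd Additive noise SD (mg/L); default 1.
#' @param floor Detection floor (mg/L); default 0.5.
#' @param seed Integer seed.
#' @param label Curve label.
#' @return A [decay_curve()].
#' @examples
#' simulate_decay(seed = 7)
#' @export
simulate_decay <- function(C0 = 50, k = 0.0193, times = seq(0, 144, by = 24),
                           sd = 1, floor = 0.5, seed = 1L,
                           label = "treatment") {
  if (C0 <= 0) stop("'C0' must be > 0", call. = FALSE)
  if (k < 0) stop("'k' must be >= 0", call. = FALSE)
  if (sd < 0 || floor < 0) stop("'sd' and 'floor' must be >= 0", call. = FALSE)
  if (length(times) < 2L) stop("need at least 2 sampling times", call. = FALSE)
  true <- C0 * exp(-k * times)
  obs <- local_seed(seed, true + stats::rnorm(length(times), 0, sd))
  obs <- pmax(obs, 0)
  obs[obs < floor] <- 0
  decay_curve(times, obs, label = label, C0 = C0)
}
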