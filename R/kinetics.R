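#' Construct a concentration-time decay curve
#'
#' @param time Sampling times in hours; non-negative, strictly increasing.
#' @param conc Concentrations in mg/L; non-negative, same length as
#'   \code{time}.
#' @param label Curve label, conventionally \code{"control"} or
#'   \code{"treatment"}.
#' @param C0 Nominal initial concentration (defaults to the first observed
#'   concentration).
#' @return Object of class \code{decay_curve}.
#' @examples
#' dc <- decay_curve(seq(0, 144, 24), 50 * exp(-0.0193 * seq(0, 144, 24)))
#' @export
decay_curve <- function(time, conc, label = "treatment", C0 = NULL) {
  time <- as.numeric(time); conc <- as.numeric(conc)
  if (length(time) != length(conc))
    stop("'time' and 'conc' must have the same length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(
    list(time = time, conc = conc, label = as.character(label),
         C0 = if (is.null(C0)) conc[1L] else as.numeric(C0)),
    class = "decay_curve"
  )
}

#' Read a concentration time series from delimited text
#'
#' Expects comma-separated columns \code{time_h, conc_mg_L} and optionally
#' \code{replicate} and \code{label}.  Replicates are averaged per time
#' point; with several labels a named list of curves is returned.
#'
#' @param path File path.
#' @return A \code{decay_curve}, or a named list of them.
#' @export
read_decay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df) || !all(c("time_h", "conc_mg_L") %in% names(df)))
    stop("time-series file needs columns 'time_h' and 'conc_mg_L'",
         call. = FALSE)
  if (is.null(df$label)) df$label <- "treatment"
  one <- function(d, lab) {
    agg <- stats::aggregate(conc_mg_L ~ time_h, data = d, FUN = mean)
    agg <- agg[order(agg$time_h), ]
    decay_curve(agg$time_h, agg$conc_mg_L, label = lab)
  }
  labs <- unique(df$label)
  curves <- lapply(labs, function(l) one(df[df$label == l, ], l))
  names(curves) <- labs
  if (length(curves) == 1L) curves[[1L]] else curves
}

#' Fit first-order dissipation kinetics
#'
#' Fits the exponential decay model \eqn{C_t = C_0 e^{-kt}} to a
#' concentration-time curve.  \code{method = "log_linear"} regresses
#' \eqn{\ln C} on \eqn{t} (slope \eqn{-k}); zero concentrations cannot enter
#' the log and are excluded with a warning.  \code{method = "nonlinear"}
#' (default) minimizes the residual sum of squares on the concentration
#' scale, initialized from the log-linear estimate, with \eqn{k \ge 0} and
#' \eqn{C_0 > 0} enforced; zeros are used as-is.  \eqn{R^2} is reported on
#' the concentration scale in both cases.
#'
#' @param curve A [decay_curve()].
#' @param method \code{"nonlinear"} or \code{"log_linear"}.
#' @return Object of class \code{kinetics_fit}: \code{k} (1/h), \code{C0}
#'   (mg/L), \code{half_life} (h, \eqn{\ln 2/k}), \code{r_squared},
#'   \code{method}, \code{fitted}, \code{label}.
#' @examples
#' tt <- seq(0, 144, 24)
#' fit <- fit_first_order(decay_curve(tt, 50 * exp(-0.0193 * tt)))
#' c(fit$k, fit$half_life)
#' @export
fit_first_order <- function(curve, method = c("nonlinear", "log_linear")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "decay_curve"))
  t <- curve$time; y <- curve$conc
  if (all(y == 0)) stop("all concentrations are zero: nothing to fit",
                        call. = FALSE)
  pos <- y > 0
  if (sum(pos) < 3L)
    stop("need at least 3 positive concentrations to fit", call. = FALSE)

  # log-linear start / fit
  if (method == "log_linear" && any(!pos))
    warning(sum(!pos), " zero concentration(s) excluded from the log fit ",
            "(left-censored at the detection limit)")
  ll <- stats::lm(log(y[pos]) ~ t[pos])
  k_ll <- max(-unname(stats::coef(ll)[2L]), 0)
  C0_ll <- exp(unname(stats::coef(ll)[1L]))

  if (method == "log_linear") {
    k <- k_ll; C0 <- C0_ll
  } else {
    sse_fun <- function(p) sum((y - p[1L] * exp(-p[2L] * t))^2)
    grad_fun <- function(p) {
      e <- exp(-p[2L] * t)
      r <- y - p[1L] * e
      c(-2 * sum(r * e), 2 * p[1L] * sum(r * e * t))
    }
    o <- stats::optim(c(max(C0_ll, 1e-8), k_ll), sse_fun, grad_fun,
                      method = "L-BFGS-B", lower = c(1e-10, 0),
                      control = list(factr = 1e1, maxit = 500L))
    C0 <- o$par[1L]; k <- o$par[2L]
  }
  fitted <- C0 * exp(-k * t)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(k = k, C0 = C0,
         half_life = half_life(k),
         r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
         method = method, label = curve$label,
         time = t, conc = y, fitted = fitted),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("First-order kinetics (%s, %s): k = %.4g 1/h, C0 = %.4g mg/L, t1/2 = %.2f h, R2 = %.3f\n",
              x$label, x$method, x$k, x$C0, x$half_life, x$r_squared))
  invisible(x)
}

#' First-order half-life
#'
#' \eqn{t_{1/2} = \ln 2 / k}.  A zero rate constant gives an infinite
#' half-life (with a warning); negative rates are invalid.
#'
#' @param k Rate constant in 1/h.
#' @return Half-life in hours.
#' @examples
#' half_life(0.0013)   # 533.19 h
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k))
    stop("'k' must be a single finite number", call. = FALSE)
  if (k < 0) stop("rate constant must be >= 0", call. = FALSE)
  if (k == 0) {
    warning("zero rate constant: half-life is infinite")
    return(Inf)
  }
  log(2) / k
}

#' Percent of the substrate dissipated by a given time
#'
#' \eqn{100 (1 - C(t)/C(0))}, with \eqn{C(t)} linearly interpolated between
#' observed time points.
#'
#' @param curve A [decay_curve()].
#' @param at_time Time (h) within the observed range.
#' @return Percentage dissipated.
#' @export
percent_dissipated <- function(curve, at_time) {
  stopifnot(inherits(curve, "decay_curve"))
  if (at_time < min(curve$time) || at_time > max(curve$time))
    stop("'at_time' outside the observed time range", call. = FALSE)
  c0 <- curve$conc[1L]
  if (c0 <= 0) stop("baseline concentration must be > 0", call. = FALSE)
  ct <- stats::approx(curve$time, curve$conc, xout = at_time)$y
  100 * (1 - ct / c0)
}

#' Compare treatment and control kinetics
#'
#' @param control,treatment \code{kinetics_fit} objects.
#' @return List with \code{half_life_reduction} (control minus treatment,
#'   hours) and \code{k_ratio} (treatment over control).
#' @examples
#' \dontrun{compare_treatments(fit_ctrl, fit_cf2)}
#' @export
compare_treatments <- function(control, treatment) {
  stopifnot(inherits(control, "kinetics_fit"),
            inherits(treatment, "kinetics_fit"))
  list(
    half_life_reduction = control$half_life - treatment$half_life,
    k_ratio = if (control$k > 0) treatment$k / control$k else Inf
  )
}
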