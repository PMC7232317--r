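#' Fit the second-order response-surface polynomial
#'
#' Fits, by ordinary least squares on the coded factor scale, the full
#' quadratic model
#' \deqn{Y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j +
#'       \sum_i b_{ii} x_i^2,}
#' i.e. intercept, \eqn{k} linear terms, \eqn{k(k-1)/2} two-way interactions
#' and \eqn{k} pure quadratic terms (10 parameters for \eqn{k = 3}).
#'
#' @param design A \code{ccd_design} with responses attached (column
#'   \code{y_mean}; see [set_response()] or [simulate_response_surface()]).
#' @param basis \code{"means"} (default) fits the per-run mean responses —
#'   one observation per design point; \code{"replicates"} expands each run
#'   into \code{n_rep} pseudo-replicates with the recorded mean and standard
#'   error (for a balanced design the coefficient estimates are identical,
#'   only the error degrees of freedom differ).
#'
#' @return An object of class \code{quad_fit}: coefficients split into
#'   intercept / linear / interaction / quadratic blocks, the underlying
#'   \code{lm} fit, sums of squares (SST = SSR + SSE) and degrees of freedom.
#' @examples
#' des <- allethrin_ccd()
#' fit <- fit_quadratic(des)
#' round(coef(fit), 4)
#' @export
fit_quadratic <- function(design, basis = c("means", "replicates")) {
  basis <- match.arg(basis)
  stopifnot(inherits(design, "ccd_design"))
  if (is.null(design$y_mean))
    stop("design carries no responses; attach them with set_response()",
         call. = FALSE)
  if (any(!is.finite(design$y_mean)))
    stop("all mean responses must be finite", call. = FALSE)

  xm <- coded_matrix(design)
  k <- ncol(xm)
  y <- design$y_mean

  if (basis == "replicates") {
    if (is.null(design$y_se) || any(is.na(design$y_se)) ||
        is.null(design$n_rep) || any(is.na(design$n_rep)))
      stop("replicate basis needs 'y_se' and 'n_rep' for every run",
           call. = FALSE)
    n_rep <- design$n_rep
    if (any(n_rep < 2L))
      stop("replicate basis needs n_rep >= 2", call. = FALSE)
    # expand mean +/- se into pseudo-replicates preserving mean and SE:
    # symmetric three-point sets {m - d, m, m + d} with d = se * sqrt(3)
    # (sample SD = d = se * sqrt(n) for n = 3)
    if (any(n_rep != 3L))
      stop("replicate expansion is defined for n_rep = 3", call. = FALSE)
    d <- design$y_se * sqrt(3)
    y <- as.vector(rbind(design$y_mean - d, design$y_mean, design$y_mean + d))
    xm <- xm[rep(seq_len(nrow(xm)), each = 3L), , drop = FALSE]
  }

  mm <- quad_model_matrix(xm)
  p <- ncol(mm)
  if (nrow(mm) <= p)
    stop("need more than ", p, " runs with responses to fit the model",
         call. = FALSE)
  qrx <- qr(mm)
  if (qrx$rank < p) {
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("singular design: collinear model columns ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  df <- data.frame(y = y, mm[, -1L, drop = FALSE], check.names = FALSE)
  lmfit <- stats::lm(y ~ ., data = df)
  res <- stats::resid(lmfit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)

  cn <- colnames(mm)
  co <- stats::coef(lmfit)
  names(co) <- cn
  fnames <- colnames(xm)
  structure(
    list(
      coefficients = co,
      intercept = unname(co[1L]),
      linear = co[1L + seq_len(k)],
      interaction = co[grep(":", cn)],
      quadratic = co[grep("\\^2$", cn)],
      lm = lmfit,
      term_names = cn,
      factor_names = fnames,
      factors = attr(design, "factors"),
      k = k,
      p = p,
      n = length(y),
      basis = basis,
      sst = sst, sse = sse, ssr = sst - sse,
      df_model = p - 1L,
      df_resid = length(y) - p,
      fitted = stats::fitted(lmfit),
      residuals = res,
      design = design
    ),
    class = "quad_fit"
  )
}

# model matrix with columns (Intercept), x1..xk, xi:xj (i<j), x1^2..xk^2
quad_model_matrix <- function(xm) {
  k <- ncol(xm)
  nm <- colnames(xm)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  cols <- list(`(Intercept)` = rep(1, nrow(xm)))
  for (i in seq_len(k)) cols[[nm[i]]] <- xm[, i]
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      cols[[paste0(nm[i], ":", nm[j])]] <- xm[, i] * xm[, j]
  }
  for (i in seq_len(k)) cols[[paste0(nm[i], "^2")]] <- xm[, i]^2
  do.call(cbind, cols)
}

#' @export
coef.quad_fit <- function(object, ...) object$coefficients

#' @export
print.quad_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Second-order response-surface fit (%d factors, %d obs, %s basis)\n",
    x$k, x$n, x$basis))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Predict from a quadratic response-surface fit
#'
#' Evaluates the fitted polynomial at coded coordinates; optionally returns
#' the standard error of the mean prediction from the coefficient covariance.
#'
#' @param object A \code{quad_fit}.
#' @param newdata Matrix or data frame of coded coordinates (one column per
#'   factor, in the fit's factor order), or a single numeric vector of
#'   length \eqn{k}.
#' @param se.fit If \code{TRUE}, also return prediction standard errors.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a list with \code{fit} and
#'   \code{se.fit} components.
#' @export
predict.quad_fit <- function(object, newdata, se.fit = FALSE, ...) {
  if (is.null(dim(newdata))) {
    if (length(newdata) != object$k)
      stop("coded point must have length k = ", object$k, call. = FALSE)
    newdata <- matrix(newdata, nrow = 1L)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$k)
    stop("'newdata' must have k = ", object$k, " columns", call. = FALSE)
  if (any(!is.finite(newdata)))
    stop("coded coordinates must be finite", call. = FALSE)
  colnames(newdata) <- object$factor_names
  mm <- quad_model_matrix(newdata)
  yhat <- drop(mm %*% object$coefficients)
  if (!se.fit) return(yhat)
  V <- suppressWarnings(stats::vcov(object$lm))
  se <- sqrt(rowSums((mm %*% V) * mm))
  list(fit = yhat, se.fit = unname(se))
}

#' ANOVA and summary statistics for a response-surface fit
#'
#' Computes the regression F test and the adequacy measures customarily
#' reported for response-surface models: \eqn{R^2}, adjusted \eqn{R^2},
#' PRESS and the prediction-based \eqn{R^2_{pred} = 1 - PRESS/SST}, and the
#' coefficient of variation \eqn{CV = 100\sqrt{MSE}/\bar{Y}} (percent).
#' PRESS is the closed-form leave-one-out statistic
#' \eqn{\sum_i (e_i/(1-h_{ii}))^2}.
#'
#' @param fit A \code{quad_fit}.
#' @return An object of class \code{rsm_anova}: list with \code{F},
#'   \code{p_value}, \code{r_squared}, \code{adj_r_squared},
#'   \code{pred_r_squared}, \code{press}, \code{cv}, sums of squares, and a
#'   per-coefficient table (\code{estimate}, \code{se}, \code{t}, \code{p}).
#'   A perfect (zero-residual) fit is flagged with \code{perfect_fit = TRUE}
#'   and an infinite F.
#' @examples
#' fit <- fit_quadratic(allethrin_ccd())
#' rsm_anova(fit)
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "quad_fit"))
  if (fit$df_resid < 1L)
    stop("no residual degrees of freedom: statistics undefined", call. = FALSE)
  sse <- fit$sse; sst <- fit$sst; ssr <- fit$ssr
  mse <- sse / fit$df_resid
  perfect <- sse <= 1e-10 * max(sst, 1)
  Fval <- if (perfect) Inf else (ssr / fit$df_model) / mse
  pval <- if (perfect) 0 else
    stats::pf(Fval, fit$df_model, fit$df_resid, lower.tail = FALSE)
  h <- stats::hatvalues(fit$lm)
  press_terms <- ifelse(abs(1 - h) < 1e-12, NA_real_,
                        (fit$residuals / (1 - h))^2)
  press <- sum(press_terms)

  V <- suppressWarnings(stats::vcov(fit$lm))  # zero-residual fits warn
  se <- sqrt(diag(V))
  est <- fit$coefficients
  tval <- est / se
  coefs <- data.frame(
    term = fit$term_names,
    estimate = unname(est),
    se = unname(se),
    t = unname(tval),
    p = 2 * stats::pt(abs(tval), fit$df_resid, lower.tail = FALSE),
    row.names = NULL
  )
  structure(
    list(
      F = Fval,
      p_value = pval,
      r_squared = 1 - sse / sst,
      adj_r_squared = 1 - mse / (sst / (fit$n - 1L)),
      pred_r_squared = 1 - press / sst,
      press = press,
      cv = 100 * sqrt(mse) / mean(fit$design$y_mean, na.rm = TRUE),
      sst = sst, ssr = ssr, sse = sse, mse = mse,
      df_model = fit$df_model, df_resid = fit$df_resid,
      perfect_fit = perfect,
      coefficients = coefs
    ),
    class = "rsm_anova"
  )
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.2f, p = %.3g\n", x$df_model, x$df_resid,
              x$F, x$p_value))
  cat(sprintf("R2 = %.4f  adj R2 = %.4f  pred R2 = %.4f  CV = %.2f%%\n",
              x$r_squared, x$adj_r_squared, x$pred_r_squared, x$cv))
  if (x$perfect_fit) cat("(perfect fit: zero residual sum of squares)\n")
  invisible(x)
}

#' Per-run regression diagnostics
#'
#' Leverage (hat values), internally and externally studentized residuals,
#' and Cook's distance for each run of the fit.  The leverages always sum to
#' the number of model parameters; runs with leverage 1 get \code{NA}
#' studentized residuals and Cook's distances rather than an error.
#'
#' @param fit A \code{quad_fit}.
#' @return Data frame with columns \code{run}, \code{observed},
#'   \code{predicted}, \code{residual}, \code{leverage},
#'   \code{student_internal}, \code{student_external}, \code{cooks_d}.
#' @export
rsm_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "quad_fit"))
  if (fit$df_resid < 2L)
    stop("need at least 2 residual degrees of freedom", call. = FALSE)
  lmfit <- fit$lm
  h <- stats::hatvalues(lmfit)
  run <- if (fit$basis == "means") fit$design$run else seq_len(fit$n)
  data.frame(
    run = run,
    observed = fit$fitted + fit$residuals,
    predicted = fit$fitted,
    residual = fit$residuals,
    leverage = unname(h),
    student_internal = unname(stats::rstandard(lmfit)),
    student_external = unname(stats::rstudent(lmfit)),
    cooks_d = unname(stats::cooks.distance(lmfit)),
    row.names = NULL
  )
}

#' Compact letter display from pairwise LSD comparisons
#'
#' Assigns letters to run (treatment) means so that two means share no
#' letter exactly when they differ significantly under a pooled-variance
#' least-significant-difference (LSD) test at level \code{alpha}: the pair
#' \eqn{(i, j)} differs when \eqn{|m_i - m_j| >
#' t_{1-\alpha/2, df} \sqrt{MSE (1/n_i + 1/n_j)}} with the pooled
#' within-run mean square \eqn{MSE = \sum (n_i - 1) s_i^2 / \sum (n_i - 1)}.
#'
#' @param means Per-run mean responses.
#' @param se Per-run replicate standard errors (of the mean).
#' @param n_rep Replicates per run (recycled; all >= 2).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of letter codes, one per run, in input order.
#'   With zero pooled variance, runs are grouped by exact mean equality.
#' @examples
#' group_letters(c(64, 64.5, 95), se = c(.5, .5, .5), n_rep = 3)
#' @export
group_letters <- function(means, se, n_rep = 3L, alpha = 0.05) {
  m <- length(means)
  n_rep <- rep_len(as.integer(n_rep), m)
  se <- rep_len(as.numeric(se), m)
  if (any(n_rep < 2L)) stop("need n_rep >= 2 for every run", call. = FALSE)
  if (any(se < 0)) stop("standard errors must be non-negative", call. = FALSE)
  sd2 <- (se * sqrt(n_rep))^2              # replicate variances
  df_err <- sum(n_rep - 1L)
  mse <- sum((n_rep - 1L) * sd2) / df_err
  if (mse <= 0) {
    # degenerate: no within-run spread; group by exact equality
    grp <- match(means, sort(unique(means)))
    return(letter_codes(max(grp))[grp])
  }
  tcrit <- stats::qt(1 - alpha / 2, df_err)
  diffmat <- outer(means, means, function(a, b) abs(a - b))
  lsd <- tcrit * sqrt(mse * outer(n_rep, n_rep, function(a, b) 1 / a + 1 / b))
  signif_pair <- diffmat > lsd
  cld_insert_absorb(signif_pair, order(means))
}

# insert-and-absorb construction of a compact letter display.
# signif: m x m logical, TRUE where the pair differs; ord: display order.
cld_insert_absorb <- function(signif, ord) {
  m <- nrow(signif)
  groups <- list(seq_len(m))           # start: one letter covering everything
  pairs <- which(signif & upper.tri(signif), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    newg <- list()
    for (g in groups) {
      if (i %in% g && j %in% g) {
        newg <- c(newg, list(setdiff(g, i)), list(setdiff(g, j)))
      } else {
        newg <- c(newg, list(g))
      }
    }
    # absorb groups contained in another
    keep <- rep(TRUE, length(newg))
    for (a in seq_along(newg)) for (b in seq_along(newg)) {
      if (a != b && keep[a] && keep[b] &&
          all(newg[[a]] %in% newg[[b]]) &&
          (length(newg[[a]]) < length(newg[[b]]) || a > b))
        keep[a] <- FALSE
    }
    groups <- unique(newg[keep])
  }
  # order letters by the smallest-ranked member so 'a' starts at the low end
  rank_of <- integer(m); rank_of[ord] <- seq_len(m)
  groups <- groups[order(vapply(groups, function(g) min(rank_of[g]), 0))]
  letters_out <- rep("", m)
  codes <- letter_codes(length(groups))
  for (gi in seq_along(groups))
    for (idx in groups[[gi]])
      letters_out[idx] <- paste0(letters_out[idx], codes[gi])
  letters_out
}

letter_codes <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, paste0)))[seq_len(n)]
}
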