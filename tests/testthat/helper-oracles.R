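# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force (explicit refits, dense grids, all-pairs tests)
# rather than calling the package's own closed-form paths.

# leave-one-out PRESS by explicit refits of the quadratic model
loo_press_oracle <- function(design) {
  xm <- rsmkin::coded_matrix(design)
  mm <- rsmkin:::quad_model_matrix(xm)
  y <- design$y_mean
  sum(vapply(seq_len(nrow(mm)), function(i) {
    fit <- stats::lm.fit(mm[-i, , drop = FALSE], y[-i])
    (y[i] - sum(mm[i, ] * fit$coefficients))^2
  }, 0))
}

# externally studentized residuals by explicit refit without each run
rstudent_oracle <- function(design) {
  xm <- rsmkin::coded_matrix(design)
  mm <- rsmkin:::quad_model_matrix(xm)
  y <- design$y_mean
  p <- ncol(mm)
  n <- nrow(mm)
  vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(mm[-i, , drop = FALSE], y[-i])
    pred <- sum(mm[i, ] * fit$coefficients)
    s2 <- sum(fit$residuals^2) / (n - 1 - p)
    # prediction variance at the held-out point
    XtX_inv <- chol2inv(chol(crossprod(mm[-i, , drop = FALSE])))
    v <- 1 + drop(t(mm[i, ]) %*% XtX_inv %*% mm[i, ])
    (y[i] - pred) / sqrt(s2 * v)
  }, 0)
}

# dense grid search for the surface maximum: coarse pass then 0.005-step
# refinement around the coarse optimum
grid_search_max <- function(fit, lim = 1.681793, coarse = 0.05,
                            fine = 0.005) {
  g <- seq(-lim, lim, by = coarse)
  pts <- as.matrix(expand.grid(g, g, g))
  yy <- predict(fit, pts)
  best <- pts[which.max(yy), ]
  gf <- lapply(best, function(b)
    seq(max(-lim, b - coarse), min(lim, b + coarse), by = fine))
  pts2 <- as.matrix(expand.grid(gf[[1]], gf[[2]], gf[[3]]))
  yy2 <- predict(fit, pts2)
  list(coded = unname(pts2[which.max(yy2), ]), value = max(yy2))
}

# all-pairs LSD significance matrix (the letters must encode exactly this)
lsd_signif_oracle <- function(means, se, n_rep, alpha = 0.05) {
  m <- length(means)
  n_rep <- rep_len(n_rep, m)
  sd2 <- (se * sqrt(n_rep))^2
  dfe <- sum(n_rep - 1)
  mse <- sum((n_rep - 1) * sd2) / dfe
  tcrit <- stats::qt(1 - alpha / 2, dfe)
  out <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j)
      out[i, j] <- abs(means[i] - means[j]) >
        tcrit * sqrt(mse * (1 / n_rep[i] + 1 / n_rep[j]))
  }
  out
}

shares_letter <- function(letters_vec, i, j) {
  a <- strsplit(letters_vec[i], "")[[1]]
  b <- strsplit(letters_vec[j], "")[[1]]
  length(intersect(a, b)) > 0
}

# stack the per-run replicate draws of a simulated design as 3n
# separate runs (replicate-level view of the same experiment)
expand_replicates <- function(sim) {
  r <- attr(sim, "replicates")
  stopifnot(!is.null(r))
  d <- sim[rep(seq_len(nrow(sim)), ncol(r)), ]
  d <- rsmkin:::new_ccd_design(d, attr(sim, "factors"), attr(sim, "alpha"))
  d$run <- seq_len(nrow(d))
  rsmkin::set_response(d, as.vector(r))
}

# a small noiseless quadratic truth used in several recovery tests
toy_truth <- c("(Intercept)" = 90, "x1" = 2, "x2:x3" = -1, "x3^2" = -4)
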