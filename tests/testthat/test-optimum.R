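test_that("stationary points solve the vanishing-gradient system and classify curvature", {
  des <- ccd_design(3, n_center = 10)

  # pure concave bowl: stationary point at the origin, a maximum
  bowl <- c("(Intercept)" = 90, "x1^2" = -2, "x2^2" = -3, "x3^2" = -1)
  fit <- fit_quadratic(simulate_response_surface(des, coef = bowl, sd = 0,
                                                 seed = 1))
  sp <- stationary_point(fit)
  expect_equal(unname(sp$coded), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(sp$classification, "maximum")
  expect_equal(sp$predicted, 90, tolerance = 1e-10)

  # mixed-sign curvature is a saddle
  sad <- c("(Intercept)" = 10, "x1^2" = 1, "x2^2" = -1, "x3^2" = 2)
  sps <- stationary_point(fit_quadratic(
    simulate_response_surface(des, coef = sad, sd = 0, seed = 1)))
  expect_equal(sps$classification, "saddle")

  # gradient-norm-zero invariant at random fitted stationary points
  for (s in 1:8) {
    sim <- simulate_response_surface(des, sd = 3, seed = s, clip = NULL)
    f <- fit_quadratic(sim)
    x <- stationary_point(f)$coded
    B <- rsmkin:::curvature_matrix(f)
    grad <- unname(f$linear) + 2 * drop(B %*% x)
    expect_lt(sqrt(sum(grad^2)), 1e-8)
  }
})

test_that("the bundled-table stationary point agrees with a dense grid search", {
  fit <- fit_quadratic(allethrin_ccd())
  sp <- stationary_point(fit)
  expect_equal(sp$classification, "maximum")
  expect_true(sp$inside_region)
  gs <- grid_search_max(fit)
  expect_equal(sp$predicted, gs$value, tolerance = 1e-4)
  expect_true(all(abs(unname(sp$coded) - gs$coded) <= 0.005 + 1e-9))
  # interior optimum close to the center, as the center-heavy data suggest
  expect_lt(max(abs(sp$coded)), 0.6)
})

test_that("constrained optimum respects its bounds and beats every design point", {
  des <- ccd_design(3, n_center = 10)
  fit <- fit_quadratic(allethrin_ccd())

  # interior stationary maximum: constrained search returns it unchanged
  opt <- constrained_optimum(fit, bounds = "cube")
  sp <- stationary_point(fit)
  expect_equal(unname(opt$coded), unname(sp$coded), tolerance = 1e-5)

  # shifted concave surface whose peak lies outside the unit cube
  shifted <- c("(Intercept)" = 80, "x1" = 8, "x1^2" = -2, "x2^2" = -2,
               "x3^2" = -2)                     # peak at x1 = 2
  fs <- fit_quadratic(simulate_response_surface(des, coef = shifted, sd = 0,
                                                seed = 1, clip = NULL))
  oc <- constrained_optimum(fs, bounds = "cube", radius = 1)
  expect_equal(unname(oc$coded), c(1, 0, 0), tolerance = 1e-6)
  os <- constrained_optimum(fs, bounds = "sphere", radius = 1)
  expect_equal(unname(os$coded), c(1, 0, 0), tolerance = 1e-6)

  # zero-radius sphere collapses to the center prediction (the intercept)
  o0 <- constrained_optimum(fit, bounds = "sphere", radius = 0)
  expect_equal(unname(o0$predicted), unname(coef(fit)[1]))

  # never below the best design-point prediction within bounds
  for (s in 1:5) {
    f <- fit_quadratic(simulate_response_surface(des, sd = 3, seed = s,
                                                 clip = NULL))
    for (b in c("cube", "sphere")) {
      o <- constrained_optimum(f, bounds = b, radius = 1)
      inside <- if (b == "cube") {
        apply(abs(coded_matrix(des)) <= 1 + 1e-9, 1, all)
      } else sqrt(rowSums(coded_matrix(des)^2)) <= 1 + 1e-9
      best_design <- max(predict(f, coded_matrix(des)[inside, , drop = FALSE]))
      expect_gte(o$predicted, best_design - 1e-8)
    }
  }

  # sphere search agrees with a dense boundary/interior grid on a saddle
  sad <- c("(Intercept)" = 0, "x1" = 1, "x2" = -2, "x1^2" = 3, "x2^2" = -1,
           "x3^2" = 2, "x1:x2" = 1.5)
  fsad <- fit_quadratic(simulate_response_surface(des, coef = sad, sd = 0,
                                                  seed = 1, clip = NULL))
  osad <- constrained_optimum(fsad, bounds = "sphere", radius = 1.5)
  g <- seq(-1.5, 1.5, by = 0.02)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- pts[sqrt(rowSums(pts^2)) <= 1.5, ]
  expect_gte(osad$predicted, max(predict(fsad, pts)) - 1e-3)
})

test_that("Box-Cox scans profile the likelihood correctly", {
  des <- allethrin_ccd()
  bc <- boxcox_scan(des)
  expect_equal(bc$best, 1.72, tolerance = 1e-9)
  expect_true(bc$ci[1] <= bc$best && bc$best <= bc$ci[2])
  expect_equal(bc$loglik[which.max(bc$loglik)], max(bc$loglik))

  # independent cross-check against MASS's profile on the same model
  df <- as.data.frame(cbind(coded_matrix(des), y = des$y_mean))
  lmfit <- stats::lm(y ~ pH + temperature + time + pH:temperature +
                       pH:time + temperature:time + I(pH^2) +
                       I(temperature^2) + I(time^2), data = df,
                     y = TRUE, qr = TRUE)
  mb <- MASS::boxcox(lmfit, lambda = seq(-3, 5, 0.01), plotit = FALSE)
  expect_equal(bc$best, mb$x[which.max(mb$y)], tolerance = 1e-9)

  # continuity across lambda = 0 (log-limit)
  ll <- boxcox_scan(des, lambda = c(-1e-6, 0, 1e-6))$loglik
  expect_lt(max(abs(ll - ll[2])), 1e-4)

  # degenerate flat data is inconclusive, not an answer
  flat <- set_response(ccd_design(3, n_center = 10), rep(50, 24))
  expect_true(boxcox_scan(flat)$inconclusive)

  expect_error(boxcox_scan(set_response(ccd_design(3, n_center = 10),
                                        c(-1, rep(50, 23)))),
               "positive")
})

test_that("Box-Cox intervals cover lambda = 1 for untransformed Gaussian data", {
  # coverage is assessed on the replicate-level fit (72 observations),
  # where the chi-square profile cutoff is close to nominal; the 24-run
  # means fit has too few error degrees of freedom for a 10-parameter
  # model and its profile interval is anti-conservative (see vignette)
  # true coverage here is ~0.91, close to the 0.90 bound, so a wide
  # replication (1000 seeds) is used to keep binomial noise small
  des <- ccd_design(3, n_center = 10)
  covered <- vapply(1:1000, function(s) {
    sim <- simulate_response_surface(des, sd = 0.6, seed = s)
    bc <- boxcox_scan(expand_replicates(sim), lambda = seq(-15, 15, by = 0.05))
    bc$ci[1] <= 1 && 1 <= bc$ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.90)
})

test_that("surface grids are faithful slices of the fitted polynomial", {
  des <- ccd_design(3, n_center = 10)
  fit <- fit_quadratic(allethrin_ccd())

  g <- surface_grid(fit, c("pH", "temperature"), fixed = 0.3,
                    resolution = 21)
  # spot-check grid entries against predict()
  i <- c(5, 100, 300)
  expect_equal(g$y_pred[i],
               predict(fit, as.matrix(g[i, fit$factor_names])),
               ignore_attr = TRUE)
  # center cell with everything at 0 equals the intercept
  g0 <- surface_grid(fit, c(1, 2), fixed = 0, resolution = 3)
  expect_equal(g0$y_pred[g0$pH == 0 & g0$temperature == 0],
               unname(coef(fit)[1]))

  # symmetric fit: grid invariant under coordinate negation
  bowl <- c("(Intercept)" = 5, "x1^2" = -1, "x2^2" = -2, "x3^2" = -1)
  fb <- fit_quadratic(simulate_response_surface(des, coef = bowl, sd = 0,
                                                seed = 1))
  gb <- surface_grid(fb, c(1, 2), resolution = 11)
  m <- matrix(gb$y_pred, 11, 11)
  expect_equal(m, m[11:1, 11:1])

  # fine-grid argmax consistent with the stationary point
  sp <- stationary_point(fit)
  gf <- surface_grid(fit, c("pH", "temperature"),
                     fixed = unname(sp$coded["time"]), resolution = 673)
  best <- gf[which.max(gf$y_pred), ]
  step <- diff(attr(gf, "g1"))[1]
  expect_lt(abs(best$pH - sp$coded[["pH"]]), step + 1e-9)
  expect_lt(abs(best$temperature - sp$coded[["temperature"]]), step + 1e-9)

  expect_error(surface_grid(fit, c(1, 1)), "distinct")
  expect_error(surface_grid(fit, c(1, 4)), "distinct|factors")
  expect_error(surface_grid(fit, c(1, 2), resolution = 1), "resolution")
})
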