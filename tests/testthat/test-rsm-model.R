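test_that("quadratic fit recovers constructed surfaces and degenerate cases", {
  des <- ccd_design(3, n_center = 10)

  # noiseless construct-and-recover: coefficients back to 1e-10
  sim <- simulate_response_surface(des, coef = toy_truth, sd = 0, seed = 1)
  fit <- fit_quadratic(sim)
  truth_full <- attr(sim, "truth")
  expect_equal(coef(fit), truth_full, tolerance = 1e-10)

  # constant response: intercept c, everything else zero
  flat <- set_response(des, rep(77.7, 24))
  cflat <- coef(fit_quadratic(flat))
  expect_equal(unname(cflat[1]), 77.7)
  expect_equal(unname(cflat[-1]), rep(0, 9), tolerance = 1e-10)

  # parameter count p = 1 + k + k(k-1)/2 + k
  expect_equal(fit$p, 10)
  expect_equal(fit$sst, fit$ssr + fit$sse, tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly, naming collinear columns", {
  des <- ccd_design(3, n_center = 10)
  # collapse the third factor onto the second
  des$x_x3 <- des$x_x2
  des <- set_response(des, rnorm(24, 80))
  expect_error(fit_quadratic(des), "singular design.*x")
  expect_error(fit_quadratic(ccd_design(3, n_center = 10)), "responses")
})

test_that("run order and replicate expansion leave coefficients unchanged", {
  des <- allethrin_ccd()
  fit <- fit_quadratic(des)

  # randomize_runs carries the responses along with the rows
  fit_perm <- fit_quadratic(randomize_runs(des, seed = 7))
  expect_equal(coef(fit_perm), coef(fit), tolerance = 1e-9)

  # balanced replicate expansion reproduces the means-fit coefficients
  fit_rep <- fit_quadratic(des, basis = "replicates")
  expect_equal(coef(fit_rep), coef(fit), tolerance = 1e-9)
  expect_equal(fit_rep$n, 72)
})

test_that("ANOVA adequacy statistics match their definitions and the LOO oracle", {
  des <- allethrin_ccd()
  fit <- fit_quadratic(des)
  an <- rsm_anova(fit)

  # PRESS equals 24 explicit leave-one-out refits
  expect_equal(an$press, loo_press_oracle(des), tolerance = 1e-8)
  expect_equal(an$pred_r_squared, 1 - loo_press_oracle(des) / fit$sst,
               tolerance = 1e-10)

  # predicted R2 <= R2 and PRESS >= SSE on arbitrary datasets
  for (s in 1:5) {
    sim <- simulate_response_surface(des, sd = 2, seed = s)
    a2 <- rsm_anova(fit_quadratic(sim))
    expect_lte(a2$pred_r_squared, a2$r_squared)
    expect_gte(a2$press, a2$sse)
    expect_lte(a2$adj_r_squared, a2$r_squared)
  }

  # perfect noiseless fit is flagged rather than dividing by zero
  exact <- simulate_response_surface(ccd_design(3, n_center = 10),
                                     coef = toy_truth, sd = 0, seed = 1)
  ap <- rsm_anova(fit_quadratic(exact))
  expect_true(ap$perfect_fit)
  expect_identical(ap$F, Inf)
  expect_equal(ap$r_squared, 1)
})

test_that("prediction evaluates the ten-term polynomial with sensible errors", {
  # the quoted equation (with the data-derived -2.00 pH:time sign),
  # hand-evaluated at (+1, +1, -1), gives 76.26
  quoted <- c("(Intercept)" = 94.23, "x1" = -0.1231, "x2" = -0.2929,
              "x3" = 4.04, "x1:x2" = -1.25, "x1:x3" = -2.00,
              "x2:x3" = -4.50, "x1^2" = -6.74, "x2^2" = -6.91,
              "x3^2" = -5.11)
  sim <- simulate_response_surface(ccd_design(3, n_center = 10),
                                   coef = quoted, sd = 0, seed = 1)
  fit <- fit_quadratic(sim)
  expect_equal(unname(predict(fit, c(1, 1, -1))), 76.26, tolerance = 5e-3)
  expect_equal(unname(predict(fit, c(0, 0, 0))), 94.23, tolerance = 1e-8)

  # zero coefficients predict zero everywhere
  zfit <- fit_quadratic(set_response(ccd_design(3, n_center = 10), rep(0, 24)))
  expect_equal(unname(predict(zfit, c(1.2, -0.4, 0.9))), 0, tolerance = 1e-12)

  expect_error(predict(fit, c(1, 2)), "length k")
  sef <- predict(fit, c(0, 0, 0), se.fit = TRUE)
  expect_true(sef$se.fit >= 0)
})

test_that("case diagnostics agree with explicit leave-one-out refits", {
  des <- allethrin_ccd()
  fit <- fit_quadratic(des)
  d <- rsm_diagnostics(fit)

  expect_equal(sum(d$leverage), 10, tolerance = 1e-10)  # trace = p
  expect_true(all(d$leverage >= 0 & d$leverage <= 1))
  expect_true(all(d$cooks_d >= 0))

  # externally studentized residuals from explicit refits without each run
  expect_equal(d$student_external, rstudent_oracle(des), tolerance = 1e-8)

  # identical center rows share identical leverage
  ctr <- d$leverage[des$class == "center"]
  expect_equal(max(ctr) - min(ctr), 0, tolerance = 1e-12)

  # Cook's distance matches its closed form e^2 h / (p MSE (1-h)^2)
  mse <- fit$sse / fit$df_resid
  expect_equal(d$cooks_d,
               d$residual^2 * d$leverage /
                 (10 * mse * (1 - d$leverage)^2),
               tolerance = 1e-10)
})

test_that("compact letter display encodes exactly the pairwise LSD verdicts", {
  # all means identical: a single letter
  expect_equal(unique(group_letters(rep(80, 6), se = rep(0.5, 6))), "a")

  # two groups 20 pooled SDs apart: exactly two letters
  m <- c(50, 50.2, 49.9, 70, 70.1, 69.8)
  lt <- group_letters(m, se = rep(1 / sqrt(3), 6), n_rep = 3)
  expect_equal(length(unique(lt)), 2)
  expect_false(shares_letter(lt, 1, 4))
  expect_true(shares_letter(lt, 1, 2))

  # random configurations: sharing a letter <=> not significantly different
  set.seed(5)
  for (rep in 1:10) {
    mm <- rnorm(8, 80, 4)
    se <- runif(8, 0.2, 1.2)
    lt <- group_letters(mm, se = se, n_rep = 3)
    sig <- lsd_signif_oracle(mm, se, 3)
    for (i in 1:7) for (j in (i + 1):8)
      expect_equal(!shares_letter(lt, i, j), sig[i, j],
                   info = sprintf("rep %d pair %d-%d", rep, i, j))
  }

  # bundled table: the extreme runs 6 (64.0) and 10 (95.6) never share
  des <- allethrin_ccd()
  lt <- group_letters(des$y_mean, des$y_se, des$n_rep)
  expect_false(shares_letter(lt, 6, 10))

  # degenerate zero-variance case resolved by exact equality
  lt0 <- group_letters(c(1, 1, 2), se = c(0, 0, 0), n_rep = 3)
  expect_true(shares_letter(lt0, 1, 2))
  expect_false(shares_letter(lt0, 1, 3))

  expect_error(group_letters(c(1, 2), se = c(0.1, 0.1), n_rep = 1), "n_rep")
})
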