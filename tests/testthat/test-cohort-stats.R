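test_that("OLS matches the explicit normal-equations oracle", {
  set.seed(11)
  n <- 10
  fr <- data.frame(
    participant_id = sprintf("P%02d", 1:n),
    lnTEE = rnorm(n, 7.7, 0.2),
    lnFFM = rnorm(n, 3.7, 0.1),
    lnFM = rnorm(n, 2.0, 0.4),
    age = runif(n, 20, 55),
    sex = factor(sample(c("F", "M"), n, TRUE), c("F", "M"))
  )
  fit <- fit_cohort_model(model_spec("lnTEE", c("lnFFM", "lnFM", "sex")), fr)
  X <- cbind(1, fr$lnFFM, fr$lnFM, as.numeric(fr$sex == "M"))
  beta <- solve(t(X) %*% X, t(X) %*% fr$lnTEE)
  expect_equal(fit$coefficients$estimate, drop(beta), tolerance = 1e-10)
  # adjusted R2 definition
  r2 <- fit$r_squared
  expect_equal(fit$adj_r_squared, 1 - (1 - r2) * (n - 1) / (n - 3 - 1),
               tolerance = 1e-12)
  # residuals of an intercept model sum to ~0 and are keyed by participant
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  expect_named(fit$residuals, fr$participant_id)
})

test_that("exact linear data is recovered to machine precision", {
  set.seed(2)
  n <- 20
  fr <- data.frame(
    participant_id = as.character(1:n),
    lnFFM = rnorm(n, 3.7, 0.15),
    lnFM = rnorm(n, 2, 0.3),
    age = runif(n, 20, 50),
    sex = factor(sample(c("F", "M"), n, TRUE), c("F", "M"))
  )
  fr$lnTEE <- 3.35 + 1.33 * fr$lnFFM - 0.16 * fr$lnFM - 0.22 * (fr$sex == "M")
  fit <- suppressWarnings(  # lm warns about the zero-residual fit
    fit_cohort_model(model_spec("lnTEE", c("lnFFM", "lnFM", "sex")), fr))
  expect_equal(fit$coefficients$estimate, c(3.35, 1.33, -0.16, -0.22),
               tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
})

test_that("model validation: collinearity, log-positivity, minimum n", {
  derived <- fixture_derived()
  fr <- cohort_model_frame(derived)
  # a predictor that is an exact linear combination is named in the error
  fr_coll <- fr
  fr_coll$FFM <- 2 * fr_coll$lnFFM + 1
  expect_error(
    fit_cohort_model(model_spec("lnTEE", c("lnFFM", "FFM")), fr_coll),
    "collinear")
  bad <- derived; bad$fm_kg[3] <- -1
  expect_error(cohort_model_frame(bad), bad$participant_id[3])
  expect_error(
    fit_cohort_model(model_spec("lnTEE", c("lnFFM", "lnFM", "sex")), fr[1:4, ]),
    "complete rows")
})

test_that("adding predictors never lowers unadjusted R2 on the fixture", {
  fr <- cohort_model_frame(fixture_derived())
  nested <- list(c("lnFFM"),
                 c("lnFFM", "lnFM"),
                 c("lnFFM", "lnFM", "sex"),
                 c("lnFFM", "lnFM", "sex", "age"),
                 c("lnFFM", "lnFM", "sex", "age", "community"))
  r2 <- vapply(nested, function(p)
    fit_cohort_model(model_spec("lnTEE", p), fr)$r_squared, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("residual ANOVA: t^2 = F identity and zero-F by construction", {
  set.seed(3)
  fr <- data.frame(
    participant_id = as.character(1:24),
    lnTEE = rnorm(24, 7.7, 0.2),
    lnFFM = rnorm(24, 3.7, 0.1),
    grp = rep(c("a", "b"), each = 12)
  )
  fit <- fit_cohort_model(model_spec("lnTEE", "lnFFM"), fr)
  a <- residual_anova(fit, setNames(fr$grp, fr$participant_id))
  tt <- t.test(fit$residuals[fr$grp == "a"], fit$residuals[fr$grp == "b"],
               var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$df_between, 1)

  # grouping already in the model => residual F ~ 0
  frc <- cohort_model_frame(fixture_derived())
  fitc <- fit_cohort_model(model_spec("lnTEE", c("lnFFM", "community")), frc)
  ac <- residual_anova(fitc, setNames(frc$community, frc$participant_id))
  expect_lt(ac$F, 1e-10)

  # identical group means by construction => F = 0
  res_fit <- fit
  vals <- c(-2, -1, 1, 2)
  res_fit$residuals <- setNames(rep(vals, 2), as.character(1:8))
  a0 <- residual_anova(res_fit, setNames(rep(c("a", "b"), each = 4),
                                         as.character(1:8)))
  expect_equal(a0$F, 0, tolerance = 1e-12)

  expect_error(residual_anova(fit, setNames(c("a", rep("b", 23)),
                                            fr$participant_id)),
               "fewer than 2")
})

test_that("Kruskal-Wallis matches the explicit rank-sum formula", {
  set.seed(5)
  vals <- c(rnorm(7, 0), rnorm(6, 0.5), rnorm(8, 1))
  grp <- rep(c("x", "y", "z"), c(7, 6, 8))
  kw <- kruskal_wallis(vals, grp)
  # brute-force H without ties: 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1)
  r <- rank(vals)
  N <- length(vals)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, sum)^2 / tapply(r, grp, length)) - 3 * (N + 1)
  expect_equal(kw$H, H, tolerance = 1e-10)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(H, 2, lower.tail = FALSE), tolerance = 1e-10)

  expect_warning(kw0 <- kruskal_wallis(rep(3, 9), rep(c("a", "b", "c"), 3)),
                 "identical")
  expect_equal(kw0$H, 0)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 non-empty groups")
})

test_that("steps-by-community-and-sex Kruskal-Wallis runs on the fixture", {
  coh <- daasanach_cohort()
  sub <- coh[!is.na(coh$steps_day), ]
  kw <- kruskal_wallis(sub$steps_day, interaction(sub$community, sub$sex))
  expect_equal(kw$df, 3)  # 4 community x sex cells carry accelerometry
  expect_true(kw$H > 0 && kw$p <= 1)
})

test_that("prediction intervals: coverage, collapse, and row skipping", {
  set.seed(9)
  n <- 1000
  world <- data.frame(lnFFM = rnorm(n, 3.8, 0.2), lnFM = rnorm(n, 2.3, 0.5),
                      age = runif(n, 20, 60),
                      sexM = rbinom(n, 1, 0.5))
  world$lnTEE <- 4.7 + 0.84 * world$lnFFM - 0.02 * world$lnFM -
    0.002 * world$age + 0.01 * world$sexM + rnorm(n, 0, 0.15)
  ref <- as_reference_model(
    lm(lnTEE ~ lnFFM + lnFM + age + sexM, world), log_scale = TRUE)

  new <- data.frame(lnFFM = rnorm(n, 3.8, 0.2), lnFM = rnorm(n, 2.3, 0.5),
                    age = runif(n, 20, 60), sexM = rbinom(n, 1, 0.5))
  obs <- exp(4.7 + 0.84 * new$lnFFM - 0.02 * new$lnFM - 0.002 * new$age +
               0.01 * new$sexM + rnorm(n, 0, 0.15))
  scr <- predict_with_interval(ref, new, obs)
  cover <- mean(scr$status == "inside")
  expect_gt(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / n))
  expect_lt(cover, 0.95 + 3 * sqrt(0.95 * 0.05 / n))

  # zero residual variance collapses the interval to the point estimate
  ref0 <- reference_model(c("(Intercept)" = 1, x = 2), sigma = 0, n = 50)
  scr0 <- predict_with_interval(ref0, data.frame(x = c(1, 1)),
                                observed = c(3, 3.2))
  expect_equal(scr0$pi_lo, scr0$predicted)
  expect_equal(scr0$status, c("inside", "above"))

  # missing covariate rows are skipped with a warning
  new2 <- data.frame(x = c(1, NA, 2))
  expect_warning(scr2 <- predict_with_interval(ref0, new2, c(3, 5, 5)),
                 "skipped")
  expect_equal(nrow(scr2), 2)
  expect_error(predict_with_interval(ref0, data.frame(z = 1), 3), "missing covariate")
})

test_that("group summaries: printed-column means and singleton SD", {
  coh <- daasanach_cohort()
  s <- group_summaries(coh, "tee_kcal_day", "sex")
  expect_equal(round(s$mean[s$sex == "F"]), 2325)
  w <- group_summaries(coh, "wt_l_day", "sex")
  expect_equal(w$mean[w$sex == "F"], 7.26, tolerance = 0.01 / 7.26)
  g1 <- group_summaries(data.frame(v = 5, g = "only"), "v", "g")
  expect_equal(g1$mean, 5)
  expect_true(is.na(g1$sd))
  st <- group_summaries(coh, "steps_day", c("community", "sex"))
  expect_equal(round(st$mean[st$community == "Roto" & st$sex == "M"]), 8222)
  expect_equal(round(st$mean[st$community == "Illeret" & st$sex == "F"]), 5608)
})
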