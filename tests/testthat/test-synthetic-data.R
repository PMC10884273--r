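test_that("default configuration matches the cohort's study conditions", {
  cfg <- default_generating_config()
  expect_equal(cfg$male_prop, 0.622)
  expect_equal(cfg$age_mean, 27.1)
  expect_equal(unname(cfg$cluster_size_probs[["11"]]), 0.75)
  expect_equal(sum(cfg$cluster_size_probs), 1)
  expect_equal(cfg$n_persons, 164L)
  expect_equal(length(cfg$schedule), 11)
  # the truncated age distribution is centred so its mean is the target
  expect_equal(rdsem:::.tnorm_mean(cfg$age_mu, cfg$age_sd, cfg$age_min),
               27.1, tolerance = 1e-6)
  expect_lt(rdsem:::.spec_radius(cfg$phi), 1)
})

test_that("calibration reproduces the standardized targets", {
  cfg <- default_generating_config()
  imp <- implied_stdyx(cfg)
  tg <- stdyx_targets()
  expect_lt(max(abs(imp$phi - tg$phi)), 0.005)
  expect_lt(max(abs(imp$resid_w - tg$resid_w)), 0.005)
  expect_lt(max(abs(imp$trend_w - tg$trend_w)), 0.005)
  expect_lt(max(abs(imp$cor_u - tg$cor_u)), 0.005)
  expect_lt(max(abs(imp$cor_b - tg$cor_b)), 0.005)
  expect_lt(max(abs(imp$intercept_b - tg$intercept_b)), 0.005)
  expect_lt(max(abs(imp$gamma_alpha - tg$gamma_alpha)), 0.005)
  # the identity-consistent R-squared values
  expect_equal(unname(imp$r2_w), c(0.234, 0.262, 0.298), tolerance = 1e-6)
})

test_that("degenerate and infeasible targets are handled", {
  tg <- stdyx_targets()
  # all lag/trend targets zero with unit residual variances: white noise
  tg0 <- tg
  tg0$phi[] <- 0
  tg0$resid_w[] <- 1
  tg0$cor_u[] <- diag(3)
  tg0$trend_w[] <- 0
  cfg0 <- calibrate_to_stdyx(tg0)
  expect_equal(unname(cfg0$phi), matrix(0, 3, 3))
  expect_equal(unname(cfg0$sigma_u), diag(unname(cfg0$within_scale)),
               tolerance = 1e-8)
  expect_lt(max(cfg0$s2_trend), 1e-9)

  # an autoregressive target of 1.2 violates stationarity
  tg_bad <- tg
  tg_bad$phi["SWLS", "SWLS"] <- 1.2
  expect_error(calibrate_to_stdyx(tg_bad), "calibration failure")
})

test_that("panel generation is reproducible and respects the design", {
  cfg <- default_generating_config()
  p1 <- generate_panel(cfg, seed = 7)
  p2 <- generate_panel(cfg, seed = 7)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$persons, p2$persons)
  expect_equal(nrow(p1$records), 164 * 11)
  expect_true(p1$rescaled)
  expect_silent(validate_panel(p1))

  # white-noise configuration: no between variance, near-zero ICC
  cfg0 <- cfg
  cfg0$phi[] <- 0
  cfg0$sigma_u <- diag(diag(cfg0$sigma_u))
  cfg0$sigma_eps <- cfg0$sigma_u
  cfg0$sigma_b <- diag(1e-10, 3)
  cfg0$s2_trend[] <- 1e-12
  cfg0$trend_sd_total[] <- 1e-6
  cfg0$gamma_alpha[] <- 0
  cfg0$gamma_trend[] <- 0
  cfg0$trend_means[] <- 0
  cfg0$n_persons <- 500L
  p0w <- generate_panel(cfg0, seed = 1)
  expect_lt(icc1(p0w, "DUDIT"), 0.02)
  expect_lt(icc1(p0w, "SWLS"), 0.02)
})

test_that("simulated residual moments match the stationary oracle", {
  # analytic checks of the Lyapunov solution
  su <- diag(3)
  expect_equal(stationary_moments(list(phi = matrix(0, 3, 3), sigma_u = su)),
               su, ignore_attr = TRUE)
  expect_equal(diag(stationary_moments(list(phi = diag(0.5, 3),
                                            sigma_u = su))),
               rep(4 / 3, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(stationary_moments(list(phi = diag(1.01, 3), sigma_u = su)),
               "not stationary")

  # long-run simulated covariance of the residual process
  cfg <- default_generating_config()
  se <- stationary_moments(cfg)
  set.seed(55)
  Tn <- 4e4
  L <- chol(cfg$sigma_u)
  e <- matrix(0, Tn, 3)
  e[1, ] <- rnorm(3) %*% chol(cfg$sigma_eps)
  for (t in 2:Tn)
    e[t, ] <- e[t - 1, ] %*% t(cfg$phi) + rnorm(3) %*% L
  expect_lt(max(abs(cov(e) - se)), 0.02)

  # generated panels: detrend with the true latent effects and compare the
  # cross-sectional residual covariance and lag-1 autocovariance
  cfgN <- default_generating_config(n_persons = 2000)
  p <- generate_panel(cfgN, seed = 56)
  lat <- attr(p, "latents")
  r <- p$records
  t_years <- r$month / 12
  idx <- match(r$person_id, lat$person_id)
  eps <- sapply(1:3, function(v)
    r[[unname(rdsem:::.OUTCOME_COLS)[v]]] -
      lat$alpha[cbind(idx, v)] - lat$beta[cbind(idx, v)] * t_years)
  e0 <- eps[r$month == 0, ]
  expect_lt(max(abs(cov(e0) - se)), 0.02)
  lag1 <- cov(eps[r$month == 3, ], eps[r$month == 0, ])
  expect_lt(max(abs(lag1 - cfgN$phi %*% se)), 0.02)
})

test_that("missingness imposition reproduces attrition and item rates", {
  cfg <- default_generating_config()
  # null configuration leaves the panel untouched
  cfg_null <- cfg
  cfg_null$miss_rates[] <- 0
  cfg_null$cluster_size_probs <- c(`11` = 1)
  p <- generate_panel(default_generating_config(n_persons = 50), seed = 10)
  p_null <- impose_missingness(p, modifyList(cfg_null,
                                             list(n_persons = 50L)), seed = 11)
  expect_identical(p_null$records, p$records)

  # cluster-size distribution at scale
  cfgB <- default_generating_config(n_persons = 4000)
  pm <- impose_missingness(generate_panel(cfgB, seed = 12), cfgB, seed = 13)
  ms <- missingness_patterns(pm)
  expect_equal(unname(ms$cluster_size_table[["11"]]) / 100, 0.75,
               tolerance = 0.025)
  # item rates at attended occasions, against the configuration
  att <- !is.na(pm$records$drug_free_friends)
  expect_equal(mean(is.na(pm$records$dudit_c[att])),
               unname(cfg$miss_rates["dudit"]), tolerance = 0.02)
  expect_equal(mean(is.na(pm$records$scl90r_gsi[att])),
               unname(cfg$miss_rates["scl90r"]), tolerance = 0.02)

  # dependence multiplier 1: no distributional dependence
  cfg1 <- cfgB
  cfg1$missing_dependence <- 1
  pm1 <- impose_missingness(generate_panel(cfgB, seed = 14), cfg1, seed = 15)
  dep <- distribution_by_missingness(pm1, "DUDIT", "SWLS")
  expect_lt(abs(dep$cliffs_delta), 0.06)

  cfg_bad <- cfg
  cfg_bad$miss_rates["dudit"] <- 1.4
  expect_error(impose_missingness(p, cfg_bad), "\\[0, 1\\]")
})
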