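test_that("model specification builds the cohort lag structure", {
  spec <- build_model_spec()
  expect_equal(sum(spec$lag_mask), 5)  # 3 into DUDIT, own lags for the rest
  expect_true(all(spec$lag_mask["DUDIT", ]))
  expect_false(spec$lag_mask["SWLS", "DUDIT"])
  expect_equal(sum(build_model_spec("full")$lag_mask), 9)
  custom <- build_model_spec(lag = list(DUDIT = c("DUDIT", "SWLS"),
                                        SWLS = "SWLS", SCL90R = "SCL90R"))
  expect_equal(sum(custom$lag_mask), 4)
  expect_error(build_model_spec(lag = list(DUDIT = "NOPE")),
               "unknown outcome")
  expect_error(build_model_spec(between_predictors = "height"),
               "unknown between-level predictor")
})

test_that("prior regimes are ordered and the admissible regime truncates", {
  ref <- default_priors("reference")
  adm <- default_priors("admissible_range")
  expect_gte(ref$phi_sd, 10 * adm$phi_sd)
  expect_equal(phi_prior_density(adm, 1.5), 0)
  expect_equal(phi_prior_density(adm, -1.01), 0)
  expect_gt(phi_prior_density(adm, 0.3), 0)
  # both regimes put unit mass on the lagged-coefficient axis (propriety)
  for (pr in list(ref, adm)) {
    Z <- stats::integrate(function(x) phi_prior_density(pr, x),
                          -Inf, Inf)$value
    expect_equal(Z, 1, tolerance = 1e-5)
  }
})

test_that("complete-data log density matches hand and brute-force values", {
  spec <- build_model_spec()
  o <- c("DUDIT", "SWLS", "SCL90R")

  # single person, two occasions on a 3-month lattice
  set.seed(71)
  params <- list(
    phi = matrix(c(0.3, 0.1, 0.05, 0, 0.25, 0, 0, 0, 0.2), 3, 3,
                 byrow = TRUE),
    sigma_u = diag(c(0.2, 0.3, 0.25)) + 0.05,
    sigma_b = diag(c(0.1, 0.15, 0.12)) + 0.02,
    s2_trend = c(0.02, 0.03, 0.025))
  # delta is q x 6 (3 predictors x [3 intercepts, 3 trend slopes])
  params$delta <- matrix(0, 3, 6)
  params$delta[1, ] <- c(0.5, 1.2, 0.8, -0.05, 0.1, -0.02)
  params$delta[2, ] <- c(0.1, -0.1, 0.05, 0.01, 0, 0.02)
  params$delta[3, ] <- c(0, 0.02, -0.03, 0, 0.01, 0)

  make_panel <- function(n, months, y) {
    recs <- data.frame(person_id = rep(sprintf("P%d", 1:n), each = length(months)),
                       month = rep(months, n),
                       dudit_c = y[, 1], swls = y[, 2], scl90r_gsi = y[, 3],
                       drug_free_friends = NA)
    pers <- data.frame(person_id = sprintf("P%d", 1:n),
                       age = seq(20, by = 4, length.out = n),
                       gender = rep_len(c(1, 0), n))
    expand_time_lattice(panel_dataset(recs, pers, rescaled = TRUE))
  }

  # brute force via the joint multivariate normal over stacked occasions:
  # Cov(eps_t, eps_s) = Phi^(t-s) Sigma_eps for t >= s
  joint_loglik <- function(params, panel, eta) {
    se <- stationary_moments(params)
    tyears <- panel$lattice / 12
    Tn <- length(tyears)
    X <- cbind(1, panel$persons$gender,
               (panel$persons$age - mean(panel$persons$age)) /
                 sd(panel$persons$age))
    Om <- matrix(0, 3 * Tn, 3 * Tn)
    pw <- list(diag(3))
    for (k in 1:(Tn - 1)) pw[[k + 1]] <- params$phi %*% pw[[k]]
    for (t in 1:Tn) for (s in 1:Tn) {
      blk <- if (t >= s) pw[[t - s + 1]] %*% se else se %*% t(pw[[s - t + 1]])
      Om[(3 * t - 2):(3 * t), (3 * s - 2):(3 * s)] <- blk
    }
    Sb6 <- matrix(0, 6, 6)
    Sb6[1:3, 1:3] <- params$sigma_b
    diag(Sb6)[4:6] <- params$s2_trend
    total <- 0
    ycols <- c("dudit_c", "swls", "scl90r_gsi")
    for (i in seq_len(nrow(panel$persons))) {
      ri <- panel$records[panel$records$person_id ==
                            panel$persons$person_id[i], ]
      ri <- ri[order(ri$month), ]
      Y <- t(as.matrix(ri[, ycols]))
      a <- eta[i, 1:3]; b <- eta[i, 4:6]
      epsv <- as.vector(Y - a - outer(b, tyears))
      total <- total + ref_dmvnorm_log(epsv, rep(0, 3 * Tn), Om) +
        ref_dmvnorm_log(eta[i, ], drop(t(params$delta) %*% X[i, ]), Sb6)
    }
    total
  }

  # 2 persons x 4 occasions
  set.seed(72)
  months <- c(0, 3, 6, 9)
  y <- matrix(rnorm(2 * 4 * 3, mean = 1), 8, 3)
  panel <- make_panel(2, months, y)
  eta <- cbind(matrix(rnorm(6, 1, 0.3), 2, 3), matrix(rnorm(6, 0, 0.1), 2, 3))
  ld <- complete_data_log_density(params, spec, panel, eta)
  ld_ref <- joint_loglik(params, panel, eta)
  expect_equal(ld, ld_ref, tolerance = 1e-8)

  # single person, single transition: density falls as an observation moves
  # away from its conditional mean
  y1 <- matrix(rnorm(2 * 3, 1), 2, 3)
  pan1 <- make_panel(2, c(0, 3), y1)
  eta1 <- cbind(matrix(1, 2, 3), matrix(0, 2, 3))
  base <- complete_data_log_density(params, spec, pan1, eta1)
  pan_far <- pan1
  pan_far$records$swls[2] <- pan_far$records$swls[2] + 5
  expect_lt(complete_data_log_density(params, spec, pan_far, eta1), base)

  # invalid inputs
  bad <- params; bad$phi <- diag(1.2, 3)
  expect_error(complete_data_log_density(bad, spec, pan1, eta1),
               "not stationary")
  bad2 <- params; bad2$sigma_u <- matrix(1, 3, 3)
  expect_error(complete_data_log_density(bad2, spec, pan1, eta1),
               "positive definite")
})
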