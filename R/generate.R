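#' Simulate a complete synthetic cohort
#'
#' Draws a complete (pre-missingness) panel from the two-level residual DSEM
#' data-generating process of an [rdsem_config][calibrate_to_stdyx]: per
#' person, baseline age (truncated normal, minimum 16, location solved so the
#' truncated mean matches the configured mean) and gender; latent intercepts
#' and linear trend slopes from the between-level model; within-person
#' residuals from the stationary lag-1 vector autoregression simulated on the
#' 3-month lattice spanning the schedule, emitted at scheduled months only.
#' Outcomes are on the rescaled analysis metric. A binary, almost
#' person-constant `drug_free_friends` covariate is attached for the
#' screening tools; it plays no role in the outcome model.
#'
#' @param config an `rdsem_config`.
#' @param seed integer seed (overrides `config$seed`); `NULL` leaves the RNG
#'   state alone.
#' @return a complete `rdsem_panel` (`rescaled = TRUE`).
#' @export
generate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "rdsem_config"))
  if (!is.null(seed)) set.seed(seed)
  if (.spec_radius(config$phi) >= 1)
    stop("refusing to simulate: phi is not stationary", call. = FALSE)
  N <- config$n_persons
  sched <- config$schedule
  lattice <- seq(min(sched), max(sched), by = config$step)
  tyears <- lattice / 12
  Tn <- length(lattice)
  keep <- match(sched, lattice)

  # demographics
  gender <- rbinom(N, 1, config$male_prop)
  age <- config$age_mu + config$age_sd * rnorm(N)
  while (any(bad <- age < config$age_min))   # rejection sampling at the bound
    age[bad] <- config$age_mu + config$age_sd * rnorm(sum(bad))
  z <- (age - config$age_mean) / config$age_sd
  Xc <- cbind(gender - config$male_prop, z)  # centred predictors

  # between level: intercepts (correlated) and trend slopes (independent)
  Lb <- chol(config$sigma_b)
  alpha <- matrix(rnorm(3 * N), N, 3) %*% Lb +
    rep(config$grand_intercepts, each = N) + Xc %*% t(config$gamma_alpha)
  beta <- matrix(rnorm(3 * N), N, 3) %*% diag(sqrt(config$s2_trend)) +
    rep(config$trend_means, each = N) + Xc %*% t(config$gamma_trend)

  # within level: VAR(1) on the full lattice, stationary (or diffuse) start
  Lu <- chol(config$sigma_u)
  S0 <- if (isTRUE(config$stationary_start)) config$sigma_eps else config$sigma_u
  eps <- array(0, c(N, 3, Tn))
  eps[, , 1] <- matrix(rnorm(3 * N), N, 3) %*% chol(S0)
  for (t in 2:Tn)
    eps[, , t] <- eps[, , t - 1] %*% t(config$phi) +
      matrix(rnorm(3 * N), N, 3) %*% Lu

  # drug-free friends: nearly constant within person
  dff0 <- rbinom(N, 1, 0.65)

  ids <- sprintf("P%04d", seq_len(N))
  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    t <- keep[j]
    y <- alpha + beta * tyears[t] + eps[, , t]
    flip <- rbinom(N, 1, 0.02)
    recs[[j]] <- data.frame(
      person_id = ids, month = sched[j],
      dudit_c = y[, 1], swls = y[, 2], scl90r_gsi = y[, 3],
      drug_free_friends = ifelse(flip == 1, 1 - dff0, dff0))
  }
  records <- do.call(rbind, recs)
  if (isTRUE(config$clip)) {
    records$dudit_c <- pmin(pmax(records$dudit_c, 0), 8 / 5)
    records$swls <- pmin(pmax(records$swls, 5 / 10), 35 / 10)
    records$scl90r_gsi <- pmin(pmax(records$scl90r_gsi, 0), 4)
  }
  persons <- data.frame(person_id = ids, age = age, gender = gender)
  out <- panel_dataset(records, persons, schedule = sched, rescaled = TRUE)
  # true latent effects, for oracle checks of the generating process
  attr(out, "latents") <- list(alpha = alpha, beta = beta,
                               person_id = ids)
  out
}

#' Impose attrition and item missingness on a complete panel
#'
#' Two-stage missingness mechanism emulating the cohort: (a) each person's
#' number of attended occasions is drawn from the configured cluster-size
#' distribution, with the dropped occasions chosen uniformly and all
#' outcomes set missing there; (b) within attended occasions, each outcome
#' is set missing at its configured rate, with the odds of a missing
#' life-satisfaction score multiplied by `missing_dependence` at occasions
#' where the *observed* drug-use score exceeds its occasion-specific
#' model-implied mean — so the observed drug-use distribution depends on
#' life-satisfaction missingness while the mechanism remains
#' missing-at-random (it conditions only on observed values).
#'
#' @param data a complete `rdsem_panel` from [generate_panel()].
#' @param config the `rdsem_config` holding the missingness settings.
#' @param seed optional integer seed.
#' @return the `rdsem_panel` with missing cells.
#' @export
impose_missingness <- function(data, config, seed = NULL) {
  stopifnot(inherits(data, "rdsem_panel"), inherits(config, "rdsem_config"))
  if (!is.null(seed)) set.seed(seed)
  rates <- config$miss_rates
  if (any(rates < 0 | rates > 1))
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  mult <- config$missing_dependence
  if (mult <= 0) stop("missing_dependence must be positive", call. = FALSE)
  sched <- data$schedule
  n_occ <- length(sched)
  sizes <- as.integer(names(config$cluster_size_probs))
  r <- data$records
  ids <- data$persons$person_id
  r <- r[order(r$person_id, r$month), , drop = FALSE]

  # (a) attrition: drop whole occasions down to the drawn cluster size
  cl <- if (length(sizes) == 1) rep(sizes, length(ids)) else
    sample(sizes, length(ids), replace = TRUE,
           prob = config$cluster_size_probs)
  drop_keys <- character(0)
  for (i in seq_along(ids)) {
    nd <- n_occ - cl[i]
    if (nd > 0) {
      dm <- sample(sched, nd)
      drop_keys <- c(drop_keys, paste(ids[i], dm))
    }
  }
  dropped <- paste(r$person_id, r$month) %in% drop_keys
  r[dropped, c("dudit_c", "swls", "scl90r_gsi", "drug_free_friends")] <- NA

  att <- !dropped
  n_att <- sum(att)
  # (b) item missingness at attended occasions
  r$dudit_c[att][runif(n_att) < rates["dudit"]] <- NA
  r$scl90r_gsi[att][runif(n_att) < rates["scl90r"]] <- NA
  mu_d <- config$grand_intercepts["DUDIT"] +
    config$trend_means["DUDIT"] * r$month / 12
  high <- att & !is.na(r$dudit_c) & r$dudit_c > mu_d
  p_base <- rates["swls"]
  odds <- p_base / (1 - p_base) * ifelse(high, mult, 1)
  p_swls <- odds / (1 + odds)
  mis_w <- att & (runif(nrow(r)) < p_swls)
  r$swls[mis_w] <- NA

  data$records <- r
  rownames(data$records) <- NULL
  data
}
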