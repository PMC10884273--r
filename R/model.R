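# internal linear-algebra helpers shared by the model, generator and reporting

.lyap <- function(phi, sigma_u) {
  S <- matrix(solve(diag(9) - kronecker(phi, phi), as.vector(sigma_u)), 3, 3)
  (S + t(S)) / 2
}

.spec_radius <- function(phi) max(Mod(eigen(phi, only.values = TRUE)$values))

.dmvnorm_log <- function(x, mean, sigma) {
  R <- chol(sigma)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Declarative model structure
#'
#' Builds the two-level residual DSEM specification: which lag-1 residual
#' paths exist, which outcomes carry a random linear time trend, and which
#' person-level covariates predict the between-level intercepts and trends.
#' The default mirrors the cohort analysis: the substance-use residual is
#' predicted by all three lagged residuals while life satisfaction and
#' psychological distress carry only their own lag (5 paths in total);
#' `lag = "full"` frees all 9 lagged paths for sensitivity work.
#'
#' @param lag `"default"`, `"full"`, or a named list mapping each outcome to
#'   the outcomes whose lagged residuals predict it, e.g.
#'   `list(DUDIT = c("DUDIT", "SWLS"), SWLS = "SWLS", SCL90R = "SCL90R")`.
#' @param trend logical, length 1 or 3: per-outcome random linear trend.
#' @param between_predictors person-level covariates for the between-level
#'   regressions; subset of `c("gender", "age")`.
#' @return an `rdsem_spec` with the lag mask, trend flags and predictors.
#' @export
#' @examples
#' sum(build_model_spec()$lag_mask)        # 5 lagged paths
#' sum(build_model_spec("full")$lag_mask)  # 9
build_model_spec <- function(lag = "default", trend = TRUE,
                             between_predictors = c("gender", "age")) {
  mask <- matrix(FALSE, 3, 3, dimnames = list(.OUTCOMES, .OUTCOMES))
  if (identical(lag, "default")) {
    mask["DUDIT", ] <- TRUE
    diag(mask) <- TRUE
  } else if (identical(lag, "full")) {
    mask[] <- TRUE
  } else if (is.list(lag)) {
    bad <- setdiff(c(names(lag), unlist(lag)), .OUTCOMES)
    if (length(bad))
      stop("unknown outcome(s) in lag structure: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    for (v in names(lag)) mask[v, unlist(lag[[v]])] <- TRUE
  } else stop("lag must be \"default\", \"full\" or a named list", call. = FALSE)
  trend <- rep_len(as.logical(trend), 3)
  names(trend) <- .OUTCOMES
  bad <- setdiff(between_predictors, c("gender", "age"))
  if (length(bad))
    stop("unknown between-level predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(outcomes = .OUTCOMES, lag_mask = mask, trend = trend,
                 between_predictors = between_predictors),
            class = "rdsem_spec")
}

#' @export
print.rdsem_spec <- function(x, ...) {
  cat("rDSEM specification:", sum(x$lag_mask), "lagged residual paths;",
      "trends on", paste(names(x$trend)[x$trend], collapse = ", "), "\n")
  cat("  between-level predictors:",
      paste(x$between_predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Prior regimes
#'
#' Two prior regimes for the rDSEM. The `reference` regime uses diffuse
#' normals on all location parameters and weak inverse-Wishart /
#' inverse-gamma priors on covariances, to test convergence. The
#' `admissible_range` regime concentrates mass on the theoretically
#' admissible region: lagged coefficients get a Normal(0, 0.5^2) prior
#' truncated to (-1, 1) (the stationary range for own-lags), and location
#' scales are tightened to 1. Covariance priors use scale matrices of 0.01
#' on the downscaled analysis metric, where outcome variances are well below
#' one, so that they stay weakly informative.
#'
#' @param regime `"admissible_range"` (default, the reporting regime) or
#'   `"reference"`.
#' @return an `rdsem_priors` list of hyperparameters.
#' @export
default_priors <- function(regime = c("admissible_range", "reference")) {
  regime <- match.arg(regime)
  adm <- regime == "admissible_range"
  structure(list(
    regime = regime,
    phi_sd = if (adm) 0.5 else 10,
    phi_trunc = adm,
    phi_bounds = if (adm) c(-1, 1) else c(-Inf, Inf),
    delta_sd = if (adm) 1 else 10,
    su_df = 5, su_scale = diag(0.01, 3),
    sb_df = 5, sb_scale = diag(0.01, 3),
    tv_shape = 2, tv_rate = 0.01,
    rho_max = 0.995),
    class = "rdsem_priors")
}

#' @export
print.rdsem_priors <- function(x, ...) {
  cat("rDSEM priors (", x$regime, "): AR ~ N(0, ", x$phi_sd, "^2)",
      if (x$phi_trunc) " truncated to (-1, 1)", "; locations ~ N(0, ",
      x$delta_sd, "^2)\n", sep = "")
  invisible(x)
}

#' Prior density for a single lagged coefficient
#'
#' Marginal prior density of one autoregressive/cross-lagged coefficient
#' under a prior regime; zero outside the admissible range when truncated.
#'
#' @param priors an `rdsem_priors`.
#' @param x coefficient value(s).
#' @return density value(s).
#' @export
phi_prior_density <- function(priors, x) {
  stopifnot(inherits(priors, "rdsem_priors"))
  d <- stats::dnorm(x, 0, priors$phi_sd)
  if (priors$phi_trunc) {
    Z <- diff(pnorm(priors$phi_bounds, 0, priors$phi_sd))
    d <- ifelse(x > priors$phi_bounds[1] & x < priors$phi_bounds[2], d / Z, 0)
  }
  d
}

#' Stationary within-level covariance of the residual process
#'
#' Solves the discrete Lyapunov equation
#' `vec(Sigma_eps) = (I - Phi (x) Phi)^{-1} vec(Sigma_u)` for the stationary
#' covariance of the lag-1 residual autoregression.
#'
#' @param config an `rdsem_config`, or any list with elements `phi` and
#'   `sigma_u`.
#' @return 3x3 stationary covariance matrix.
#' @export
#' @examples
#' stationary_moments(list(phi = diag(0.5, 3), sigma_u = diag(3)))
stationary_moments <- function(config) {
  phi <- config$phi
  su <- config$sigma_u
  stopifnot(is.matrix(phi), is.matrix(su), all(dim(phi) == 3),
            all(dim(su) == 3))
  if (.spec_radius(phi) >= 1)
    stop("phi is not stationary (spectral radius ",
         round(.spec_radius(phi), 3), " >= 1)", call. = FALSE)
  S <- .lyap(phi, su)
  dimnames(S) <- list(.OUTCOMES, .OUTCOMES)
  S
}

# build the between-level design matrix (intercept + requested predictors);
# age is standardized by the sample mean/SD of the person table
.build_design <- function(data, spec) {
  p <- data$persons
  X <- matrix(1, nrow(p), 1)
  cn <- "(Intercept)"
  if ("gender" %in% spec$between_predictors) {
    X <- cbind(X, p$gender); cn <- c(cn, "gender")
  }
  if ("age" %in% spec$between_predictors) {
    z <- (p$age - mean(p$age)) / sd(p$age)
    X <- cbind(X, z); cn <- c(cn, "age")
  }
  colnames(X) <- cn
  X
}

#' Complete-data log density of the two-level rDSEM
#'
#' Joint log density of the latent person effects and the complete outcome
#' panel: for each person, the between-level Gaussian density of
#' `(alpha_i, beta_i)` given the covariates, plus the within-level VAR(1)
#' density of the detrended residuals under `Phi` and `Sigma_u`, with the
#' first occasion drawn from the stationary distribution. This is the
#' complete-data target whose product with the priors the Gibbs sampler
#' explores (missing and phantom cells being part of the augmented state).
#'
#' @param params list with `phi` (3x3), `sigma_u` (3x3), `delta`
#'   (q x 6 between-level coefficients, components ordered as three
#'   intercepts then three trend slopes, predictors as in
#'   `.build_design`), `sigma_b` (3x3 intercept residual covariance) and
#'   `s2_trend` (length-3 trend residual variances).
#' @param spec an `rdsem_spec`.
#' @param data a lattice-expanded, complete `rdsem_panel` (imputations filled
#'   in; no `NA` outcome cells).
#' @param eta N x 6 matrix of latent person effects (alpha, beta), person
#'   rows ordered as in `data$persons`.
#' @return log-density value.
#' @export
complete_data_log_density <- function(params, spec, data, eta) {
  stopifnot(inherits(data, "rdsem_panel"), inherits(spec, "rdsem_spec"))
  if (!is_lattice_expanded(data))
    stop("data must be lattice-expanded", call. = FALSE)
  phi <- params$phi; su <- params$sigma_u
  if (.spec_radius(phi) >= 1) stop("phi not stationary", call. = FALSE)
  ev <- eigen(su, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sigma_u is not positive definite", call. = FALSE)
  se <- .lyap(phi, su)
  X <- .build_design(data, spec)
  ids <- data$persons$person_id
  tyears <- data$lattice / 12
  Tn <- length(tyears)
  r <- data$records
  ycols <- unname(.OUTCOME_COLS)
  if (anyNA(r[, ycols]))
    stop("complete-data density needs imputations for all missing cells",
         call. = FALSE)
  # between-level covariance of the active components
  act <- c(1:3, 3 + which(spec$trend))
  Sb6 <- matrix(0, 6, 6)
  Sb6[1:3, 1:3] <- params$sigma_b
  diag(Sb6)[4:6] <- params$s2_trend
  ld <- 0
  for (i in seq_along(ids)) {
    ri <- r[r$person_id == ids[i], , drop = FALSE]
    ri <- ri[order(ri$month), , drop = FALSE]
    Y <- t(as.matrix(ri[, ycols]))           # 3 x T
    a <- eta[i, 1:3]; b <- eta[i, 4:6]
    mu_i <- drop(t(params$delta) %*% X[i, ]) # 6
    ld <- ld + .dmvnorm_log(eta[i, act], mu_i[act],
                            Sb6[act, act, drop = FALSE])
    eps <- Y - a - outer(b, tyears)
    ld <- ld + .dmvnorm_log(eps[, 1], rep(0, 3), se)
    for (t in 2:Tn)
      ld <- ld + .dmvnorm_log(eps[, t], drop(phi %*% eps[, t - 1]), su)
  }
  ld
}
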