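.safe_var_rows <- function(m) {
  v <- apply(m, 1, var)
  v[!is.finite(v)] <- 0.01
  v
}

# map spec + design to the canonical parameter names, in the exact storage
# order of the C++ sampler
.param_names <- function(spec, xnames) {
  o <- .OUTCOMES
  nm <- character(0)
  for (v in 1:3) for (u in 1:3)
    if (spec$lag_mask[v, u]) nm <- c(nm, paste0("phi_", o[v], "_", o[u]))
  for (v in 1:3) for (w in v:3)
    nm <- c(nm, paste0("sigma_u_", o[w], "_", o[v]))
  for (comp in 1:6) {
    blk <- if (comp <= 3) "alpha" else "trend"
    ov <- o[(comp - 1) %% 3 + 1]
    for (j in seq_along(xnames)) {
      nm <- c(nm, if (j == 1) paste0("mu_", blk, "_", ov)
              else paste0("gamma_", blk, "_", ov, "_", xnames[j]))
    }
  }
  for (v in 1:3) for (w in v:3)
    nm <- c(nm, paste0("sigma_b_", o[w], "_", o[v]))
  nm <- c(nm, paste0("s2_trend_", o))
  nm <- c(nm, paste0("aux_EinvV_", o), paste0("aux_ErootinvV_", o),
          paste0("aux_EbrootinvV_", o))
  nm
}

#' Fit the two-level residual DSEM by MCMC
#'
#' Blocked Gibbs sampler with data augmentation: missing and phantom outcome
#' cells and the latent person effects (intercepts, trend slopes) are sampled
#' from their Gaussian full conditionals; between-level coefficients and
#' covariances use conjugate updates; the lagged-coefficient matrix and the
#' innovation covariance use Metropolis-within-Gibbs steps whose independence
#' proposal is the conjugate transition-only conditional, with the stationary
#' initial-occasion density entering the acceptance ratio, so the sampler
#' targets the exact posterior of [complete_data_log_density()] times the
#' priors. Under the admissible-range regime, lagged coefficients are
#' truncated to (-1, 1) and non-stationary proposals are rejected.
#'
#' @param data a lattice-expanded, rescaled `rdsem_panel`.
#' @param spec an `rdsem_spec` (default [build_model_spec()]).
#' @param priors an `rdsem_priors` (default admissible-range regime).
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iterations iterations per chain, including warmup.
#' @param warmup warmup iterations discarded per chain (default half).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param within_updates number of visits to the tightly coupled
#'   within-level blocks (augmented cells, person effects, lagged
#'   coefficients, innovation covariance) per Gibbs scan; the default 2
#'   roughly halves the integrated autocorrelation time at modest cost.
#' @param verbose print sampler progress.
#' @return an `rdsem_fit`: draws array (iterations x chains x parameters)
#'   with canonical parameter names, acceptance rates, posterior means of the
#'   augmented cells, convergence flag, and the data/spec/priors used.
#' @seealso [stdyx_standardize()], [r_squared()], [ess()], [rhat()]
#' @export
fit_mcmc <- function(data, spec = build_model_spec(),
                     priors = default_priors(), chains = 2,
                     iterations = 5000, warmup = floor(iterations / 2),
                     seed = 1, within_updates = 2, verbose = FALSE) {
  stopifnot(inherits(data, "rdsem_panel"), inherits(spec, "rdsem_spec"),
            inherits(priors, "rdsem_priors"))
  if (nrow(data$records) == 0) stop("empty panel", call. = FALSE)
  if (!is_lattice_expanded(data))
    stop("data must be lattice-expanded (expand_time_lattice) before fitting",
         call. = FALSE)
  if (!data$rescaled)
    stop("data must be on the rescaled analysis metric (rescale_outcomes)",
         call. = FALSE)
  if (warmup >= iterations) stop("warmup must be < iterations", call. = FALSE)

  persons <- data$persons
  ids <- persons$person_id
  N <- length(ids)
  lattice <- data$lattice
  Tn <- length(lattice)
  tyears <- lattice / 12
  r <- data$records
  ycols <- unname(.OUTCOME_COLS)
  # records -> T x 3 x N cube (records are sorted person, month)
  stopifnot(nrow(r) == N * Tn)
  Y <- array(NA_real_, c(Tn, 3, N))
  for (v in 1:3) Y[, v, ] <- matrix(r[[ycols[v]]], Tn, N)
  OBS <- array(as.integer(!is.na(Y)), c(Tn, 3, N))
  X <- .build_design(data, spec)

  # starting values: person means for intercepts, grand means elsewhere
  gm <- apply(Y, 2, mean, na.rm = TRUE)
  gm[is.na(gm)] <- 0
  pm <- apply(Y, c(2, 3), mean, na.rm = TRUE)       # 3 x N
  for (v in 1:3) pm[v, is.na(pm[v, ])] <- gm[v]
  Yfill <- Y
  for (v in 1:3) {
    miss <- is.na(Yfill[, v, ])
    Yfill[, v, ][miss] <- rep(pm[v, ], each = Tn)[miss]
  }
  wvar <- sapply(1:3, function(v) {
    dev <- sweep(matrix(Y[, v, ], Tn, N), 2, pm[v, ])
    m <- var(as.vector(dev), na.rm = TRUE)
    if (!is.finite(m) || m <= 0) 0.1 else m
  })
  eta0 <- cbind(t(pm), matrix(0, N, 3))
  delta0 <- matrix(0, ncol(X), 6)
  delta0[1, 1:3] <- gm
  init <- list(eta = eta0, delta = delta0, phi = matrix(0, 3, 3),
               sigma_u = diag(0.5 * wvar),
               sigma_b = diag(pmax(0.5 * .safe_var_rows(pm), 0.01)),
               s2_trend = rep(0.01, 3))

  var_t <- var(data$schedule / 12) * (length(data$schedule) - 1) /
    length(data$schedule)                            # population variance
  prior_list <- list(phi_sd = priors$phi_sd, phi_trunc = priors$phi_trunc,
                     delta_sd = priors$delta_sd,
                     su_df = priors$su_df, su_scale = priors$su_scale,
                     sb_df = priors$sb_df, sb_scale = priors$sb_scale,
                     tv_shape = priors$tv_shape, tv_rate = priors$tv_rate,
                     rho_max = priors$rho_max)
  pnames <- .param_names(spec, colnames(X))
  n_keep <- iterations - warmup
  draws <- array(NA_real_, c(n_keep, chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  accept <- matrix(NA_real_, chains, 2,
                   dimnames = list(NULL, c("phi", "sigma_u")))
  imp <- 0
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1)
    if (verbose) message("chain ", ch, "/", chains)
    res <- rdsem_gibbs_cpp(Yfill, OBS, tyears, X,
                           matrix(as.integer(spec$lag_mask), 3, 3),
                           as.integer(spec$trend), var_t, prior_list,
                           as.integer(iterations), as.integer(warmup),
                           init, as.integer(within_updates), verbose)
    stopifnot(ncol(res$draws) == length(pnames))
    draws[, ch, ] <- res$draws
    accept[ch, ] <- c(res$accept_phi, res$accept_sigma_u)
    imp <- imp + res$impute_mean / chains
  }

  fit <- structure(list(
    draws = draws, warmup = warmup, iterations = iterations,
    chains = chains, seed = seed, spec = spec, priors = priors,
    data = data, accept = accept, impute_mean = imp,
    var_t = var_t, param_names = pnames,
    xnames = colnames(X)), class = "rdsem_fit")
  model_pars <- pnames[!startsWith(pnames, "aux_")]
  if (chains >= 2) {
    rh <- vapply(model_pars, function(p) rhat(fit, p), numeric(1))
    fit$rhat <- rh
    fit$converged <- all(rh < 1.05, na.rm = TRUE)
    if (!fit$converged)
      warning("convergence not reached: max Rhat = ",
              round(max(rh, na.rm = TRUE), 3), " (threshold 1.05); ",
              "inspect the flagged fit before reporting", call. = FALSE)
  } else {
    fit$rhat <- NULL
    fit$converged <- NA
  }
  fit
}

#' @rdname fit_mcmc
#' @param ... passed on to [fit_mcmc()].
#' @export
rdsem <- function(data, ...) fit_mcmc(data, ...)

#' @export
print.rdsem_fit <- function(x, ...) {
  cat("rDSEM fit:", x$chains, "chains x", x$iterations, "iterations (",
      x$warmup, "warmup ), N =", nrow(x$data$persons), "persons\n")
  cat("  priors:", x$priors$regime, "\n")
  cat("  MH acceptance: phi", round(mean(x$accept[, 1]), 2),
      ", sigma_u", round(mean(x$accept[, 2]), 2), "\n")
  if (!is.null(x$rhat))
    cat("  max Rhat:", round(max(x$rhat, na.rm = TRUE), 3),
        if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
coef.rdsem_fit <- function(object, ...) {
  pars <- object$param_names[!startsWith(object$param_names, "aux_")]
  vapply(pars, function(p) mean(object$draws[, , p]), numeric(1))
}

#' @export
as.matrix.rdsem_fit <- function(x, ...) {
  d <- x$draws
  out <- matrix(d, dim(d)[1] * dim(d)[2], dim(d)[3])
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' @export
summary.rdsem_fit <- function(object, ...) {
  std <- stdyx_standardize(object)
  r2 <- r_squared(object)
  out <- list(stdyx = std, r2 = r2, fit = object)
  class(out) <- "summary.rdsem_fit"
  out
}

#' @export
print.summary.rdsem_fit <- function(x, ...) {
  print(x$fit)
  cat("\nSTDYX standardized results:\n")
  credible_table(x$stdyx)
  cat("\nR-squared:\n")
  print(x$r2$table, digits = 3)
  invisible(x)
}

#' @export
plot.rdsem_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars))
    pars <- head(x$param_names[startsWith(x$param_names, "phi_")], 6)
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    m <- x$draws[, , p, drop = FALSE]
    graphics::matplot(m[, , 1], type = "l", lty = 1, ylab = p, xlab = "")
  }
  invisible(x)
}
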