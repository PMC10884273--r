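#' Missingness and cluster-size summary
#'
#' Tabulates, over the full person-by-schedule grid of nominal occasions,
#' the 2^3 outcome-missingness patterns (an occasion with no record counts as
#' missing on all three outcomes), the number of complete occasions, and the
#' cluster-size distribution (number of attended occasions per person, where
#' attended means at least one outcome observed).
#'
#' @param data an `rdsem_panel` on the nominal schedule (call before
#'   [expand_time_lattice()]).
#' @return an `rdsem_missingness` list: `n_total_cells`,
#'   `n_complete_occasions`, `pattern_counts`, `cluster_size_table`
#'   (percentages), `n_persons`, `n_occasions`.
#' @export
missingness_patterns <- function(data) {
  stopifnot(inherits(data, "rdsem_panel"))
  if (is_lattice_expanded(data))
    stop("missingness summary is defined on the nominal schedule; ",
         "call before expand_time_lattice()", call. = FALSE)
  ids <- data$persons$person_id
  sched <- data$schedule
  grid <- expand.grid(person_id = ids, month = sched,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- merge(grid, data$records, by = c("person_id", "month"), all.x = TRUE)
  obs <- !is.na(m[, unname(.OUTCOME_COLS)])
  colnames(obs) <- .OUTCOMES
  pat <- apply(obs, 1, function(o) {
    mis <- .OUTCOMES[!o]
    if (!length(mis)) "none" else paste(mis, collapse = "+")
  })
  levels_pat <- c("none", "DUDIT", "SWLS", "SCL90R", "DUDIT+SWLS",
                  "DUDIT+SCL90R", "SWLS+SCL90R", "DUDIT+SWLS+SCL90R")
  pattern_counts <- table(factor(pat, levels = levels_pat))
  # attended = any recorded response at the occasion, including the
  # social-support item (a skipped questionnaire still counts as attendance)
  attended <- rowSums(obs) > 0 | !is.na(m$drug_free_friends)
  cl <- tapply(attended, m$person_id, sum)
  cluster_size_table <- 100 * table(factor(cl, levels = 0:length(sched))) /
    length(ids)
  cluster_size_table <- cluster_size_table[cluster_size_table > 0]
  structure(list(
    n_total_cells = nrow(grid),
    n_complete_occasions = sum(pat == "none"),
    pattern_counts = pattern_counts,
    cluster_size_table = cluster_size_table,
    n_persons = length(ids),
    n_occasions = length(sched)),
    class = "rdsem_missingness")
}

#' @export
print.rdsem_missingness <- function(x, ...) {
  cat("Missingness summary:", x$n_persons, "persons x", x$n_occasions,
      "occasions =", x$n_total_cells, "person-occasions\n")
  cat("  complete occasions:", x$n_complete_occasions, "\n")
  cat("  missingness patterns (missing outcomes -> count):\n")
  pc <- x$pattern_counts[x$pattern_counts > 0]
  for (nm in names(pc)) cat(sprintf("    %-20s %d\n", nm, pc[[nm]]))
  cat("  cluster sizes (attended occasions -> % of persons):\n")
  for (nm in names(x$cluster_size_table))
    cat(sprintf("    %-4s %.1f%%\n", nm, x$cluster_size_table[[nm]]))
  invisible(x)
}

#' Intraclass correlation ICC(1)
#'
#' One-way random-effects ANOVA estimate of the between-person share of
#' outcome variance, with the usual unbalanced-design correction for the
#' average cluster size, clipped to [0, 1]. High values indicate that a
#' hierarchical model is required.
#'
#' @param data an `rdsem_panel`.
#' @param outcome outcome name (`"DUDIT"`, `"SWLS"`, `"SCL90R"` or a record
#'   column name).
#' @return ICC(1) estimate in [0, 1].
#' @export
icc1 <- function(data, outcome) {
  stopifnot(inherits(data, "rdsem_panel"))
  col <- .outcome_col(outcome)
  v <- data$records[[col]]
  id <- data$records$person_id[!is.na(v)]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("outcome '", outcome, "' has no observed values", call. = FALSE)
  n_i <- table(id)
  if (sum(n_i >= 2) < 2)
    stop("ICC needs >= 2 persons with >= 2 observed values", call. = FALSE)
  k <- length(n_i)
  N <- sum(n_i)
  gm <- mean(v)
  mi <- tapply(v, id, mean)
  ssb <- sum(n_i * (mi - gm)^2)
  ssw <- sum((v - mi[as.character(id)])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  icc <- (msb - msw) / (msb + (n0 - 1) * msw)
  min(max(icc, 0), 1)
}

#' Dependence of an outcome's distribution on another outcome's missingness
#'
#' Compares observed values of `target`, stratified by whether `indicator`
#' is missing at the same occasion, with a Wilcoxon rank-sum test, Cliff's
#' delta and the standardized mean difference. Used to judge whether
#' missingness is ignorable for the observed-data distribution.
#'
#' @param data an `rdsem_panel`.
#' @param target outcome whose distribution is compared.
#' @param indicator outcome whose missingness defines the strata.
#' @return an `rdsem_dependence` list: `cliffs_delta`, `smd`, `statistic`,
#'   `p_value`, group sizes and means.
#' @export
distribution_by_missingness <- function(data, target, indicator) {
  stopifnot(inherits(data, "rdsem_panel"))
  tc <- .outcome_col(target)
  ic <- .outcome_col(indicator)
  if (tc == ic) stop("target and indicator must differ", call. = FALSE)
  r <- data$records
  keep <- !is.na(r[[tc]])
  y <- r[[tc]][keep]
  mis <- is.na(r[[ic]])[keep]
  n1 <- sum(mis); n0 <- sum(!mis)
  if (n1 == 0 || n0 == 0)
    stop("degenerate stratum: indicator '", indicator,
         if (n1 == 0) "' is never missing" else "' is always missing",
         " where target is observed", call. = FALSE)
  w <- suppressWarnings(wilcox.test(y[mis], y[!mis], exact = FALSE))
  delta <- 2 * unname(w$statistic) / (n1 * n0) - 1  # P(X>Y) - P(X<Y), ties halved
  sp <- sqrt(((n1 - 1) * var(y[mis]) + (n0 - 1) * var(y[!mis])) / (n1 + n0 - 2))
  smd <- (mean(y[mis]) - mean(y[!mis])) / sp
  structure(list(target = .resolve_outcome(target),
                 indicator = .resolve_outcome(indicator),
                 cliffs_delta = delta, smd = smd,
                 statistic = unname(w$statistic), p_value = w$p.value,
                 n_indicator_missing = n1, n_indicator_observed = n0,
                 mean_when_missing = mean(y[mis]),
                 mean_when_observed = mean(y[!mis])),
            class = "rdsem_dependence")
}

#' @export
print.rdsem_dependence <- function(x, ...) {
  cat(sprintf(
    "%s distribution by %s-missingness: Cliff's delta %.3f, SMD %.3f, W = %.0f, p = %.3g\n",
    x$target, x$indicator, x$cliffs_delta, x$smd, x$statistic, x$p_value))
  cat(sprintf("  mean %s: %.3f when %s missing (n=%d), %.3f when observed (n=%d)\n",
              x$target, x$mean_when_missing, x$indicator,
              x$n_indicator_missing, x$mean_when_observed,
              x$n_indicator_observed))
  invisible(x)
}
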