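test_that("CSV round trip preserves the panel and validates ranges", {
  p <- toy_panel(n = 3, months = c(0, 3))
  expect_equal(nrow(p$records), 6)
  f <- tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(p2$records, p$records)
  expect_equal(p2$persons, p$persons)
  expect_equal(p2$schedule, p$schedule)

  # out-of-range consumption score is rejected with the offending row
  d <- read.csv(f)
  d$dudit_c[2] <- 9
  write.csv(d, f, row.names = FALSE, na = "")
  expect_error(read_panel(f), "dudit_c out of range.*2")

  # missing required column
  d2 <- read.csv(f)[, -3]
  write.csv(d2, f, row.names = FALSE, na = "")
  expect_error(read_panel(f), "missing required column")

  # duplicate (person, month)
  d3 <- read.csv(f)
  d3$dudit_c[2] <- 3
  d3 <- rbind(d3, d3[1, ])
  write.csv(d3, f, row.names = FALSE, na = "")
  expect_error(read_panel(f), "duplicate")
})

test_that("empty and partially missing panels are written faithfully", {
  p <- toy_panel(2, c(0, 3))
  p$records$swls[2] <- NA
  f <- tempfile(fileext = ".csv")
  write_panel(p, f)
  lines <- readLines(f)
  # missing cell is empty, not a sentinel
  expect_match(lines[3], ",,")
  p2 <- read_panel(f)
  expect_true(is.na(p2$records$swls[2]))
  expect_equal(nrow(p2$records), nrow(p$records))

  p$records <- p$records[0, ]
  write_panel(p, f)
  expect_equal(length(readLines(f)), 1)  # header only
})

test_that("rescaling divides by the instrument factors and inverts exactly", {
  p <- toy_panel(3, c(0, 3))
  p$records$dudit_c[1] <- 8
  p$records$swls[1] <- 35
  p$records$scl90r_gsi[1] <- 2.5
  p$records$swls[2] <- NA
  r <- rescale_outcomes(p)
  expect_equal(r$records$dudit_c[1], 1.6)
  expect_equal(r$records$swls[1], 3.5)
  expect_equal(r$records$scl90r_gsi[1], 2.5)  # GSI untouched
  expect_true(is.na(r$records$swls[2]))
  expect_true(r$rescaled)
  expect_error(rescale_outcomes(r), "already rescaled")
  back <- rescale_outcomes(r, inverse = TRUE)
  expect_equal(back$records, p$records, tolerance = 1e-12)
  expect_error(rescale_outcomes(p, inverse = TRUE), "not rescaled")
})

test_that("lattice expansion inserts phantom occasions on a constant grid", {
  cfg <- default_generating_config(n_persons = 4)
  p <- generate_panel(cfg, seed = 3)
  e <- expand_time_lattice(p)
  # months 0..48 in steps of 3: 17 occasions, 6 of them phantom
  expect_equal(length(e$lattice), 17)
  expect_equal(nrow(e$records), 4 * 17)
  phantom <- !(e$records$month %in% p$schedule)
  expect_equal(sum(phantom), 4 * 6)
  expect_true(all(is.na(e$records$dudit_c[phantom])))
  # original records unchanged
  orig <- e$records[!phantom, ]
  rownames(orig) <- NULL
  expect_equal(orig, p$records)
  # idempotent
  e2 <- expand_time_lattice(e)
  expect_equal(e2$records, e$records)

  # already equally spaced schedule: no rows added
  q <- toy_panel(2, c(0, 3, 6))
  expect_equal(nrow(expand_time_lattice(q)$records), nrow(q$records))

  # a person observed at few occasions still gets the full lattice
  pm <- impose_missingness(p, cfg, seed = 4)
  em <- expand_time_lattice(pm)
  n_per <- table(em$records$person_id)
  expect_true(all(n_per == 17))

  expect_error(expand_time_lattice(toy_panel(2, c(0, 3)), step_months = 5),
               "smallest schedule gap")
})

test_that("drug-use dichotomization applies the abstinence cutoff", {
  p <- toy_panel(2, c(0, 3))
  p$records$dudit_c <- c(0, 1, 5, NA)
  d <- dichotomize_dudit(p)
  expect_equal(d$use, c(0, 1, 1, NA))
  expect_error(dichotomize_dudit(rescale_outcomes(p)), "unrescaled")
})

test_that("low-variance covariate screening follows the constancy threshold", {
  p <- toy_panel(4, c(0, 3, 6))
  p$records$drug_free_friends <- 1
  s <- screen_low_variance_covariate(p)
  expect_equal(s$decision, "drop")
  expect_equal(s$pooled_variance, 0)

  p$records$drug_free_friends <- rep(c(0, 1, 0), 4)  # alternating
  expect_equal(screen_low_variance_covariate(p)$decision, "keep")

  # exactly at the threshold counts as droppable
  p$records$drug_free_friends <- 1
  p$records$drug_free_friends[p$records$person_id == "P01"] <- c(0, 1, 0)
  s3 <- screen_low_variance_covariate(p, threshold = 0.75)
  expect_equal(s3$prop_constant, 0.75)
  expect_equal(s3$decision, "drop")
  expect_error(screen_low_variance_covariate(p, covariate = "nope"),
               "not found")
})

test_that("missingness patterns count the full person-by-schedule grid", {
  p <- toy_panel(3, c(0, 3))
  ms <- missingness_patterns(p)
  expect_equal(ms$n_total_cells, 6)
  expect_equal(ms$n_complete_occasions, 6)
  expect_equal(sum(ms$pattern_counts), 6)
  expect_equal(unname(ms$cluster_size_table[["2"]]), 100)

  p$records$swls[1] <- NA
  ms2 <- missingness_patterns(p)
  expect_equal(unname(ms2$pattern_counts[["SWLS"]]), 1)
  expect_equal(ms2$n_complete_occasions, 5)

  # a fully absent occasion row counts as missing on all three outcomes
  p$records <- p$records[-2, ]
  ms3 <- missingness_patterns(p)
  expect_equal(sum(ms3$pattern_counts), 6)
  expect_equal(unname(ms3$pattern_counts[["DUDIT+SWLS+SCL90R"]]), 1)
  expect_error(missingness_patterns(expand_time_lattice(toy_panel(2))),
               "nominal schedule")
})

test_that("ICC(1) matches known variance components", {
  # person means differ, zero within-person variation -> 1
  p <- toy_panel(3, c(0, 3))
  p$records$swls <- rep(c(10, 20, 30), each = 2)
  expect_equal(icc1(p, "SWLS"), 1)

  # i.i.d. values -> ~0 (clipped at 0)
  set.seed(31)
  n <- 400; k <- 6
  recs <- data.frame(person_id = rep(sprintf("P%03d", 1:n), each = k),
                     month = rep(seq(0, by = 3, length.out = k), n),
                     dudit_c = NA, swls = NA,
                     scl90r_gsi = runif(n * k, 0, 4),
                     drug_free_friends = NA)
  pers <- data.frame(person_id = sprintf("P%03d", 1:n), age = 25, gender = 1)
  pan <- panel_dataset(recs, pers)
  expect_lt(icc1(pan, "SCL90R"), 0.03)

  # balanced generator with known between share 0.49
  set.seed(32)
  n <- 2000; k <- 11
  b <- rnorm(n, 0, sqrt(0.49))
  y <- rep(b, each = k) + rnorm(n * k, 0, sqrt(0.51))
  recs2 <- data.frame(person_id = rep(sprintf("P%04d", 1:n), each = k),
                      month = rep(seq(0, by = 3, length.out = k), n),
                      dudit_c = NA, swls = NA, scl90r_gsi = y,
                      drug_free_friends = NA)
  pers2 <- data.frame(person_id = sprintf("P%04d", 1:n), age = 25, gender = 1)
  pan2 <- panel_dataset(recs2, pers2, rescaled = TRUE)  # analysis metric
  expect_equal(icc1(pan2, "SCL90R"), 0.49, tolerance = 0.08)

  expect_error(icc1(pan2, "SWLS"), "no observed values")
  one <- toy_panel(2, c(0, 3))
  one$records$dudit_c <- c(1, NA, NA, NA)
  expect_error(icc1(one, "DUDIT"), ">= 2 persons")
})

test_that("distribution-by-missingness dependence test behaves at the null
           and detects configured dependence", {
  # null: indicator missing completely at random
  set.seed(41)
  n <- 300; k <- 6
  recs <- data.frame(person_id = rep(sprintf("P%03d", 1:n), each = k),
                     month = rep(seq(0, by = 3, length.out = k), n),
                     dudit_c = sample(0:8, n * k, replace = TRUE),
                     swls = ifelse(runif(n * k) < 0.3, NA,
                                   sample(5:35, n * k, replace = TRUE)),
                     scl90r_gsi = NA, drug_free_friends = NA)
  pers <- data.frame(person_id = sprintf("P%03d", 1:n), age = 25, gender = 1)
  pan <- panel_dataset(recs, pers)
  dep <- distribution_by_missingness(pan, "DUDIT", "SWLS")
  expect_lt(abs(dep$cliffs_delta), 0.1)

  # configured dependence: drug use higher when life satisfaction missing
  cfg <- default_generating_config(n_persons = 400)
  pm <- impose_missingness(generate_panel(cfg, seed = 8), cfg, seed = 9)
  dep2 <- distribution_by_missingness(pm, "DUDIT", "SWLS")
  expect_gt(dep2$cliffs_delta, 0)
  expect_lt(dep2$p_value, 0.01)

  # degenerate stratum
  recs$swls <- sample(5:35, n * k, replace = TRUE)
  pan3 <- panel_dataset(recs, pers)
  expect_error(distribution_by_missingness(pan3, "DUDIT", "SWLS"),
               "degenerate stratum")
})

test_that("panel invariants are enforced", {
  p <- toy_panel(2, c(0, 3))
  bad <- p
  bad$persons$age[1] <- 15
  expect_error(validate_panel(bad), "inclusion minimum")
  bad2 <- p
  bad2$records$person_id[1] <- "ghost"
  expect_error(validate_panel(bad2), "unknown person")
  bad3 <- p
  bad3$records$month[1] <- 7
  expect_error(validate_panel(bad3), "outside the schedule")
})
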