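test_that("compute_bmi follows weight/(height in m)^2 and rejects degenerate input", {
  expect_identical(compute_bmi(100, 200), 25)
  expect_equal(compute_bmi(87, 193), 23.36, tolerance = 0.01 / 23.36)
  expect_error(compute_bmi(87, 0), "height")
  expect_error(compute_bmi(0, 193), "weight")
  expect_error(compute_bmi(-1, 180), "weight")
})

test_that("default edition parameters carry the published marginals", {
  params <- default_edition_params()
  expect_length(params, 10L)
  labels <- vapply(params, `[[`, character(1), "edition_label")
  expect_length(unique(labels), 5L)
  groups <- vapply(params, `[[`, character(1), "group_label")
  expect_equal(sum(groups == "medalist"), 5L)

  key <- paste(labels, groups, sep = "/")
  sydney_med <- params[[which(key == "Sydney/medalist")]]
  expect_equal(sydney_med$means[["age"]], 22.000)
  expect_equal(sydney_med$sds[["age"]], 2.000)
  expect_equal(sydney_med$n_athletes, 3L)

  rio_non <- params[[which(key == "Rio/non_medalist")]]
  expect_equal(rio_non$means[["olympic_medals"]], 0)
  expect_equal(rio_non$sds[["olympic_medals"]], 0)
  expect_equal(rio_non$n_athletes, 5L)
  # zero SD => degenerate variable is flagged at generation time
  expect_warning(generate_cohort(rio_non, seed = 1), "olympic_medals")
})

test_that("edition_params validates its invariants", {
  means <- setNames(c(25, 85, 190, 2, 0.7, 21.8),
                    c("age", "weight", "height", "olympic_medals",
                      "reaction_time", "race_time"))
  sds <- setNames(rep(1, 6), names(means))
  expect_s3_class(edition_params("X", "medalist", 3, means, sds), "edition_params")
  expect_error(edition_params("X", "medalist", 1, means, sds), "n_athletes")
  expect_error(edition_params("X", "medalist", 3, means, -sds), "non-negative")
  expect_error(edition_params("X", "medalist", 3, means, sds,
                              factor_loading = 1.2), "\\[0, 1\\]")
  bad_means <- means; bad_means[["height"]] <- -190
  expect_error(edition_params("X", "medalist", 3, bad_means, sds), "positive")
})

test_that("generator is deterministic and derives BMI and velocity", {
  params <- default_edition_params()[[1]]
  a <- generate_cohort(params, seed = 123)
  b <- generate_cohort(params, seed = 123)
  expect_identical(a, b)
  c <- generate_cohort(params, seed = 124)
  expect_false(identical(a$age, c$age))
  # BMI is recomputed from weight and height, never sampled
  expect_equal(a$bmi, a$weight / (a$height / 100)^2, tolerance = 1e-12)
  expect_equal(a$velocity, 50 / a$race_time, tolerance = 1e-12)
  expect_true(all(a$olympic_medals >= 0))
  expect_true(all(a$olympic_medals == round(a$olympic_medals)))
  expect_error(generate_cohort(params, seed = 1, n = -3), "positive")
  expect_error(generate_cohort(params), "seed")
})

test_that("zero loadings give near-independent variables, unit loadings rank-1", {
  params <- default_edition_params()[[1]]
  zero <- setNames(rep(0, 6), names(params$factor_loading))
  big <- generate_cohort(params, seed = 99, loading_overrides = zero, n = 500)
  sampled <- c("age", "weight", "height", "reaction_time", "race_time")
  cors <- cor(big[, sampled])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.15)

  one <- setNames(rep(1, 6), names(params$factor_loading))
  rank1 <- generate_cohort(params, seed = 7, loading_overrides = one, n = 20)
  # continuous variables are exact affine images of the single latent factor;
  # olympic_medals is rounded/clipped so exactness applies to the others
  cors1 <- cor(rank1[, sampled])
  expect_equal(abs(cors1[upper.tri(cors1)]), rep(1, 10), tolerance = 1e-12)
})

test_that("marginals are calibrated at large n for continuous variables", {
  params <- default_edition_params()[[1]]   # Sydney medalists
  big <- generate_cohort(params, seed = 2024, n = 10000)
  for (v in c("age", "weight", "height", "reaction_time", "race_time")) {
    expect_equal(mean(big[[v]]), params$means[[v]],
                 tolerance = 0.02, ignore_attr = TRUE)
    expect_equal(sd(big[[v]]), params$sds[[v]],
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("mean absolute pairwise correlation increases with the loading", {
  params <- default_edition_params()[[2]]   # n = 5 group
  sampled <- c("age", "weight", "height", "reaction_time", "race_time")
  mean_abs_r <- function(lambda) {
    ld <- setNames(rep(lambda, 6), names(params$factor_loading))
    reps <- vapply(1:200, function(i) {
      g <- suppressWarnings(
        generate_cohort(params, seed = 5000 + i, loading_overrides = ld, n = 5))
      m <- cor(g[, sampled])
      mean(abs(m[upper.tri(m)]))
    }, numeric(1))
    mean(reps)
  }
  r0 <- mean_abs_r(0); r5 <- mean_abs_r(0.5); r9 <- mean_abs_r(0.9)
  expect_lt(r0, r5)
  expect_lt(r5, r9)
})

test_that("synthesize_cohorts builds full finals with ranks 1..8 per edition", {
  cohort <- suppressWarnings(synthesize_cohorts(synthetic_config(seed = 31)))
  expect_equal(nrow(cohort), 40L)
  expect_length(unique(cohort$edition), 5L)
  for (ed in unique(cohort$edition)) {
    sub <- cohort[cohort$edition == ed, ]
    expect_setequal(sub$rank, 1:8)
    expect_equal(sub$group[order(sub$rank)],
                 c(rep("medalist", 3), rep("non_medalist", 5)))
  }
  # bit-identical reproduction under the same config
  again <- suppressWarnings(synthesize_cohorts(synthetic_config(seed = 31)))
  expect_identical(cohort, again)
  # degenerate flag propagated for the zero-SD Rio non-medalist medals
  expect_true("olympic_medals" %in%
                attr(cohort, "degenerate_variables")[["Rio/non_medalist"]])
})
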