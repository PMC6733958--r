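test_that("oneway_anova matches hand computation and handles edge cases", {
  # identical group means: F = 0, p = 1
  a0 <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a0$f, 0)
  expect_equal(a0$p, 1)
  # hand-computed toy: SS_between = 8, SS_within = 10, df = (1, 6)
  a1 <- oneway_anova(list(c(1, 2, 3, 4), c(3, 4, 5, 6)))
  expect_equal(a1$f, 4.8, tolerance = 1e-12)
  expect_equal(a1$p, pf(4.8, 1, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(a1$df), c(1L, 6L))

  expect_error(oneway_anova(list(c(1, 2, 3))), "2 groups")
  expect_error(oneway_anova(list(c(1, 2), c(3))), "at least 2 observations")
  expect_error(oneway_anova(list(c(2, 2), c(3, 3))), "degenerate")
})

test_that("ANOVA agrees with the pooled t-test and stats::aov on random data", {
  set.seed(301)
  for (i in 1:25) {
    g1 <- rnorm(sample(3:8, 1)); g2 <- rnorm(sample(3:8, 1), mean = runif(1))
    a <- oneway_anova(list(a = g1, b = g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(a$f, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a$p, tt$p.value, tolerance = 1e-9)
    g3 <- rnorm(sample(3:8, 1), mean = runif(1))
    dat <- data.frame(y = c(g1, g2, g3),
                      g = rep(c("a", "b", "c"), c(length(g1), length(g2), length(g3))))
    ref <- summary(stats::aov(y ~ g, dat))[[1]]
    a3 <- oneway_anova(list(g1, g2, g3))
    expect_equal(a3$f, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(a3$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("tukey_hsd reproduces q = sqrt(2F) for two groups and TukeyHSD for three", {
  set.seed(302)
  for (i in 1:20) {
    g1 <- rnorm(5); g2 <- rnorm(5, 0.5)
    a <- oneway_anova(list(g1, g2))
    tk <- tukey_hsd(list(g1, g2))
    expect_equal(tk$q, sqrt(2 * a$f), tolerance = 1e-9)
    # with two groups the Tukey-adjusted p equals the ANOVA p
    expect_equal(tk$p_adj, a$p, tolerance = 1e-6)
  }
  # identical groups: p ~ 1
  expect_gt(tukey_hsd(list(c(1, 2, 3), c(1, 2, 3)))$p_adj, 0.999)
  # 3 balanced groups against the reference implementation
  set.seed(303)
  groups <- list(a = rnorm(6), b = rnorm(6, 0.8), c = rnorm(6, -0.4))
  tk3 <- tukey_hsd(groups)
  dat <- data.frame(y = unlist(groups), g = rep(names(groups), each = 6))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, dat))$g
  expect_equal(sort(tk3$p_adj), sort(unname(ref[, "p adj"])), tolerance = 1e-6)
  expect_equal(sort(abs(tk3$mean_diff)), sort(abs(unname(ref[, "diff"]))),
               tolerance = 1e-9)
})

test_that("compare_link_weights separates clearly different networks", {
  high <- uniform_complete(6, 0.9); low <- uniform_complete(6, 0.3)
  jitter_net <- function(m, seed) {
    # perturb slightly so within-group variance is nonzero
    set.seed(seed)
    d <- matrix(0, 6, 6); d[upper.tri(d)] <- rnorm(15, 0, 0.02)
    d <- d + t(d)
    out <- m + d; diag(out) <- 0
    net <- build_network(matrix(rnorm(42), 7, 6))  # shell for structure
    net$weights <- abs(out); net$signed_weights <- out
    dimnames(net$weights) <- dimnames(net$signed_weights) <-
      list(net$node_labels, net$node_labels)
    net
  }
  a <- jitter_net(high, 1); b <- jitter_net(low, 2)
  res <- compare_link_weights(a, b)
  expect_s3_class(res, "comparison_result")
  expect_lt(res$anova_p, 1e-6)
  expect_match(res$direction, ">=")
  expect_equal(res$group_summaries$n, c(15L, 15L))

  # identical networks: F = 0
  net <- build_network(select_node_variables(split_by_medal(make_manual_final())$non_medalist))
  res_id <- compare_link_weights(net, net)
  expect_equal(res_id$anova_f, 0)
  expect_equal(res_id$anova_p, 1)

  other <- build_network(matrix(c(1, 2, 4, 3, 2, 8), 3, 2))
  expect_error(compare_link_weights(net, other), "node set")
})

test_that("compare_spectral_radii reports per-edition ordering", {
  med <- c(3.75, 3.5, 3.39, 2.91, 3.66)
  non <- c(2.18, 2.51, 2.23, 2.07, 2.04)
  tab <- data.frame(
    edition = rep(c("Sydney", "Athens", "Beijing", "London", "Rio"), 2),
    group = rep(c("medalist", "non_medalist"), each = 5),
    sr = c(med, non))
  res <- compare_spectral_radii(tab)
  expect_equal(res$group_summaries$mean[res$group_summaries$group == "medalist"],
               mean(med))
  expect_true(all(res$edition_ordering$medalist_higher))
  expect_lt(res$anova_p, 0.05)

  # identical SR lists: F = 0 and all orderings tie (FALSE under strict >)
  tied <- tab; tied$sr <- rep(c(3, 3.2, 2.9, 3.1, 3.05), 2)
  res_tied <- compare_spectral_radii(tied)
  expect_equal(res_tied$anova_f, 0)
  expect_false(any(res_tied$edition_ordering$medalist_higher))

  expect_error(compare_spectral_radii(tab[c(1, 6), ]), "at least 2")
})

test_that("permutation test is deterministic, bounded below, and detects separation", {
  final <- make_final(seed = 21L)
  groups <- split_by_medal(final)
  p1 <- permutation_group_test(groups$medalist$records,
                               groups$non_medalist$records,
                               n_permutations = 99, seed = 5)
  p2 <- permutation_group_test(groups$medalist$records,
                               groups$non_medalist$records,
                               n_permutations = 99, seed = 5)
  expect_identical(p1, p2)
  expect_gte(p1$p, 1 / 100)
  expect_lte(p1$p, 1)

  expect_error(permutation_group_test(groups$medalist$records,
                                      groups$non_medalist$records,
                                      n_permutations = 10, seed = 1),
               "99")
  expect_error(permutation_group_test(groups$medalist$records[1:2, ],
                                      groups$non_medalist$records[1:2, ],
                                      n_permutations = 99, seed = 1),
               "5 pooled")

  # a trivially separable statistic attains the minimal achievable p once the
  # pool is large enough that resampling cannot redraw the observed partition
  sep_stat <- function(ma, mb) mean(ma[, "age"]) - mean(mb[, "age"])
  make_rec <- function(age) {
    data.frame(age = age, weight = 85 + seq_along(age), height = 190 + seq_along(age),
               bmi = 23, olympic_medals = 1, reaction_time = 0.7)
  }
  p_sep <- permutation_group_test(make_rec(100 + 1:10), make_rec(1:10),
                                  n_permutations = 199, seed = 9,
                                  statistic = sep_stat)
  expect_equal(p_sep$p, 1 / 200)
})

test_that("permutation p-values are roughly uniform under the null", {
  # identical generating process for both groups (loading 0.45, same marginals)
  params <- default_edition_params()[[2]]   # Sydney non-medalists, n = 5
  pvals <- vapply(1:60, function(i) {
    a <- generate_cohort(params, seed = 9000 + 2 * i, n = 3)
    b <- generate_cohort(params, seed = 9001 + 2 * i, n = 5)
    permutation_group_test(a, b, n_permutations = 99,
                           seed = 100 + i)$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.85)
})
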