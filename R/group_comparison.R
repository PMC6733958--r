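# Group comparison: one-way ANOVA + Tukey HSD (the tests used in the source
# analyses) plus a permutation test on the spectral-radius difference, added
# because groups of 3 vs 5 athletes make F-distribution assumptions fragile.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("at least 2 groups are required")
  }
  if (any(!vapply(groups, is.numeric, logical(1)))) {
    stop("groups must be numeric vectors")
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' One-way fixed-effects ANOVA
#'
#' Classical decomposition: `F = MS_between / MS_within` on `(k - 1, N - k)`
#' degrees of freedom, p-value from the F distribution.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return List of class `anova_result`: `f`, `p`, `df`, `ms_between`,
#'   `ms_within`, `group_means`, `group_sds`, `group_n`.
#' @export
oneway_anova <- function(groups) {
  groups <- check_groups(groups)
  n <- vapply(groups, length, integer(1))
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- c(between = k - 1L, within = N - k)
  if (df[["within"]] < 1L) stop("total sample size must exceed the number of groups")
  ms_within <- ss_within / df[["within"]]
  if (ms_within == 0) {
    stop("all within-group variances are zero; ANOVA is degenerate")
  }
  f <- (ss_between / df[["between"]]) / ms_within
  structure(
    list(f = f, p = stats::pf(f, df[["between"]], df[["within"]], lower.tail = FALSE),
         df = df, ms_between = ss_between / df[["between"]],
         ms_within = ms_within,
         group_means = means,
         group_sds = vapply(groups, stats::sd, numeric(1)),
         group_n = n),
    class = "anova_result"
  )
}

#' Tukey honestly-significant-difference post hoc test
#'
#' For every pair of groups reports the mean difference, the studentized
#' range statistic `q = |diff| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`
#' (Tukey-Kramer for unbalanced groups), a `(1 - alpha)` family-wise
#' confidence interval, and the adjusted p-value from the studentized range
#' distribution with `k` groups and `N - k` degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @param alpha Family-wise error rate for the confidence intervals.
#' @return Data frame with one row per pair: `pair`, `mean_diff`, `q`,
#'   `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  a <- oneway_anova(groups)
  k <- length(groups)
  dfw <- a$df[["within"]]
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- a$group_means[[i]] - a$group_means[[j]]
    se <- sqrt(a$ms_within / 2 * (1 / a$group_n[[i]] + 1 / a$group_n[[j]]))
    q <- abs(diff) / se
    crit <- stats::qtukey(1 - alpha, k, dfw)
    data.frame(pair = paste(i, j, sep = " - "),
               mean_diff = diff, q = q,
               lwr = diff - crit * se, upr = diff + crit * se,
               p_adj = stats::ptukey(q, k, dfw, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

new_comparison_result <- function(kind, groups, anova, tukey,
                                  direction = NULL, edition_ordering = NULL,
                                  permutation = NULL) {
  structure(
    list(comparison_kind = kind,
         group_summaries = data.frame(
           group = names(groups),
           n = vapply(groups, length, integer(1)),
           mean = vapply(groups, mean, numeric(1)),
           sd = vapply(groups, stats::sd, numeric(1)),
           row.names = NULL, stringsAsFactors = FALSE),
         anova_f = anova$f, anova_p = anova$p, anova_df = anova$df,
         tukey_pairs = tukey,
         direction = direction,
         edition_ordering = edition_ordering,
         permutation = permutation),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s\n", x$comparison_kind))
  print(transform(x$group_summaries, mean = round(mean, 4), sd = round(sd, 4)))
  cat(sprintf("  ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$anova_df[["between"]], x$anova_df[["within"]],
              x$anova_f, x$anova_p))
  if (!is.null(x$direction)) cat("  direction:", x$direction, "\n")
  if (!is.null(x$edition_ordering)) {
    ok <- sum(x$edition_ordering$medalist_higher)
    cat(sprintf("  medalist SR higher in %d/%d editions\n",
                ok, nrow(x$edition_ordering)))
  }
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation$p, x$permutation$n_permutations))
  }
  invisible(x)
}

#' Compare the link weights of two networks
#'
#' The 15 upper-triangle weights of each 6-node network form the two ANOVA
#' groups; the result reports which group's mean link weight is larger.
#'
#' @param net_a,net_b `correlation_network`s over the same node set, built
#'   in the same weight mode.
#' @return A `comparison_result` of kind `link_weights`.
#' @export
compare_link_weights <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "correlation_network"),
            inherits(net_b, "correlation_network"))
  if (!setequal(net_a$node_labels, net_b$node_labels)) {
    stop("networks must share the same node set")
  }
  if (!identical(net_a$weight_mode, net_b$weight_mode)) {
    stop("networks must be built in the same weight mode")
  }
  label <- function(net, fallback) {
    if (is.na(net$group_label)) fallback else net$group_label
  }
  groups <- stats::setNames(
    list(upper_weights(net_a), upper_weights(net_b)),
    make.unique(c(label(net_a, "network_a"), label(net_b, "network_b")))
  )
  a <- oneway_anova(groups)
  direction <- sprintf(
    "%s mean link weight (%.3f) %s %s (%.3f)",
    names(groups)[1], a$group_means[[1]],
    if (a$group_means[[1]] >= a$group_means[[2]]) ">=" else "<",
    names(groups)[2], a$group_means[[2]])
  new_comparison_result("link_weights", groups, a, tukey_hsd(groups),
                        direction = direction)
}

#' Compare spectral radii between groups of networks
#'
#' Pools the spectral radii of many networks (typically one medalist and one
#' non-medalist network per edition) by group label and runs one-way ANOVA
#' plus Tukey HSD; when both groups are present in an edition the per-edition
#' ordering (medalist SR > non-medalist SR?) is also reported.
#'
#' @param summaries Either a list of `spectral_summary` objects or a data
#'   frame with columns `edition`, `group`, `sr`.
#' @return A `comparison_result` of kind `spectral_radius`.
#' @export
compare_spectral_radii <- function(summaries) {
  if (is.data.frame(summaries)) {
    tab <- summaries
    stopifnot(all(c("edition", "group", "sr") %in% names(tab)))
  } else {
    stopifnot(all(vapply(summaries, inherits, logical(1), "spectral_summary")))
    tab <- data.frame(
      edition = vapply(summaries, `[[`, character(1), "edition_label"),
      group = vapply(summaries, `[[`, character(1), "group_label"),
      sr = vapply(summaries, `[[`, numeric(1), "spectral_radius"),
      stringsAsFactors = FALSE
    )
  }
  groups <- split(tab$sr, tab$group)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs spectral radii from at least 2 networks")
  }
  a <- oneway_anova(groups)
  ordering <- NULL
  if (setequal(names(groups), c("medalist", "non_medalist"))) {
    wide <- merge(
      tab[tab$group == "medalist", c("edition", "sr")],
      tab[tab$group == "non_medalist", c("edition", "sr")],
      by = "edition", suffixes = c("_medalist", "_non_medalist")
    )
    ordering <- data.frame(
      edition = wide$edition,
      sr_medalist = wide$sr_medalist,
      sr_non_medalist = wide$sr_non_medalist,
      medalist_higher = wide$sr_medalist > wide$sr_non_medalist,
      stringsAsFactors = FALSE
    )
  }
  direction <- sprintf(
    "%s mean SR (%.3f) %s %s (%.3f)",
    names(groups)[1], a$group_means[[1]],
    if (a$group_means[[1]] >= a$group_means[[2]]) ">=" else "<",
    names(groups)[2], a$group_means[[2]])
  new_comparison_result("spectral_radius", groups, a, tukey_hsd(groups),
                        direction = direction, edition_ordering = ordering)
}

#' Permutation test for a between-group network statistic
#'
#' Re-partitions the pooled athletes into groups of the original sizes,
#' rebuilds both networks and recomputes the statistic (by default the
#' spectral-radius difference) for each shuffle.  The two-sided p-value is
#' `(1 + #{|stat_perm| >= |stat_obs|}) / (n_permutations + 1)`, which is a
#' valid p-value for any number of random permutations.
#'
#' @param records_a,records_b Data frames of athlete records (the two
#'   groups).
#' @param n_permutations Number of random re-partitions, >= 99.
#' @param seed Integer seed (required; the test is deterministic given it).
#' @param variables Node variables used to build the networks.
#' @param mode Weight mode passed to [build_network()].
#' @param statistic Function `(matrix_a, matrix_b) -> scalar`; default is
#'   the difference of spectral radii of the two correlation networks.
#' @return List of class `permutation_test`: `p`, `observed`,
#'   `n_permutations`, `seed`, `n_redrawn`.
#' @export
permutation_group_test <- function(records_a, records_b,
                                   n_permutations = 199L, seed,
                                   variables = node_variables(),
                                   mode = c("absolute", "signed"),
                                   statistic = NULL) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required")
  if (n_permutations < 99L) stop("at least 99 permutations are required")
  xa <- select_node_variables(records_a, variables)
  xb <- select_node_variables(records_b, variables)
  na <- nrow(xa); nb <- nrow(xb)
  if (na + nb < 5L) stop("at least 5 pooled athletes are required")
  if (na < 2L || nb < 2L) stop("each group needs at least 2 athletes")
  if (is.null(statistic)) {
    statistic <- function(ma, mb) {
      spectral_radius(build_network(ma, mode = mode)) -
        spectral_radius(build_network(mb, mode = mode))
    }
  }
  pooled <- rbind(xa, xb)
  observed <- statistic(xa, xb)
  if (!is.finite(observed)) stop("statistic undefined on the observed grouping")
  n_redrawn <- 0L
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      for (attempt in 1:10) {
        idx <- sample.int(na + nb, na)
        s <- suppressWarnings(
          tryCatch(statistic(pooled[idx, , drop = FALSE],
                             pooled[-idx, , drop = FALSE]),
                   error = function(e) NA_real_))
        if (is.finite(s)) return(s)
        n_redrawn <<- n_redrawn + 1L
      }
      stop("statistic undefined on 10 consecutive shuffles")
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_stats) >= abs(observed))) / (n_permutations + 1)
  structure(
    list(p = p, observed = observed, n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), n_redrawn = n_redrawn),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$observed, x$p, x$n_permutations, x$seed))
  invisible(x)
}
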