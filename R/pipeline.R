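# End-to-end orchestration: ingest or synthesise a cohort, split each edition
# into medalists / non-medalists, build the 2 networks per edition, run the
# spectral decomposition, compare groups, and write a deterministic report.

#' Pipeline configuration
#'
#' @param input_csv Path to a cohort CSV; when `NULL` a synthetic cohort is
#'   generated from `synthetic`.
#' @param synthetic A [synthetic_config()]; defaults to the published
#'   5-edition parameters with seed `seed`.
#' @param weight_mode `"absolute"` (default) or `"signed"`.
#' @param seed Master seed for every stochastic step (synthesis,
#'   permutation tests).
#' @param n_permutations Permutations for the per-edition spectral-radius
#'   permutation test; `0` disables it.
#' @param variables Node variables (default [node_variables()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL, synthetic = NULL,
                            weight_mode = c("absolute", "signed"),
                            seed = 42L, n_permutations = 199L,
                            variables = node_variables()) {
  weight_mode <- match.arg(weight_mode)
  if (is.null(input_csv) && is.null(synthetic)) {
    synthetic <- synthetic_config(seed = seed)
  }
  structure(
    list(input_csv = input_csv, synthetic = synthetic,
         weight_mode = weight_mode, seed = as.integer(seed),
         n_permutations = as.integer(n_permutations), variables = variables),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: ingest (or synthesise) the cohort; split every edition's 8
#' finalists into medalists (ranks 1-3) and non-medalists (ranks 4-8); build
#' one weighted complete correlation network per group (2 per edition);
#' spectrally decompose each network; compare link weights per edition,
#' spectral radii across editions, and optionally run a per-edition
#' permutation test.  A default 5-edition run produces 10 networks, 60
#' nodes, and 300 directed weighted links.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`: per-edition networks and
#'   spectral summaries, structural counts, the SR table, all comparison
#'   results, the resolved configuration, and collected warnings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  cohort <- stage("ingest", withCallingHandlers({
    if (!is.null(config$input_csv)) {
      read_cohort_csv(config$input_csv)
    } else {
      synthesize_cohorts(config$synthetic)
    }
  }, warning = note))
  editions <- unique(cohort$edition)
  per_edition <- stage("networks", withCallingHandlers({
    lapply(editions, function(ed) {
      groups <- split_by_medal(cohort[cohort$edition == ed, , drop = FALSE])
      networks <- lapply(groups, function(g) {
        build_network(select_node_variables(g, config$variables),
                      mode = config$weight_mode,
                      edition_label = g$edition_label,
                      group_label = g$group_label)
      })
      summaries <- lapply(networks, eigen_system)
      list(edition = ed, groups = groups, networks = networks,
           summaries = summaries)
    })
  }, warning = note))
  all_networks <- unlist(lapply(per_edition, `[[`, "networks"), recursive = FALSE)
  all_summaries <- unlist(lapply(per_edition, `[[`, "summaries"), recursive = FALSE)
  for (net in all_networks) {
    if (nrow(net$degenerate_pairs)) {
      warnings_log <- c(warnings_log, sprintf(
        "%s/%s: %d degenerate (zero-variance) pair(s) kept as weight-0 links",
        net$edition_label, net$group_label, nrow(net$degenerate_pairs)))
    }
  }
  sr_table <- data.frame(
    edition = vapply(all_summaries, `[[`, character(1), "edition_label"),
    group = vapply(all_summaries, `[[`, character(1), "group_label"),
    spectral_radius = vapply(all_summaries, `[[`, numeric(1), "spectral_radius"),
    mean_node_eigen_score = vapply(all_summaries, `[[`, numeric(1),
                                   "mean_node_eigen_score"),
    stringsAsFactors = FALSE
  )
  comparisons <- stage("comparisons", withCallingHandlers({
    out <- list()
    for (pe in per_edition) {
      out[[paste0("link_weights_", pe$edition)]] <-
        compare_link_weights(pe$networks$medalist, pe$networks$non_medalist)
    }
    if (length(per_edition) >= 2L) {
      out$spectral_radius <- compare_spectral_radii(all_summaries)
    }
    if (config$n_permutations > 0L) {
      for (i in seq_along(per_edition)) {
        pe <- per_edition[[i]]
        out[[paste0("permutation_", pe$edition)]] <- permutation_group_test(
          pe$groups$medalist$records, pe$groups$non_medalist$records,
          n_permutations = config$n_permutations,
          seed = derive_seed(config$seed, 1000L + i),
          variables = config$variables, mode = config$weight_mode)
      }
    }
    out
  }, warning = note))
  p <- length(config$variables)
  structure(
    list(editions = per_edition,
         network_count = length(all_networks),
         node_count_total = p * length(all_networks),
         directed_link_count_total = p * (p - 1L) * length(all_networks),
         sr_table = sr_table,
         comparisons = comparisons,
         config_echo = config,
         warnings = warnings_log),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d networks, %d nodes, %d directed links\n",
              x$network_count, x$node_count_total, x$directed_link_count_total))
  print(transform(x$sr_table,
                  spectral_radius = round(spectral_radius, 4),
                  mean_node_eigen_score = round(mean_node_eigen_score, 4)))
  if (!is.null(x$comparisons$spectral_radius)) print(x$comparisons$spectral_radius)
  if (length(x$warnings)) {
    cat("warnings:\n"); cat(paste(" -", x$warnings), sep = "\n")
  }
  invisible(x)
}

comparison_to_list <- function(cmp) {
  if (inherits(cmp, "permutation_test")) {
    return(list(kind = "permutation", p = cmp$p, observed = cmp$observed,
                n_permutations = cmp$n_permutations, seed = cmp$seed))
  }
  list(kind = cmp$comparison_kind,
       group_summaries = cmp$group_summaries,
       anova_f = cmp$anova_f, anova_p = cmp$anova_p,
       tukey = cmp$tukey_pairs, direction = cmp$direction,
       edition_ordering = cmp$edition_ordering)
}

#' Write all pipeline artifacts to a directory
#'
#' Writes `report.json`, `sr_table.csv`, `comparisons.json`, per-network
#' edge lists (CSV and GraphML), connection matrices (CSV), node-score CSVs
#' and `log.txt`.  On error, partial outputs are removed.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths (the manifest).
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (report$network_count == 0L) stop("report contains no networks")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  add <- function(path) { written <<- c(written, path); path }
  tryCatch({
    cfg <- report$config_echo
    report_json <- list(
      network_count = report$network_count,
      node_count_total = report$node_count_total,
      directed_link_count_total = report$directed_link_count_total,
      sr_table = report$sr_table,
      config = list(
        input_csv = cfg$input_csv, weight_mode = cfg$weight_mode,
        seed = cfg$seed, n_permutations = cfg$n_permutations,
        variables = cfg$variables,
        synthetic_seed = if (!is.null(cfg$synthetic)) cfg$synthetic$seed,
        medalist_loading = if (!is.null(cfg$synthetic)) cfg$synthetic$medalist_loading,
        non_medalist_loading = if (!is.null(cfg$synthetic)) cfg$synthetic$non_medalist_loading
      ),
      warnings = report$warnings
    )
    jsonlite::write_json(report_json, add(file.path(out_dir, "report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(report$sr_table, add(file.path(out_dir, "sr_table.csv")),
                     row.names = FALSE)
    jsonlite::write_json(lapply(report$comparisons, comparison_to_list),
                         add(file.path(out_dir, "comparisons.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (pe in report$editions) {
      for (net in pe$networks) {
        tag <- paste(gsub("[^A-Za-z0-9]", "_", net$edition_label),
                     net$group_label, sep = "_")
        utils::write.csv(edge_list(net),
                         add(file.path(out_dir, paste0("edges_", tag, ".csv"))),
                         row.names = FALSE)
        write_graphml(net, add(file.path(out_dir, paste0("network_", tag, ".graphml"))))
        utils::write.csv(as.data.frame(net$weights),
                         add(file.path(out_dir, paste0("matrix_", tag, ".csv"))))
      }
      for (s in pe$summaries) {
        tag <- paste(gsub("[^A-Za-z0-9]", "_", s$edition_label),
                     s$group_label, sep = "_")
        export_spectral_summary(
          s, csv_path = add(file.path(out_dir, paste0("nodes_", tag, ".csv"))))
      }
    }
    log_lines <- c(
      sprintf("specnet pipeline run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("networks: %d, nodes: %d, directed links: %d",
              report$network_count, report$node_count_total,
              report$directed_link_count_total),
      if (length(report$warnings)) paste("WARNING:", report$warnings)
    )
    writeLines(log_lines, add(file.path(out_dir, "log.txt")))
    written
  }, error = function(e) {
    unlink(written)
    stop(sprintf("[stage: write_report] %s", conditionMessage(e)), call. = FALSE)
  })
}
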