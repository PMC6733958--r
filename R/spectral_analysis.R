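# Spectral decomposition of correlation networks.  The headline statistic is
# the spectral radius (SR): the largest eigenvalue of the symmetric weighted
# connection matrix C.  For non-negative C, Perron-Frobenius theory applies:
# SR is real, dominates every eigenvalue in magnitude, comes with a
# non-negative eigenvector (the Perron vector), is simple when the network is
# irreducible, and never increases when edges are removed.

#' Full spectral decomposition of a network
#'
#' Computes the eigenvalue spectrum of the connection matrix (descending),
#' the spectral radius, the principal eigenvector oriented non-negative and
#' normalised to unit Euclidean length, per-node eigen scores, weighted
#' degrees (row sums), and Perron-Frobenius diagnostics (irreducibility and
#' spectral gap).
#'
#' The per-node eigen score of node `i` is defined as
#' `SR * v_i / max_j(v_j)` where `v` is the principal eigenvector: an
#' eigenvector-centrality score rescaled so the most central node scores
#' exactly the spectral radius.  In signed mode the decomposition is still
#' computed but Perron-specific guarantees do not hold and a warning is
#' emitted.
#'
#' @param network A `correlation_network`, or a plain symmetric numeric
#'   matrix with zero diagonal.
#' @return An object of class `spectral_summary` with fields `eigenvalues`,
#'   `spectral_radius`, `spectral_gap`, `principal_eigenvector`,
#'   `node_eigen_scores`, `mean_node_eigen_score`, `weighted_degrees`,
#'   `irreducible`, `weight_mode`, `node_labels`, `edition_label`,
#'   `group_label`.
#' @export
eigen_system <- function(network) {
  if (inherits(network, "correlation_network")) {
    w <- network$weights
    mode <- network$weight_mode
    edition <- network$edition_label
    group <- network$group_label
  } else if (is.matrix(network) && is.numeric(network)) {
    w <- network
    mode <- NULL                          # classified after validation
    edition <- group <- NA_character_
  } else {
    stop("expected a correlation_network or a numeric matrix")
  }
  if (anyNA(w) || any(!is.finite(w))) stop("connection matrix contains NA/NaN/Inf")
  if (nrow(w) != ncol(w) || max(abs(w - t(w))) > 1e-12) {
    stop("connection matrix must be symmetric")
  }
  if (is.null(mode)) mode <- if (all(w >= 0)) "absolute" else "signed"
  if (mode == "signed") {
    warning("signed weight mode: Perron-Frobenius guarantees (non-negative ",
            "principal eigenvector, |theta| <= SR) do not apply", call. = FALSE)
  }
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(w)))
  e <- eigen(w, symmetric = TRUE)
  values <- e$values                      # already descending
  sr <- values[1]
  v <- e$vectors[, 1]
  # Orient the principal eigenvector so its largest-magnitude entry is
  # positive; for non-negative irreducible matrices this is the Perron vector.
  if (v[which.max(abs(v))] < 0) v <- -v
  names(v) <- labels
  vmax <- max(v)
  scores <- if (vmax > 0) sr * v / vmax else stats::setNames(rep(0, length(v)), labels)
  summary <- structure(
    list(edition_label = edition, group_label = group, node_labels = labels,
         eigenvalues = values, spectral_radius = sr,
         spectral_gap = sr - values[2],
         principal_eigenvector = v,
         node_eigen_scores = scores,
         mean_node_eigen_score = mean(scores),
         weighted_degrees = stats::setNames(rowSums(w), labels),
         irreducible = is_irreducible(w),
         weight_mode = mode),
    class = "spectral_summary"
  )
  summary
}

# Strong connectivity of the support graph (symmetric => connectivity),
# checked by breadth-first search over nonzero weights.
is_irreducible <- function(w) {
  p <- nrow(w)
  if (p == 1L) return(TRUE)
  seen <- logical(p)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(w[i, ] != 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %s / %s\n", x$edition_label, x$group_label))
  cat(sprintf("  spectral radius: %.4f (gap %.4f, %sirreducible)\n",
              x$spectral_radius, x$spectral_gap,
              if (x$irreducible) "" else "NOT "))
  cat("  eigenvalues:", paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  cat("  node eigen scores:\n")
  print(round(sort(x$node_eigen_scores, decreasing = TRUE), 4))
  invisible(x)
}

#' Spectral radius of a network
#'
#' Convenience accessor: the largest eigenvalue of the weighted connection
#' matrix, identical to `eigen_system(x)$spectral_radius`.
#'
#' @param x A `correlation_network`, `spectral_summary`, or symmetric matrix.
#' @return The spectral radius (a real number; 0 for an empty network).
#' @export
spectral_radius <- function(x) {
  if (inherits(x, "spectral_summary")) return(x$spectral_radius)
  eigen_system(x)$spectral_radius
}

#' Per-node eigen scores with ranking
#'
#' Returns the eigenvector-centrality scores of [eigen_system()] as a ranked
#' table: score `i` is `SR * v_i / max(v)` so the top node scores exactly the
#' spectral radius.  Ranking is descending, ties broken stably by node-label
#' order.
#'
#' @param summary A `spectral_summary` (or anything [eigen_system()] accepts).
#' @return Data frame with columns `node`, `score`, `rank`.
#' @export
node_eigen_scores <- function(summary) {
  if (!inherits(summary, "spectral_summary")) summary <- eigen_system(summary)
  s <- summary$node_eigen_scores
  ord <- order(-s, seq_along(s))         # stable tie-break by label position
  data.frame(node = names(s)[ord], score = unname(s[ord]),
             rank = seq_along(s), stringsAsFactors = FALSE)
}

#' Serialise a spectral summary
#'
#' @param summary A `spectral_summary`.
#' @param json_path,csv_path Optional output paths: JSON for the full
#'   summary, CSV for one row per node (score, degree, Perron component).
#' @return The summary as a plain list, invisibly if written to file.
#' @export
export_spectral_summary <- function(summary, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(summary, "spectral_summary"))
  payload <- list(
    edition = summary$edition_label, group = summary$group_label,
    spectral_radius = summary$spectral_radius,
    spectral_gap = summary$spectral_gap,
    irreducible = summary$irreducible,
    weight_mode = summary$weight_mode,
    eigenvalues = summary$eigenvalues,
    mean_node_eigen_score = summary$mean_node_eigen_score,
    nodes = node_eigen_scores(summary)
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    tab <- node_eigen_scores(summary)
    tab$weighted_degree <- summary$weighted_degrees[tab$node]
    tab$perron_component <- summary$principal_eigenvector[tab$node]
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  if (is.null(json_path) && is.null(csv_path)) payload else invisible(payload)
}
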