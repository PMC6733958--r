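# Weighted complete correlation networks: each group's variable matrix is
# turned into a symmetric connection matrix C with zero diagonal, whose
# off-diagonal entries are (by default) absolute Pearson correlations.

#' Pearson product-moment correlation
#'
#' Plain Pearson r with the convention that a zero-variance input makes the
#' correlation *undefined* (`NA`), not an error — degenerate variables are a
#' legitimate feature of small athlete groups (e.g. a group where nobody holds
#' an Olympic medal).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return r in \[-1, 1\], or `NA_real_` when either vector is constant.
#' @export
pearson_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric vectors")
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2L) stop("correlation needs at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Link weight from a correlation
#'
#' Converts a Pearson r into a link weight.  In `absolute` mode (the default)
#' the weight is `|r|`, keeping the connection matrix non-negative so
#' Perron-Frobenius guarantees hold for the spectral radius; in `signed` mode
#' the raw r is used.  An undefined correlation maps to weight 0 (the link
#' exists with zero weight and the pair is recorded as degenerate).  Weights
#' are fractions of 1; reports render them as percentages (`100 * weight`),
#' so r = 0.56 becomes a link of weight 0.56 shown as 56%.
#'
#' @param r Correlation value(s) in \[-1, 1\], possibly `NA`.
#' @param mode `"absolute"` or `"signed"`.
#' @return Numeric weight(s); `[0, 1]` in absolute mode, `[-1, 1]` in signed.
#' @export
link_weight <- function(r, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  w <- if (mode == "absolute") abs(r) else r
  w[is.na(w)] <- 0
  w
}

#' Build a weighted complete correlation network
#'
#' Computes all `p(p-1)/2` pairwise Pearson correlations between the columns
#' of a variable matrix and stores them as a symmetric connection matrix with
#' zero diagonal.  Every pair gets a link — correlations are never thresholded
#' or discarded, so all networks over the same variables share one complete
#' topology.  Links are bidirectional; the directed link count is `p(p-1)`.
#'
#' @param x Either a numeric matrix (athletes in rows, variables in columns)
#'   or a `group_table`, in which case its node variables are extracted.
#' @param node_labels Node names (default: column names of the matrix).
#' @param mode Weight mode, `"absolute"` (default) or `"signed"`; see
#'   [link_weight()].
#' @param edition_label,group_label Metadata carried into the result (filled
#'   from the `group_table` automatically).
#' @return An object of class `correlation_network` with fields
#'   `node_labels`, `weights` (symmetric, zero diagonal), `signed_weights`
#'   (raw r, degenerate entries 0), `weight_mode`, `degenerate_pairs`
#'   (2-column character matrix of pairs whose correlation was undefined),
#'   `edition_label`, `group_label`.
#' @export
build_network <- function(x, node_labels = NULL,
                          mode = c("absolute", "signed"),
                          edition_label = NA_character_,
                          group_label = NA_character_) {
  mode <- match.arg(mode)
  if (inherits(x, "group_table")) {
    edition_label <- x$edition_label
    group_label <- x$group_label
    x <- select_node_variables(x)
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 athletes are required to correlate variables")
  if (ncol(x) < 2L) stop("at least 2 variables are required to build a network")
  if (anyNA(x)) stop("variable matrix must not contain NA")
  if (is.null(node_labels)) node_labels <- colnames(x)
  if (is.null(node_labels)) node_labels <- paste0("V", seq_len(ncol(x)))
  if (length(node_labels) != ncol(x)) {
    stop("node_labels length must match the number of variables")
  }
  p <- ncol(x)
  signed <- matrix(0, p, p, dimnames = list(node_labels, node_labels))
  degenerate <- matrix(character(0), ncol = 2,
                       dimnames = list(NULL, c("node_a", "node_b")))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- pearson_correlation(x[, i], x[, j])
      if (is.na(r)) {
        degenerate <- rbind(degenerate, c(node_labels[i], node_labels[j]))
        r <- NA_real_
      }
      signed[i, j] <- signed[j, i] <- ifelse(is.na(r), 0, r)
    }
  }
  weights <- matrix(link_weight(signed, mode), p, p,
                    dimnames = dimnames(signed))
  diag(weights) <- 0
  structure(
    list(edition_label = edition_label, group_label = group_label,
         node_labels = node_labels, weights = weights,
         signed_weights = signed, weight_mode = mode,
         degenerate_pairs = degenerate),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %s / %s: %d nodes, %d undirected links (%s mode)\n",
              x$edition_label, x$group_label, length(x$node_labels),
              count_links(x, directed = FALSE), x$weight_mode))
  if (nrow(x$degenerate_pairs)) {
    cat("  degenerate pairs (weight 0):",
        paste(apply(x$degenerate_pairs, 1, paste, collapse = "-"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count the links of a network
#'
#' A complete p-node network has `p(p-1)/2` undirected links; since every
#' link is bidirectional the directed count is `p(p-1)`.  Degenerate-pair
#' links (undefined correlation, weight 0) still count; their number is
#' attached as the `degenerate_links` attribute.
#'
#' @param network A `correlation_network`.
#' @param directed Count each link in both directions? Default `TRUE`.
#' @return Integer link count with attribute `degenerate_links`.
#' @export
count_links <- function(network, directed = TRUE) {
  stopifnot(inherits(network, "correlation_network"))
  p <- length(network$node_labels)
  n <- if (directed) p * (p - 1L) else (p * (p - 1L)) %/% 2L
  structure(as.integer(n),
            degenerate_links = nrow(network$degenerate_pairs) *
              (if (directed) 2L else 1L))
}

#' Zero out one edge of a network
#'
#' Returns a copy of the network with the weight between two nodes set to 0
#' symmetrically (in both the weight and signed matrices).  This supports the
#' Perron-Frobenius monotonicity property: the spectral radius never
#' increases when an edge is removed.
#'
#' @param network A `correlation_network`.
#' @param node_a,node_b Node labels of the edge.
#' @return The modified `correlation_network`.
#' @export
remove_edge <- function(network, node_a, node_b) {
  stopifnot(inherits(network, "correlation_network"))
  labs <- network$node_labels
  if (!(node_a %in% labs) || !(node_b %in% labs)) {
    stop("unknown node label(s): ",
         paste(setdiff(c(node_a, node_b), labs), collapse = ", "))
  }
  if (node_a == node_b) stop("self-loops do not exist in this network")
  if (network$weights[node_a, node_b] == 0) {
    warning("edge ", node_a, "-", node_b, " already has zero weight")
  }
  network$weights[node_a, node_b] <- network$weights[node_b, node_a] <- 0
  network$signed_weights[node_a, node_b] <- network$signed_weights[node_b, node_a] <- 0
  network
}

#' Edge list of a network
#'
#' @param network A `correlation_network`.
#' @return Data frame with one row per unordered pair: `node_a`, `node_b`,
#'   `weight`, `signed_r`, `percent` (100 x weight).
#' @export
edge_list <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  labs <- network$node_labels
  idx <- which(upper.tri(network$weights), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    node_a = labs[idx[, 1]], node_b = labs[idx[, 2]],
    weight = network$weights[idx],
    signed_r = network$signed_weights[idx],
    percent = 100 * network$weights[idx],
    stringsAsFactors = FALSE
  )
}

#' Convert to an igraph object
#'
#' @param network A `correlation_network`.
#' @return An undirected weighted `igraph` graph (zero-weight links omitted
#'   by the adjacency representation).
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write a network to GraphML
#'
#' @param network A `correlation_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

# Upper-triangle weights in a stable order; the unit of link-weight ANOVA.
upper_weights <- function(network) {
  network$weights[upper.tri(network$weights)]
}
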