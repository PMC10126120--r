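#' Build a correlation-threshold network for one debridement interval
#'
#' Dynamic network analysis (DyNA) draws an undirected edge between two
#' mediators when their trajectories across the interval move together:
#' the Pearson correlation over the interval sample matrix satisfies
#' \code{r >= threshold} (a parallel edge) or \code{r <= -threshold}
#' (an antiparallel edge). The comparison is inclusive at the threshold.
#' Correlations are computed pairwise-complete; a pair is only tested when
#' at least 3 complete sample pairs exist, and mediators with zero variance
#' in the interval are kept as nodes but yield no edges.
#'
#' @param x A \code{cohort_table}.
#' @param group Patient group.
#' @param compartments One compartment for a single-compartment network, or
#'   both for cross-compartment mode (nodes then carry \code{"s"}/\code{"e"}
#'   prefixes).
#' @param interval Consecutive debridement pair, e.g. \code{"n4-n5"}.
#' @param threshold Correlation stringency in (0, 1]; default 0.95.
#' @param method Sample construction passed to [interval_matrix()].
#' @return An object of class \code{interval_network}: list with
#'   \code{interval}, \code{nodes}, \code{edges} (data.frame: node_a,
#'   node_b, sign, r), \code{threshold}, \code{method}, \code{n_samples}.
#' @export
build_network <- function(x, group, compartments = "serum", interval,
                          threshold = 0.95, method = c("stacked", "delta")) {
  method <- match.arg(method)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  m <- interval_matrix(x, group = group, compartments = compartments,
                       interval = interval, method = method)
  new_interval_network(m, threshold = threshold, method = method)
}

# Core edge rule on a mediator-by-sample matrix; exposed via build_network.
new_interval_network <- function(m, threshold, method) {
  nodes <- rownames(m)
  tm <- t(m)
  present <- !is.na(tm)
  n_pair <- crossprod(present)                  # pairwise complete counts
  suppressWarnings(C <- stats::cor(tm, use = "pairwise.complete.obs"))

  idx <- which(upper.tri(C) & !is.na(C) & n_pair >= 3L &
                 abs(C) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_a = nodes[idx[, 1L]],
    node_b = nodes[idx[, 2L]],
    sign = c("antiparallel", "parallel")[(C[idx] > 0) + 1L],
    r = C[idx],
    stringsAsFactors = FALSE)

  structure(list(interval = attr(m, "interval"),
                 nodes = nodes,
                 edges = edges,
                 threshold = threshold,
                 method = method,
                 n_samples = ncol(m)),
            class = "interval_network")
}

#' @export
print.interval_network <- function(x, ...) {
  cat("Interval network", x$interval, "(threshold", x$threshold,
      ",", x$method, "):", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Per-mediator connection counts of an interval network
#'
#' @param network An \code{interval_network}.
#' @return Named integer vector: number of edges incident to each node,
#'   in node order.
#' @export
degree_profile <- function(network) {
  stopifnot(inherits(network, "interval_network"))
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$node_a, network$edges$node_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Network complexity of an interval network
#'
#' The complexity score is the sum of per-mediator connection counts divided
#' by (number of mediators - 1): \eqn{(N_1 + N_2 + \dots + N_n) / (n - 1)}.
#' It equals \eqn{2|E|/(n-1)} and reaches \eqn{n} for the complete graph.
#'
#' @param network An \code{interval_network}.
#' @return Non-negative numeric score.
#' @export
network_complexity <- function(network) {
  deg <- degree_profile(network)
  n <- length(deg)
  if (n < 2L) stop("network complexity requires at least 2 mediators")
  sum(deg) / (n - 1)
}

#' Shannon entropy of a network's connection-probability distribution
#'
#' In \code{"paper"} mode each mediator's connection probability is its
#' connection count divided by the number of possible connections for that
#' mediator (\eqn{n - 1} nodes it could attach to), and
#' \eqn{H = -\sum p_i \log_2 p_i} over mediators with at least one
#' connection. In \code{"normalized"} mode the counts are normalized to a
#' probability distribution (\eqn{q_i = N_i / \sum_j N_j}), so \eqn{H} is
#' bounded by \eqn{\log_2 n}. An empty network has entropy 0 by convention.
#'
#' @param network An \code{interval_network}.
#' @param mode \code{"paper"} (default) or \code{"normalized"}.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(network, mode = c("paper", "normalized")) {
  mode <- match.arg(mode)
  deg <- degree_profile(network)
  if (sum(deg) == 0L) return(0)
  p <- if (mode == "paper") deg / (length(deg) - 1L) else deg / sum(deg)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Connection-count matrix across interval networks
#'
#' Assembles per-mediator connection counts over a series of interval
#' networks into a mediator-by-interval matrix (the data behind a
#' connections-per-mediator heatmap).
#'
#' @param networks List of \code{interval_network}s sharing one node set.
#' @return Integer matrix, rows = mediators, columns = interval labels.
#' @export
degree_heatmap <- function(networks) {
  stopifnot(length(networks) >= 1L)
  nodes <- networks[[1L]]$nodes
  for (net in networks) {
    if (!identical(net$nodes, nodes)) {
      stop("networks must share a common node set")
    }
  }
  out <- vapply(networks, degree_profile, integer(length(nodes)))
  colnames(out) <- vapply(networks, function(net) net$interval, character(1L))
  out
}

#' Run DyNA over all consecutive intervals
#'
#' @param x A \code{cohort_table}.
#' @param group Patient group.
#' @param compartments Compartment selection, as in [build_network()].
#' @param threshold Correlation stringency.
#' @param method Sample construction.
#' @return Named list of \code{interval_network}s, one per interval
#'   (intervals without sufficient data are dropped with a warning).
#' @export
dyna_networks <- function(x, group, compartments = "serum",
                          threshold = 0.95, method = "stacked") {
  nets <- list()
  for (lab in interval_labels(attr(x, "n_debridements"))) {
    net <- tryCatch(
      build_network(x, group = group, compartments = compartments,
                    interval = lab, threshold = threshold, method = method),
      error = function(e) {
        warning("interval ", lab, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(net)) nets[[lab]] <- net
  }
  nets
}
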