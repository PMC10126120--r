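#' Window labels for dynamic-hypergraph analysis
#'
#' @param n_debridements Number of debridements.
#' @return Sliding three-debridement windows, e.g. \code{"n1-n3"},
#'   \code{"n2-n4"}, \code{"n3-n5"}.
#' @export
window_labels <- function(n_debridements = 5L) {
  k <- seq_len(n_debridements - 2L)
  sprintf("n%d-n%d", k, k + 2L)
}

#' Correlation of a mediator's group-mean level with time over one window
#'
#' For one mediator in one compartment of one group, computes the
#' per-debridement group center (mean by default) at the window's three
#' consecutive debridements and correlates it with time coded as
#' \code{(0, 3, 6)} days (one debridement every ~3 days). The trend passes
#' when \code{|r|} strictly exceeds the threshold; its sign classifies the
#' mediator as increasing or decreasing over the window.
#'
#' @param x A \code{cohort_table}.
#' @param group Patient group.
#' @param compartment Compartment.
#' @param mediator Panel mediator.
#' @param window Window label, e.g. \code{"n2-n4"}.
#' @param threshold Pass bound on \code{|r|} (strict; default 0.95).
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return An object of class \code{trend_edge}: list with \code{mediator},
#'   \code{compartment}, \code{group}, \code{window}, \code{centers},
#'   \code{r}, \code{sign} (\code{"increasing"}/\code{"decreasing"}/NA),
#'   \code{passes}, \code{degenerate}.
#' @export
trend_correlation <- function(x, group, compartment, mediator, window,
                              threshold = 0.95,
                              center = c("mean", "median")) {
  stopifnot(inherits(x, "cohort_table"))
  center <- match.arg(center)
  ds <- parse_window(window)
  if (max(ds) > attr(x, "n_debridements")) {
    stop("window ", window, " outside design range")
  }
  if (!mediator %in% attr(x, "panel")$names) {
    stop("unknown mediator: ", mediator)
  }
  cfun <- if (center == "mean") mean else stats::median
  centers <- vapply(ds, function(d) {
    v <- x$value[x$group == group & x$compartment == compartment &
                   x$mediator == mediator & x$debridement == d &
                   !is.na(x$value)]
    if (!length(v)) {
      stop("insufficient data: no ", compartment, " observations of ",
           mediator, " for ", group, " at debridement n", d)
    }
    cfun(v)
  }, numeric(1L))

  times <- c(0, 3, 6)
  # relative tolerance: centers equal to machine precision carry no trend
  degenerate <- stats::sd(centers) <= 1e-10 * mean(abs(centers))
  r <- if (degenerate) NA_real_ else stats::cor(centers, times)
  new_trend_edge(mediator, compartment, group, window, centers, r,
                 threshold, degenerate)
}

new_trend_edge <- function(mediator, compartment, group, window, centers,
                           r, threshold, degenerate) {
  structure(list(
    mediator = mediator, compartment = compartment, group = group,
    window = window, centers = centers, r = r,
    sign = if (degenerate || is.na(r)) NA_character_ else {
      if (r > 0) "increasing" else "decreasing"
    },
    passes = !degenerate && !is.na(r) && abs(r) > threshold,
    degenerate = degenerate,
    threshold = threshold), class = "trend_edge")
}

#' @export
print.trend_edge <- function(x, ...) {
  cat(sprintf("Trend %s [%s, %s, %s]: r = %s, %s\n",
              x$mediator, x$compartment, x$group, x$window,
              if (is.na(x$r)) "NA (degenerate)" else format(x$r, digits = 4),
              if (x$passes) paste0("passes (", x$sign, ")") else "fails"))
  invisible(x)
}

#' All per-mediator trend correlations for one group and window
#'
#' @inheritParams trend_correlation
#' @param compartments Compartments to scan (default both).
#' @return data.frame with one row per (mediator, compartment): columns
#'   \code{mediator}, \code{compartment}, \code{group}, \code{window},
#'   \code{r}, \code{sign}, \code{passes}, \code{degenerate}. Mediators with
#'   an empty debridement cell are dropped with a warning.
#' @export
trend_edges <- function(x, group, window, compartments = COMPARTMENTS,
                        threshold = 0.95, center = "mean") {
  panel <- attr(x, "panel")
  rows <- list()
  for (cc in compartments) {
    for (med in panel$names) {
      te <- tryCatch(
        trend_correlation(x, group = group, compartment = cc,
                          mediator = med, window = window,
                          threshold = threshold, center = center),
        error = function(e) {
          warning(conditionMessage(e)); NULL
        })
      if (!is.null(te)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mediator = te$mediator, compartment = te$compartment,
          group = te$group, window = te$window, r = te$r,
          sign = te$sign, passes = te$passes, degenerate = te$degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Assemble a dynamic hypergraph from trend correlations
#'
#' In a dynamic hypergraph the nodes are tissue compartments and the edges
#' are mediators: a mediator whose trend passes with the given sign in one
#' or more compartments becomes a hyperedge attached to exactly that
#' compartment subset. Mediators sharing a compartment subset share one
#' hyperedge labeled with all their names.
#'
#' @param edges data.frame from [trend_edges()] (or a list of
#'   \code{trend_edge} objects), all from one group and one window.
#' @param sign \code{"increasing"} or \code{"decreasing"}.
#' @param window Window label; supplying edges from a different window is an
#'   error.
#' @param compartments Node set (default both compartments).
#' @return An object of class \code{hypergraph}: list with \code{nodes},
#'   \code{window}, \code{sign} and \code{hyperedges} (named list keyed by
#'   compartment subset, e.g. \code{"serum+effluent"}, each holding
#'   \code{compartments}, \code{mediators} and a \code{weights} data.frame
#'   of per-compartment r values).
#' @export
build_hypergraph <- function(edges, sign = c("increasing", "decreasing"),
                             window, compartments = COMPARTMENTS) {
  sign <- match.arg(sign)
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(te) {
      data.frame(mediator = te$mediator, compartment = te$compartment,
                 group = te$group, window = te$window, r = te$r,
                 sign = te$sign, passes = te$passes,
                 degenerate = te$degenerate, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(mediator = character(), compartment = character(),
                        group = character(), window = character(),
                        r = numeric(), sign = character(),
                        passes = logical(), degenerate = logical(),
                        stringsAsFactors = FALSE)
  } else {
    if (length(unique(edges$window)) > 1L ||
        unique(edges$window) != window) {
      stop("trend edges from mixed or mismatched windows; expected ", window)
    }
    if (length(unique(edges$group)) > 1L) {
      stop("trend edges must come from a single group")
    }
  }

  pass <- edges[!is.na(edges$passes) & edges$passes & edges$sign == sign, ,
                drop = FALSE]
  hyperedges <- list()
  if (nrow(pass)) {
    for (med in unique(pass$mediator)) {
      sub <- pass[pass$mediator == med, , drop = FALSE]
      comps <- intersect(compartments, sub$compartment)  # canonical order
      key <- paste(comps, collapse = "+")
      if (is.null(hyperedges[[key]])) {
        hyperedges[[key]] <- list(compartments = comps,
                                  mediators = character(),
                                  weights = sub[0L, c("mediator",
                                                      "compartment", "r")])
      }
      hyperedges[[key]]$mediators <- c(hyperedges[[key]]$mediators, med)
      hyperedges[[key]]$weights <- rbind(
        hyperedges[[key]]$weights, sub[, c("mediator", "compartment", "r")])
    }
  }
  structure(list(nodes = compartments, window = window, sign = sign,
                 hyperedges = hyperedges), class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("Hypergraph [", x$window, ",", x$sign, "]:",
      length(x$hyperedges), "hyperedge set(s)\n")
  for (key in names(x$hyperedges)) {
    cat("  {", key, "}: ",
        paste(x$hyperedges[[key]]$mediators, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# canonical compartment-subset keys for a node set
subset_keys <- function(nodes) {
  ks <- character()
  for (size in seq_along(nodes)) {
    cmb <- utils::combn(nodes, size, simplify = FALSE)
    ks <- c(ks, vapply(cmb, paste, character(1L), collapse = "+"))
  }
  ks
}

#' Edge distribution of a set of dynamic hypergraphs
#'
#' Counts, for every (window, compartment subset, sign), the number of
#' mediators whose hyperedge attaches to exactly that subset. The evolution
#' of these counts across windows traces spatial shifts of inflammation
#' between compartments.
#'
#' @param hypergraphs List of \code{hypergraph} objects (typically the three
#'   windows of one group and sign, but mixed signs are tabulated too).
#' @return An object of class \code{edge_distribution}: data.frame with
#'   columns \code{window}, \code{subset}, \code{sign}, \code{count},
#'   including explicit zero rows for empty subsets.
#' @export
edge_distribution <- function(hypergraphs) {
  if (inherits(hypergraphs, "hypergraph")) hypergraphs <- list(hypergraphs)
  stopifnot(length(hypergraphs) >= 1L)
  nodes <- hypergraphs[[1L]]$nodes
  windows <- unique(vapply(hypergraphs, `[[`, character(1L), "window"))
  signs <- unique(vapply(hypergraphs, `[[`, character(1L), "sign"))
  grid <- expand.grid(window = windows, subset = subset_keys(nodes),
                      sign = signs, stringsAsFactors = FALSE)
  grid$count <- 0L
  for (hg in hypergraphs) {
    for (key in names(hg$hyperedges)) {
      sel <- grid$window == hg$window & grid$subset == key &
        grid$sign == hg$sign
      grid$count[sel] <- grid$count[sel] +
        length(hg$hyperedges[[key]]$mediators)
    }
  }
  structure(grid, class = c("edge_distribution", "data.frame"))
}

#' Exact test of independence for an r x c contingency table
#'
#' Conditional exact test with both margins fixed: every non-negative
#' integer table with the observed margins is enumerated, weighted by its
#' multivariate hypergeometric probability, and the two-sided p-value is the
#' total probability of tables no more probable than the observed one.
#' Above the enumeration budget a fixed-seed Monte Carlo estimate over
#' margin-conditioned random tables is returned instead.
#'
#' @param tab Integer matrix of counts.
#' @param max_tables Enumeration budget before falling back to Monte Carlo.
#' @param mc_B Monte Carlo replicates for the fallback.
#' @param mc_seed Seed for the fallback.
#' @return List with \code{p}, \code{table}, \code{method}
#'   (\code{"enumeration"} or \code{"monte-carlo"}) and \code{n_tables}
#'   (tables enumerated, or replicates used).
#' @export
fisher_exact <- function(tab, max_tables = 2e5, mc_B = 1e5, mc_seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  if (sum(tab) == 0) stop("undefined test: all-zero table")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    # margins force a unique table: no evidence against independence
    return(list(p = 1, table = tab, method = "enumeration", n_tables = 1L))
  }

  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  lp_of <- function(m) log_const - sum(lgamma(m + 1))
  lp_obs <- lp_of(tab)
  tol <- 1e-7

  nr <- nrow(tab); nc <- ncol(tab)
  env <- new.env(parent = emptyenv())
  env$p <- 0; env$n <- 0L; env$overflow <- FALSE
  cur <- matrix(0L, nr, nc)

  # fill rows 1..(nr-1); the last row is forced by the column margins
  recurse_row <- function(ri, col_left) {
    if (env$overflow) return()
    if (ri == nr) {
      cur[nr, ] <<- col_left
      env$n <- env$n + 1L
      if (env$n > max_tables) { env$overflow <- TRUE; return() }
      lp <- lp_of(cur)
      if (lp <= lp_obs + tol) env$p <- env$p + exp(lp)
      return()
    }
    fill_cell <- function(ci, left_in_row, col_left) {
      if (env$overflow) return()
      if (ci == nc) {
        if (left_in_row > col_left[nc]) return()
        cur[ri, nc] <<- left_in_row
        col_left[nc] <- col_left[nc] - left_in_row
        recurse_row(ri + 1L, col_left)
        return()
      }
      lo <- max(0L, left_in_row - sum(col_left[(ci + 1L):nc]))
      hi <- min(left_in_row, col_left[ci])
      if (lo > hi) return()
      for (v in lo:hi) {
        cur[ri, ci] <<- v
        cl <- col_left
        cl[ci] <- cl[ci] - v
        fill_cell(ci + 1L, left_in_row - v, cl)
      }
    }
    fill_cell(1L, rs[ri], col_left)
  }
  recurse_row(1L, cs)

  if (!env$overflow) {
    return(list(p = min(env$p, 1), table = tab, method = "enumeration",
                n_tables = env$n))
  }

  # Monte Carlo fallback, margins fixed, deterministic given mc_seed
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(mc_seed)
  sims <- stats::r2dtable(mc_B, rs, cs)
  lps <- vapply(sims, lp_of, numeric(1L))
  p <- (1 + sum(lps <= lp_obs + tol)) / (mc_B + 1)
  list(p = p, table = tab, method = "monte-carlo", n_tables = mc_B)
}

#' Compare two edge distributions with Fisher's exact test
#'
#' Tests whether hyperedge counts for one compartment subset are
#' homogeneously distributed across windows between two groups: the counts
#' form a (group x window) table that is passed to [fisher_exact()]. A large
#' p-value indicates the subset's edge distribution is independent of the
#' dynamic interval.
#'
#' @param dist_a,dist_b \code{edge_distribution} objects for the two groups.
#' @param subset Compartment subset key, e.g. \code{"serum"} or
#'   \code{"serum+effluent"}.
#' @param sign Trend sign to compare (default \code{"increasing"}, the
#'   positive edge distribution).
#' @return The [fisher_exact()] result, with the labeled table attached.
#' @export
compare_distributions <- function(dist_a, dist_b, subset,
                                  sign = "increasing") {
  pick <- function(d) {
    d <- d[d$subset == subset & d$sign == sign, , drop = FALSE]
    if (!nrow(d)) stop("subset '", subset, "' with sign '", sign,
                       "' not present in distribution")
    stats::setNames(d$count, d$window)[order(d$window)]
  }
  a <- pick(dist_a); b <- pick(dist_b)
  if (!identical(names(a), names(b))) {
    stop("distributions cover different windows")
  }
  tab <- rbind(a, b)
  rownames(tab) <- c("group_a", "group_b")
  fisher_exact(tab)
}

#' Full dynamic-hypergraph analysis for one group
#'
#' Computes trend correlations for every mediator and compartment over all
#' sliding windows, assembles increasing and decreasing hypergraphs per
#' window, and tabulates the edge distribution.
#'
#' @param x A \code{cohort_table}.
#' @param group Patient group.
#' @param threshold Pass bound on \code{|r|}.
#' @param center Group center function.
#' @return List with \code{edges} (data.frame over all windows),
#'   \code{hypergraphs} (list indexed \code{window.sign}) and
#'   \code{distribution} (an \code{edge_distribution}).
#' @export
dyhyp_analysis <- function(x, group, threshold = 0.95, center = "mean") {
  windows <- window_labels(attr(x, "n_debridements"))
  all_edges <- list()
  hgs <- list()
  for (w in windows) {
    ed <- trend_edges(x, group = group, window = w, threshold = threshold,
                      center = center)
    all_edges[[w]] <- ed
    for (sg in c("increasing", "decreasing")) {
      hgs[[paste(w, sg, sep = ".")]] <- build_hypergraph(ed, sign = sg,
                                                         window = w)
    }
  }
  list(edges = do.call(rbind, all_edges),
       hypergraphs = hgs,
       distribution = edge_distribution(hgs))
}
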