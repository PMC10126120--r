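#' Export an interval network to GraphML or JSON
#'
#' Both formats are lossless for nodes, signed weighted edges and the
#' network metadata (interval, threshold, method, sample count), so an
#' exported network re-imports to an equal edge set.
#'
#' @param net An \code{interval_network}.
#' @param path Output file path.
#' @param format \code{"graphml"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "json")) {
  stopifnot(inherits(net, "interval_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
    if (nrow(net$edges)) {
      g <- igraph::add_edges(
        g, rbind(match(net$edges$node_a, net$nodes),
                 match(net$edges$node_b, net$nodes)),
        sign = net$edges$sign, weight = net$edges$r)
    }
    g <- igraph::set_graph_attr(g, "interval", net$interval)
    g <- igraph::set_graph_attr(g, "threshold", net$threshold)
    g <- igraph::set_graph_attr(g, "method", net$method)
    g <- igraph::set_graph_attr(g, "n_samples", net$n_samples)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    jsonlite::write_json(
      list(interval = net$interval, nodes = net$nodes,
           edges = net$edges, threshold = net$threshold,
           method = net$method, n_samples = net$n_samples),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Re-import a network written by [export_network()]
#'
#' @param path File path.
#' @param format \code{"graphml"} or \code{"json"}.
#' @return An \code{interval_network}.
#' @export
import_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    el <- igraph::as_edgelist(g)
    edges <- data.frame(
      node_a = as.character(el[, 1L]), node_b = as.character(el[, 2L]),
      sign = if (igraph::ecount(g)) igraph::E(g)$sign else character(),
      r = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(),
      stringsAsFactors = FALSE)
    structure(list(interval = igraph::graph_attr(g, "interval"),
                   nodes = nodes, edges = edges,
                   threshold = igraph::graph_attr(g, "threshold"),
                   method = igraph::graph_attr(g, "method"),
                   n_samples = as.integer(igraph::graph_attr(g,
                                                             "n_samples"))),
              class = "interval_network")
  } else {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- as.data.frame(js$edges, stringsAsFactors = FALSE)
    if (!nrow(edges)) {
      edges <- data.frame(node_a = character(), node_b = character(),
                          sign = character(), r = numeric(),
                          stringsAsFactors = FALSE)
    }
    structure(list(interval = js$interval, nodes = js$nodes, edges = edges,
                   threshold = js$threshold, method = js$method,
                   n_samples = as.integer(js$n_samples)),
              class = "interval_network")
  }
}

#' Export a hypergraph to JSON
#'
#' @param hg A \code{hypergraph}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_hypergraph <- function(hg, path) {
  stopifnot(inherits(hg, "hypergraph"))
  jsonlite::write_json(
    list(nodes = hg$nodes, window = hg$window, sign = hg$sign,
         hyperedges = lapply(hg$hyperedges, function(he) {
           list(compartments = he$compartments, mediators = he$mediators,
                weights = he$weights)
         })),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Drives every stage over a cohort (loaded from CSV or generated from a
#' simulation config) and writes plain CSV/JSON/GraphML artifacts plus a
#' manifest to the output directory. Re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config List with elements: \code{input} (a cohort CSV path, a
#'   \code{cohort_table}, or a \code{simulation_config}), \code{out_dir},
#'   \code{stages} (subset of \code{c("dyna", "dyhyp", "subsets",
#'   "screen")}), \code{dyna_threshold} (0.95), \code{dyhyp_threshold}
#'   (0.95), \code{alpha} (0.05), \code{method} (\code{"stacked"}),
#'   \code{B} (1000), \code{seed} (1).
#' @return Invisibly, a list of the in-memory stage results; artifacts and
#'   \code{manifest.json} are written under \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  defaults <- list(stages = c("dyna", "dyhyp", "subsets", "screen"),
                   dyna_threshold = 0.95, dyhyp_threshold = 0.95,
                   alpha = 0.05, method = "stacked", B = 1000L, seed = 1L)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  bad <- setdiff(config$stages, c("dyna", "dyhyp", "subsets", "screen"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (config$dyna_threshold <= 0 || config$dyna_threshold > 1 ||
      config$dyhyp_threshold <= 0 || config$dyhyp_threshold > 1) {
    stop("thresholds must lie in (0, 1]")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (inherits(config$input, "cohort_table")) {
    config$input
  } else if (inherits(config$input, "simulation_config")) {
    generate_cohort(config$input)
  } else if (is.character(config$input)) {
    load_cohort(config$input)
  } else stop("config$input must be a path, cohort_table or simulation_config")
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  results <- list(cohort = cohort)
  groups <- intersect(GROUPS, unique(cohort$group))

  if ("dyna" %in% config$stages) {
    nets <- list()
    scores <- list()
    for (grp in groups) {
      for (comp in COMPARTMENTS) {
        key <- paste(grp, comp, sep = ".")
        nets[[key]] <- dyna_networks(cohort, group = grp,
                                     compartments = comp,
                                     threshold = config$dyna_threshold,
                                     method = config$method)
        for (net in nets[[key]]) {
          tag <- paste(grp, comp, net$interval, sep = "_")
          export_network(net, file.path(config$out_dir,
                                        paste0("network_", tag, ".graphml")))
          scores[[tag]] <- data.frame(
            group = grp, compartment = comp, interval = net$interval,
            n_edges = nrow(net$edges),
            complexity = network_complexity(net),
            entropy = shannon_entropy(net),
            stringsAsFactors = FALSE)
        }
        if (length(nets[[key]])) {
          hm <- degree_heatmap(nets[[key]])
          utils::write.csv(hm, file.path(config$out_dir,
                                         paste0("degrees_", grp, "_", comp,
                                                ".csv")))
        }
      }
    }
    results$dyna <- nets
    results$dyna_scores <- do.call(rbind, unname(scores))
    utils::write.csv(results$dyna_scores,
                     file.path(config$out_dir, "dyna_scores.csv"),
                     row.names = FALSE)
  }

  if ("dyhyp" %in% config$stages) {
    dists <- list()
    for (grp in groups) {
      res <- dyhyp_analysis(cohort, group = grp,
                            threshold = config$dyhyp_threshold)
      dists[[grp]] <- res$distribution
      for (key in names(res$hypergraphs)) {
        export_hypergraph(res$hypergraphs[[key]],
                          file.path(config$out_dir,
                                    paste0("hypergraph_", grp, "_", key,
                                           ".json")))
      }
      utils::write.csv(res$distribution,
                       file.path(config$out_dir,
                                 paste0("edge_distribution_", grp, ".csv")),
                       row.names = FALSE)
    }
    results$dyhyp <- dists
    if (length(dists) == 2L) {
      fisher <- lapply(c(serum = "serum", effluent = "effluent"),
                       function(sub) {
        ft <- tryCatch(compare_distributions(dists[[1L]], dists[[2L]], sub),
                       error = function(e) NULL)
        if (is.null(ft)) NULL else list(p = ft$p, method = ft$method,
                                        table = ft$table)
      })
      results$dyhyp_fisher <- fisher
      jsonlite::write_json(fisher,
                           file.path(config$out_dir, "dyhyp_fisher.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  if ("subsets" %in% config$stages) {
    calls <- do.call(rbind, lapply(groups, function(grp) {
      do.call(rbind, lapply(COMPARTMENTS, function(comp) {
        sc <- tryCatch(infer_subsets(cohort, group = grp,
                                     compartment = comp, B = config$B,
                                     alpha = config$alpha,
                                     seed = config$seed),
                       error = function(e) NULL)
        if (is.null(sc)) return(NULL)
        cbind(data.frame(group = grp, compartment = comp,
                         stringsAsFactors = FALSE), sc)
      }))
    }))
    results$subsets <- calls
    utils::write.csv(calls, file.path(config$out_dir, "subset_calls.csv"),
                     row.names = FALSE)
  }

  if ("screen" %in% config$stages) {
    screen <- do.call(rbind, lapply(COMPARTMENTS, function(comp) {
      tryCatch(anova_screen(cohort, compartment = comp,
                            alpha = config$alpha),
               error = function(e) NULL)
    }))
    results$screen <- screen
    utils::write.csv(screen, file.path(config$out_dir, "anova_screen.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("inflamnet")),
    stages = config$stages,
    dyna_threshold = config$dyna_threshold,
    dyhyp_threshold = config$dyhyp_threshold,
    alpha = config$alpha, method = config$method,
    B = config$B, seed = config$seed,
    input = if (is.character(config$input)) config$input else
      if (inherits(config$input, "simulation_config"))
        paste0("simulation_config(seed=", config$input$seed, ")") else
        "cohort_table (in memory)",
    n_patients = length(unique(cohort$patient_id)),
    n_observations = nrow(cohort))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
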