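# single-patient cohort whose per-debridement means are prescribed exactly
centers_cohort <- function(centers, mediator = "A", group = "TBI",
                           compartment = "serum", panel = small_panel(1L)) {
  rows <- do.call(rbind, lapply(seq_along(centers), function(d) {
    obs_row("P01", group, compartment, d, mediator, centers[d])
  }))
  cohort_table(rows, panel = panel)
}

test_that("trend gate: exact linearity passes, curvature fails, flat is degenerate", {
  tr <- trend_correlation(centers_cohort(c(10, 20, 30)), "TBI", "serum",
                          "A", "n1-n3")
  expect_equal(tr$r, 1)
  expect_equal(tr$sign, "increasing")
  expect_true(tr$passes)

  tr_dec <- trend_correlation(centers_cohort(c(30, 20, 10)), "TBI", "serum",
                              "A", "n1-n3")
  expect_equal(tr_dec$r, -1)
  expect_equal(tr_dec$sign, "decreasing")
  expect_true(tr_dec$passes)

  flat <- trend_correlation(centers_cohort(c(7, 7, 7)), "TBI", "serum",
                            "A", "n1-n3")
  expect_true(flat$degenerate)
  expect_false(flat$passes)

  # worked triple (5, 6, 20) against times (0, 3, 6)
  bent <- trend_correlation(centers_cohort(c(5, 6, 20)), "TBI", "serum",
                            "A", "n1-n3")
  expect_equal(bent$r, 45 / (sqrt(18) * sqrt(1266 / 9)))
  expect_equal(bent$r, pearson_brute(c(5, 6, 20), c(0, 3, 6)))
  expect_lt(bent$r, 0.95)
  expect_false(bent$passes)

  # the pass rule is strict: |r| exactly at the threshold fails
  expect_false(trend_correlation(centers_cohort(c(5, 6, 20)), "TBI",
                                 "serum", "A", "n1-n3",
                                 threshold = bent$r)$passes)

  expect_error(trend_correlation(centers_cohort(c(10, 20)), "TBI", "serum",
                                 "A", "n1-n3"), "insufficient data")
})

test_that("the group center uses the mean and honors the median option", {
  rows <- rbind(
    obs_row(c("P1", "P2", "P3"), "TBI", "serum", 1L, "A", c(1, 2, 9)),
    obs_row(c("P1", "P2", "P3"), "TBI", "serum", 2L, "A", c(2, 4, 12)),
    obs_row(c("P1", "P2", "P3"), "TBI", "serum", 3L, "A", c(3, 6, 15)))
  co <- cohort_table(rows, panel = small_panel(1L))
  tr_mean <- trend_correlation(co, "TBI", "serum", "A", "n1-n3")
  expect_equal(tr_mean$centers, c(4, 6, 8))
  tr_med <- trend_correlation(co, "TBI", "serum", "A", "n1-n3",
                              center = "median")
  expect_equal(tr_med$centers, c(2, 4, 6))
})

test_that("hypergraph assembly groups mediators by compartment subset", {
  edges <- rbind(
    data.frame(mediator = "TNF-a", compartment = c("serum", "effluent"),
               group = "TBI", window = "n2-n4", r = c(0.99, 0.98),
               sign = "increasing", passes = TRUE, degenerate = FALSE),
    data.frame(mediator = c("IL-6", "IL-8"), compartment = "serum",
               group = "TBI", window = "n2-n4", r = c(0.97, 0.96),
               sign = "increasing", passes = TRUE, degenerate = FALSE),
    data.frame(mediator = "IFN-g", compartment = "serum", group = "TBI",
               window = "n2-n4", r = -0.99, sign = "decreasing",
               passes = TRUE, degenerate = FALSE),
    data.frame(mediator = "IL-10", compartment = "serum", group = "TBI",
               window = "n2-n4", r = 0.5, sign = "increasing",
               passes = FALSE, degenerate = FALSE))

  hg <- build_hypergraph(edges, "increasing", "n2-n4")
  expect_setequal(names(hg$hyperedges), c("serum+effluent", "serum"))
  expect_equal(hg$hyperedges[["serum+effluent"]]$mediators, "TNF-a")
  expect_setequal(hg$hyperedges[["serum"]]$mediators, c("IL-6", "IL-8"))

  # opposite-sign trends live in the other hypergraph
  hg_dec <- build_hypergraph(edges, "decreasing", "n2-n4")
  expect_equal(hg_dec$hyperedges[["serum"]]$mediators, "IFN-g")

  # mediators in exactly one subset per (window, sign)
  meds <- unlist(lapply(hg$hyperedges, `[[`, "mediators"))
  expect_equal(anyDuplicated(meds), 0L)

  expect_error(build_hypergraph(edges, "increasing", "n1-n3"),
               "mismatched windows")

  empty <- build_hypergraph(edges[edges$passes == FALSE, , drop = FALSE],
                            "increasing", "n2-n4")
  expect_equal(length(empty$hyperedges), 0L)
  expect_equal(empty$nodes, c("serum", "effluent"))
})

test_that("planted zero-noise trends are recovered as the exact edge distribution", {
  serum_up <- c("TNF-a", "IL-6", "IL-17A", "IL-8")
  effluent_up <- c("IL-1b", "MCP-1")
  planted <- data.frame(
    mediator = c(serum_up, effluent_up),
    compartment = rep(c("serum", "effluent"), c(4L, 2L)),
    group = "TBI", window = "n2-n4",
    slope = 30, noise_sd = 0)
  # noise-free construction: every other (mediator, compartment) is held
  # flat (slope 0), so only the planted trends can pass the gate
  grid <- expand.grid(mediator = default_panel()$names,
                      compartment = c("serum", "effluent"),
                      stringsAsFactors = FALSE)
  key <- paste(grid$mediator, grid$compartment)
  flat <- grid[!key %in% paste(planted$mediator, planted$compartment), ]
  flat <- data.frame(mediator = flat$mediator,
                     compartment = flat$compartment, group = "TBI",
                     window = "n2-n4", slope = 0, noise_sd = 0)
  cfg <- simulation_config(
    seed = 50, n_patients = c(TBI = 15L, nonTBI = 3L),
    planted_trends = rbind(planted, flat))
  co <- generate_cohort(cfg)
  ed <- trend_edges(co, "TBI", "n2-n4")
  hg <- build_hypergraph(ed, "increasing", "n2-n4")
  dist <- edge_distribution(hg)

  count_of <- function(sub) dist$count[dist$subset == sub &
                                         dist$sign == "increasing"]
  expect_equal(count_of("serum"), 4L)
  expect_equal(count_of("effluent"), 2L)
  expect_equal(count_of("serum+effluent"), 0L)
  expect_setequal(hg$hyperedges[["serum"]]$mediators, serum_up)
})

test_that("exact test reproduces closed-form and textbook cases", {
  expect_equal(fisher_exact(matrix(1, 2, 3))$p, 1)
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5)))$p, 1 / 126)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")

  # a zero row/column just drops out
  expect_equal(fisher_exact(rbind(c(3, 2), c(0, 0)))$p, 1)

  obs <- rbind(c(3, 2, 1), c(1, 2, 3))
  mine <- fisher_exact(obs)
  expect_equal(mine$method, "enumeration")
  expect_equal(mine$p, fisher_2x3_brute(obs))
  expect_equal(mine$p, stats::fisher.test(obs)$p.value)
})

test_that("Monte Carlo fallback engages above the enumeration budget", {
  tab <- rbind(c(40, 35, 52), c(38, 44, 31))
  res <- fisher_exact(tab, max_tables = 100, mc_B = 20000, mc_seed = 4)
  expect_equal(res$method, "monte-carlo")
  ref <- stats::fisher.test(tab)$p.value
  expect_lt(abs(res$p - ref), 0.02)
  # deterministic given the seed
  res2 <- fisher_exact(tab, max_tables = 100, mc_B = 20000, mc_seed = 4)
  expect_equal(res$p, res2$p)
})

test_that("edge-distribution comparison builds the group x window table", {
  mk_dist <- function(counts) {
    hgs <- lapply(seq_along(counts), function(i) {
      edges <- if (counts[i] > 0) {
        data.frame(mediator = default_panel()$names[seq_len(counts[i])],
                   compartment = "serum", group = "TBI",
                   window = window_labels()[i], r = 0.99,
                   sign = "increasing", passes = TRUE, degenerate = FALSE)
      } else NULL
      build_hypergraph(edges, "increasing", window_labels()[i])
    })
    edge_distribution(hgs)
  }
  da <- mk_dist(c(1, 2, 4))
  db <- mk_dist(c(4, 2, 1))
  res <- compare_distributions(da, db, "serum")
  expect_equal(unname(res$table["group_a", ]), c(1, 2, 4))
  expect_equal(unname(res$table["group_b", ]), c(4, 2, 1))
  expect_equal(res$p, stats::fisher.test(rbind(c(1, 2, 4),
                                               c(4, 2, 1)))$p.value)
  expect_error(compare_distributions(da, db, "plasma"), "not present")
})

test_that("full hypergraph analysis partitions passing mediators per window", {
  co <- generate_cohort(paper_like_config(seed = 21))
  res <- dyhyp_analysis(co, "TBI")
  for (w in window_labels()) {
    for (sg in c("increasing", "decreasing")) {
      hg <- res$hypergraphs[[paste(w, sg, sep = ".")]]
      meds <- unlist(lapply(hg$hyperedges, `[[`, "mediators"))
      expect_equal(anyDuplicated(meds), 0L)
      # every hyperedge member passed in every member compartment
      for (key in names(hg$hyperedges)) {
        he <- hg$hyperedges[[key]]
        expect_equal(nrow(he$weights),
                     length(he$mediators) * length(he$compartments))
        expect_true(all(abs(he$weights$r) > 0.95))
      }
    }
  }
  # distribution counts are bounded by the panel size per (window, sign)
  d <- res$distribution
  for (w in window_labels()) {
    for (sg in c("increasing", "decreasing")) {
      expect_lte(sum(d$count[d$window == w & d$sign == sg]), 23L)
    }
  }
})
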