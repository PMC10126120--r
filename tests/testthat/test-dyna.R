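test_that("identical and negated trajectories give signed edges at |r| = 1", {
  co <- stacked_cohort(list(A = c(1, 2, 3, 4, 5, 6),
                            B = c(1, 2, 3, 4, 5, 6),
                            C = c(9, 8, 7, 6, 5, 4)))  # C = -A + 10
  net <- build_network(co, "TBI", "serum", "n1-n2")
  ab <- net$edges[net$edges$node_a == "A" & net$edges$node_b == "B", ]
  ac <- net$edges[net$edges$node_a == "A" & net$edges$node_b == "C", ]
  expect_equal(ab$sign, "parallel")
  expect_equal(ab$r, 1)
  expect_equal(ac$sign, "antiparallel")
  expect_equal(ac$r, -1)
})

test_that("the edge rule matches a hand Pearson computation at the threshold", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(1, 2, 3, 4, 5, 6, 7, 9)
  r_hand <- pearson_brute(x, y)
  expect_gt(r_hand, 0.95)  # ~0.993: the pair must form an edge
  co <- stacked_cohort(list(A = x, B = y))
  net <- build_network(co, "TBI", "serum", "n1-n2")
  expect_equal(edge_key(net), "A~B")
  expect_equal(net$edges$r, r_hand)

  # a clearly sub-threshold pair forms no edge
  co2 <- stacked_cohort(list(A = x, B = c(5, 1, 4, 2, 8, 3, 9, 2)))
  expect_equal(nrow(build_network(co2, "TBI", "serum", "n1-n2")$edges), 0L)
})

test_that("zero-variance mediators stay as nodes but never form edges", {
  co <- stacked_cohort(list(A = c(1, 2, 3, 4, 5, 6),
                            B = c(7, 7, 7, 7, 7, 7)))
  net <- build_network(co, "TBI", "serum", "n1-n2")
  expect_equal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 0L)
})

test_that("raising the threshold never adds edges", {
  cfg <- simulation_config(seed = 31, n_patients = c(TBI = 12L, nonTBI = 3L),
                           panel = small_panel(6L))
  co <- generate_cohort(cfg)
  thresholds <- c(0.3, 0.5, 0.7, 0.9, 0.95)
  counts <- vapply(thresholds, function(th) {
    nrow(build_network(co, "TBI", "serum", "n1-n2", threshold = th)$edges)
  }, numeric(1L))
  expect_true(all(diff(counts) <= 0))
  # and every higher-threshold edge set is nested in the lower one
  e_lo <- edge_key(build_network(co, "TBI", "serum", "n1-n2",
                                 threshold = 0.5))
  e_hi <- edge_key(build_network(co, "TBI", "serum", "n1-n2",
                                 threshold = 0.9))
  expect_true(all(e_hi %in% e_lo))
})

test_that("networks are invariant to mediator and patient ordering", {
  cfg <- simulation_config(seed = 32, n_patients = c(TBI = 8L, nonTBI = 3L),
                           panel = small_panel(5L))
  co <- generate_cohort(cfg)
  base <- build_network(co, "TBI", "serum", "n2-n3", threshold = 0.5)

  perm <- withr::with_seed(1, as.data.frame(co)[sample(nrow(co)), ])
  co_perm <- cohort_table(perm, panel = mediator_panel(rev(LETTERS[1:5])))
  net_perm <- build_network(co_perm, "TBI", "serum", "n2-n3",
                            threshold = 0.5)
  norm <- function(k) sort(vapply(strsplit(k, "~"), function(p) {
    paste(sort(p), collapse = "~")
  }, character(1L)))
  expect_equal(norm(edge_key(net_perm)), norm(edge_key(base)))
})

test_that("complexity follows the degree-sum formula and its identity", {
  # n = 4, edges {(A,B),(B,C)}: degrees (1,2,1,0) -> score 4/3.
  # B = A + C couples to both parents (r ~ 0.956) while r(A,C) ~ 0.829
  # stays under the 0.9 threshold.
  co <- stacked_cohort(list(A = c(1, 2, 3, 4, 5, 6),
                            B = c(3, 3, 7, 7, 11, 11),
                            C = c(2, 1, 4, 3, 6, 5),
                            D = c(5, 1, 4, 2, 8, 3)))
  net <- build_network(co, "TBI", "serum", "n1-n2", threshold = 0.9)
  expect_equal(edge_key(net), c("A~B", "B~C"))
  expect_equal(unname(degree_profile(net)), c(1L, 2L, 1L, 0L))
  expect_equal(network_complexity(net), 4 / 3)
  expect_equal(network_complexity(net),
               2 * nrow(net$edges) / (length(net$nodes) - 1))

  # empty network scores 0
  co_null <- stacked_cohort(list(A = c(1, 2, 3, 4, 5, 6),
                                 B = c(5, 1, 4, 2, 8, 3)))
  expect_equal(network_complexity(build_network(co_null, "TBI", "serum",
                                                "n1-n2")), 0)
})

test_that("a complete graph on the 23-mediator panel scores exactly 23", {
  # all mediators share one trajectory -> all pairwise r = 1
  v <- c(1, 2, 3, 4, 5, 6)
  vals <- stats::setNames(rep(list(v), 23L), default_panel()$names)
  co <- stacked_cohort(vals, panel = default_panel())
  net <- build_network(co, "TBI", "serum", "n1-n2")
  expect_equal(nrow(net$edges), choose(23, 2))
  expect_equal(network_complexity(net), 23)
  expect_equal(shannon_entropy(net, "paper"), 0)       # all p_i = 1
  expect_equal(shannon_entropy(net, "normalized"), log2(23))
})

test_that("entropy matches closed-form values for the single-edge network", {
  co <- stacked_cohort(single_edge_values(), panel = default_panel())
  net <- build_network(co, "TBI", "serum", "n1-n2")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(shannon_entropy(net, "paper"), 2 * (1 / 22) * log2(22))
  expect_equal(shannon_entropy(net, "normalized"), 1)

  co_null <- stacked_cohort(list(A = c(1, 2, 3, 4, 5, 6),
                                 B = c(5, 1, 4, 2, 8, 3)))
  net0 <- build_network(co_null, "TBI", "serum", "n1-n2")
  expect_equal(shannon_entropy(net0, "paper"), 0)
  expect_equal(shannon_entropy(net0, "normalized"), 0)
})

test_that("degree heatmap recounts edge lists and rejects mismatched nodes", {
  cfg <- simulation_config(seed = 33, n_patients = c(TBI = 10L, nonTBI = 3L),
                           panel = small_panel(5L))
  co <- generate_cohort(cfg)
  nets <- dyna_networks(co, "TBI", "serum", threshold = 0.5)
  hm <- degree_heatmap(nets)
  expect_equal(dim(hm), c(5L, length(nets)))
  for (j in seq_along(nets)) {
    recount <- table(factor(c(nets[[j]]$edges$node_a,
                              nets[[j]]$edges$node_b),
                            levels = nets[[j]]$nodes))
    expect_equal(unname(hm[, j]), as.integer(recount))
  }

  other <- build_network(generate_cohort(
    simulation_config(seed = 34, n_patients = c(TBI = 10L, nonTBI = 3L),
                      panel = small_panel(3L))), "TBI", "serum", "n1-n2")
  expect_error(degree_heatmap(c(nets, list(other))), "node set")
})

test_that("cross-compartment mode prefixes nodes and degenerates cleanly", {
  cfg <- simulation_config(seed = 35, n_patients = c(TBI = 10L, nonTBI = 3L),
                           panel = small_panel(4L))
  co <- generate_cohort(cfg)
  both <- build_network(co, "TBI", c("serum", "effluent"), "n1-n2",
                        threshold = 0.5)
  expect_equal(both$nodes,
               c(paste0("s", LETTERS[1:4]), paste0("e", LETTERS[1:4])))
  expect_equal(length(both$nodes), 8L)

  # restricted to serum alone, cross mode reduces to the single-compartment
  # network exactly
  single <- build_network(co, "TBI", "serum", "n1-n2", threshold = 0.5)
  again <- build_network(co, "TBI", compartments = "serum",
                         interval = "n1-n2", threshold = 0.5)
  expect_identical(again$nodes, single$nodes)
  expect_identical(again$edges, single$edges)
})
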