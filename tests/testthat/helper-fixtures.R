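# Fixture builders and independent oracles used across the suite.

small_panel <- function(k = 4L) {
  mediator_panel(LETTERS[seq_len(k)])
}

# quick long-format observation builder
obs_row <- function(patient, group, compartment, debridement, mediator,
                    value, ...) {
  data.frame(patient_id = patient, group = group, compartment = compartment,
             debridement = debridement, mediator = mediator, value = value,
             ..., stringsAsFactors = FALSE)
}

# cohort in which each mediator has prescribed stacked sample values:
# `values` is a named list mediator -> numeric vector of length 2 * npat,
# laid out as (patients at debridement k, patients at debridement k+1).
stacked_cohort <- function(values, interval = c(1L, 2L), group = "TBI",
                           compartment = "serum", panel = NULL) {
  npat <- length(values[[1L]]) / 2L
  if (is.null(panel)) panel <- mediator_panel(names(values))
  rows <- list()
  for (med in names(values)) {
    v <- values[[med]]
    for (p in seq_len(npat)) {
      rows[[length(rows) + 1L]] <- obs_row(
        sprintf("P%02d", p), group, compartment, interval[1L], med, v[p])
      rows[[length(rows) + 1L]] <- obs_row(
        sprintf("P%02d", p), group, compartment, interval[2L], med,
        v[npat + p])
    }
  }
  cohort_table(do.call(rbind, rows), panel = panel)
}

# 23-panel stacked values with exactly one perfectly correlated pair (the
# first two mediators); the rest are frozen uniform noise, verified to stay
# below |r| = 0.95 pairwise
single_edge_values <- function() {
  v <- c(1, 2, 3, 4, 5, 6)
  noise <- withr::with_seed(1, replicate(21, runif(6, 0, 10),
                                         simplify = FALSE))
  stats::setNames(c(list(v, v), noise), default_panel()$names)
}

# ---- independent oracles -------------------------------------------------

# textbook Pearson from sums, no cor()
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# brute-force DyNA edge list straight from the long table (complete data),
# independent of interval_matrix/build_network internals
brute_edge_set <- function(cohort, group, compartment, interval, threshold) {
  obs <- as.data.frame(cohort)
  obs <- obs[obs$group == group & obs$compartment == compartment, ]
  meds <- attr(cohort, "panel")$names
  k <- interval[1L]
  stack_vals <- function(med) {
    sub <- obs[obs$mediator == med & obs$debridement %in% c(k, k + 1L), ]
    sub <- sub[order(sub$debridement, sub$patient_id), ]
    sub$value
  }
  edges <- character()
  for (i in seq_along(meds)) {
    for (j in seq_along(meds)) {
      if (j <= i) next
      x <- stack_vals(meds[i]); y <- stack_vals(meds[j])
      if (length(x) < 3L || length(x) != length(y)) next
      r <- pearson_brute(x, y)
      if (!is.na(r) && abs(r) >= threshold) {
        edges <- c(edges, paste(meds[i], meds[j], sep = "~"))
      }
    }
  }
  sort(edges)
}

edge_key <- function(net) {
  if (!nrow(net$edges)) return(character())
  sort(paste(net$edges$node_a, net$edges$node_b, sep = "~"))
}

# closed-form two-sided Fisher p for a 2x2 table via the hypergeometric pmf
fisher_2x2_closed_form <- function(tab) {
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(tab[1L, 1L], m, n, k) * (1 + 1e-7)])
}

# brute-force 2x3 exact test by direct double loop (independent of the
# package's recursive enumeration)
fisher_2x3_brute <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  lp <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1) -
      sum(lgamma(m + 1))
  }
  lp_obs <- lp(tab)
  p <- 0
  for (a in 0:min(rs[1L], cs[1L])) {
    for (b in 0:min(rs[1L] - a, cs[2L])) {
      cc <- rs[1L] - a - b
      if (cc > cs[3L]) next
      m <- rbind(c(a, b, cc), cs - c(a, b, cc))
      if (any(m < 0)) next
      lpt <- lp(m)
      if (lpt <= lp_obs + 1e-7) p <- p + exp(lpt)
    }
  }
  min(p, 1)
}
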