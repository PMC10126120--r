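#' Spearman rank correlation with a percentile bootstrap confidence interval
#'
#' Computes Spearman's rho (average ranks for ties) between two paired
#' vectors after dropping incomplete pairs, and a percentile bootstrap
#' confidence interval obtained by resampling pairs with replacement.
#' Deterministic given \code{seed}; the caller's RNG state is restored.
#'
#' @param x,y Numeric vectors of equal length.
#' @param B Bootstrap replicates (default 1000).
#' @param alpha CI level complement (default 0.05 for a 95\% interval).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class \code{correlation_result}: list with
#'   \code{rho}, \code{n}, \code{ci_low}, \code{ci_high}, \code{alpha},
#'   \code{B}, \code{seed}, \code{degenerate}, \code{p} (large-sample t
#'   approximation, NA when degenerate).
#' @export
spearman_bootstrap <- function(x, y, B = 1000L, alpha = 0.05, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs, got ", n)

  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    return(structure(list(rho = NA_real_, n = n, ci_low = NA_real_,
                          ci_high = NA_real_, alpha = alpha, B = B,
                          seed = seed, degenerate = TRUE, p = NA_real_),
                     class = "correlation_result"))
  }

  rho <- stats::cor(x, y, method = "spearman")
  tstat <- rho * sqrt((n - 2) / (1 - min(rho^2, 1 - 1e-15)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  boots <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    boots[b] <- if (stats::sd(xb) == 0 || stats::sd(yb) == 0) NA_real_ else {
      stats::cor(xb, yb, method = "spearman")
    }
  }
  boots <- boots[!is.na(boots)]
  ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2)))

  structure(list(rho = rho, n = n, ci_low = ci[1L], ci_high = ci[2L],
                 alpha = alpha, B = B, seed = seed, degenerate = FALSE,
                 p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Spearman correlation: degenerate (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("Spearman rho = %.3f (n = %d), %g%% bootstrap CI [%.3f, %.3f]\n",
                x$rho, x$n, 100 * (1 - x$alpha), x$ci_low, x$ci_high))
  }
  invisible(x)
}

SUBSET_PARTNERS <- c("GM-CSF" = "pathogenic Th17",
                     "IL-10" = "non-pathogenic Th17",
                     "TNF-a" = "memory/effector T")

#' Infer IL-17A-producing cell subsets from mediator co-correlation
#'
#' Correlates IL-17A with GM-CSF, IL-10 and TNF-a within one group and
#' compartment, pooling all (patient, debridement) observations as pairs.
#' The three pairings are interpretive signatures: IL-17A/GM-CSF co-
#' expression marks pathogenic Th17 cells, IL-17A/IL-10 non-pathogenic Th17
#' cells, and IL-17A/TNF-a memory/effector T cells. A subset is called
#' \code{inferred-present} when the bootstrap CI lies entirely above zero,
#' \code{inferred-reduced} when entirely below, else \code{indeterminate}.
#'
#' @param x A \code{cohort_table} whose panel includes IL-17A and the three
#'   partner mediators.
#' @param group Patient group.
#' @param compartment Compartment.
#' @param B,alpha,seed Bootstrap parameters, see [spearman_bootstrap()].
#' @param stratify If TRUE, returns one call per debridement instead of
#'   pooling (sensitivity analysis).
#' @return data.frame with columns \code{partner}, \code{population},
#'   \code{rho}, \code{n}, \code{ci_low}, \code{ci_high}, \code{verdict}
#'   (and \code{debridement} when stratified).
#' @export
infer_subsets <- function(x, group, compartment, B = 1000L, alpha = 0.05,
                          seed = 1L, stratify = FALSE) {
  stopifnot(inherits(x, "cohort_table"))
  need <- c("IL-17A", names(SUBSET_PARTNERS))
  missing_meds <- setdiff(need, attr(x, "panel")$names)
  if (length(missing_meds)) {
    stop("panel lacks required mediator(s): ",
         paste(missing_meds, collapse = ", "))
  }
  obs <- as.data.frame(x)
  obs <- obs[obs$group == group & obs$compartment == compartment &
               !is.na(obs$value), , drop = FALSE]

  pull <- function(med, deb = NULL) {
    sel <- obs$mediator == med
    if (!is.null(deb)) sel <- sel & obs$debridement == deb
    sub <- obs[sel, c("patient_id", "debridement", "value")]
    names(sub)[3L] <- "v"
    sub
  }

  call_one <- function(partner, deb = NULL) {
    a <- pull("IL-17A", deb)
    b <- pull(partner, deb)
    if (!nrow(b)) {
      stop("data error: no ", compartment, " observations of ", partner,
           " for group ", group)
    }
    pairs <- merge(a, b, by = c("patient_id", "debridement"))
    res <- spearman_bootstrap(pairs$v.x, pairs$v.y, B = B, alpha = alpha,
                              seed = seed)
    verdict <- if (res$degenerate || is.na(res$ci_low)) "indeterminate"
      else if (res$ci_low > 0) "inferred-present"
      else if (res$ci_high < 0) "inferred-reduced"
      else "indeterminate"
    data.frame(partner = partner,
               population = unname(SUBSET_PARTNERS[partner]),
               debridement = if (is.null(deb)) NA_integer_ else deb,
               rho = res$rho, n = res$n, ci_low = res$ci_low,
               ci_high = res$ci_high, verdict = verdict,
               stringsAsFactors = FALSE)
  }

  out <- if (stratify) {
    debs <- sort(unique(obs$debridement))
    do.call(rbind, lapply(names(SUBSET_PARTNERS), function(p) {
      do.call(rbind, lapply(debs, function(d) call_one(p, d)))
    }))
  } else {
    do.call(rbind, lapply(names(SUBSET_PARTNERS), call_one))
  }
  if (!stratify) out$debridement <- NULL
  rownames(out) <- NULL
  out
}
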