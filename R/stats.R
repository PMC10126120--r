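#' Per-mediator two-way ANOVA screen (group x debridement)
#'
#' Fits, for each panel mediator within one compartment, the two-factor
#' linear model \code{value ~ group * factor(debridement)} and reports Type
#' II p-values for the group and time main effects and their interaction
#' (Type II sums of squares suit the unbalanced cohort). Mediators whose
#' cell structure leaves a factor unidentifiable are reported with NA for
#' that factor and a warning; when only one debridement carries data the
#' time factor is dropped and a one-way group comparison is returned.
#'
#' @param x A \code{cohort_table}.
#' @param compartment Compartment to screen.
#' @param alpha Significance level for the group-effect flag.
#' @param adjust Multiplicity adjustment for the group p-values across
#'   mediators (\code{"none"} default, or any [stats::p.adjust()] method
#'   such as \code{"BH"}).
#' @return data.frame with one row per mediator: \code{mediator},
#'   \code{compartment}, \code{p_group}, \code{p_time},
#'   \code{p_interaction}, \code{F_group}, \code{df_group}, \code{n_used},
#'   \code{significant} (group effect at \code{alpha}, after adjustment).
#' @export
anova_screen <- function(x, compartment, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(x, "cohort_table"))
  obs <- as.data.frame(x)
  obs <- obs[obs$compartment == compartment & !is.na(obs$value), ,
             drop = FALSE]
  if (length(unique(obs$group)) < 2L) {
    stop("ANOVA screen requires data from both groups")
  }

  rows <- lapply(attr(x, "panel")$names, function(med) {
    d <- obs[obs$mediator == med, , drop = FALSE]
    out <- data.frame(mediator = med, compartment = compartment,
                      p_group = NA_real_, p_time = NA_real_,
                      p_interaction = NA_real_, F_group = NA_real_,
                      df_group = NA_integer_, n_used = nrow(d),
                      stringsAsFactors = FALSE)
    if (length(unique(d$group)) < 2L) {
      warning("mediator ", med, " skipped: only one group has data")
      return(out)
    }
    d$group <- factor(d$group)
    d$deb <- factor(d$debridement)
    if (nlevels(d$deb) < 2L) {
      warning("mediator ", med,
              ": single debridement level; time factor dropped")
      fit <- stats::lm(value ~ group, data = d)
      a <- stats::anova(fit)
      out$p_group <- a[["Pr(>F)"]][1L]
      out$F_group <- a[["F value"]][1L]
      out$df_group <- a[["Df"]][1L]
      return(out)
    }
    # interaction needs every (group, debridement) cell occupied
    full_cells <- all(table(d$group, d$deb) > 0)
    form <- if (full_cells) value ~ group * deb else value ~ group + deb
    if (!full_cells) {
      warning("mediator ", med,
              ": empty group x debridement cell; interaction dropped")
    }
    fit <- stats::lm(form, data = d)
    a <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
    if (is.null(a)) {
      warning("mediator ", med, " skipped: model not estimable")
      return(out)
    }
    term <- rownames(a)
    out$p_group <- a[["Pr(>F)"]][term == "group"]
    out$p_time <- a[["Pr(>F)"]][term == "deb"]
    out$F_group <- a[["F value"]][term == "group"]
    out$df_group <- a[["Df"]][term == "group"]
    if ("group:deb" %in% term) {
      out$p_interaction <- a[["Pr(>F)"]][term == "group:deb"]
    }
    out
  })
  res <- do.call(rbind, rows)
  p_adj <- stats::p.adjust(res$p_group, method = adjust)
  res$significant <- !is.na(p_adj) & p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Chi-square test for a 2 x 2 contingency table
#'
#' Pearson chi-square with optional Yates continuity correction (on by
#' default, as used for the cohort characteristics table), with the p-value
#' from the 1-df chi-square distribution.
#'
#' @param counts 2 x 2 matrix (or coercible) of non-negative integers.
#' @param yates Apply the continuity correction (default TRUE).
#' @return An object of class \code{contingency_result}: list with
#'   \code{table}, \code{statistic}, \code{df}, \code{p}, \code{method}.
#' @export
chi_square_2x2 <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("undefined test: zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  structure(list(table = counts,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 method = if (yates) "chi-square-yates" else "chi-square"),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s: X-squared = %.4g, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

#' Clinical characteristics summary with per-descriptor chi-square tests
#'
#' Produces the standard cohort-characteristics layout: for each covariate
#' level, the count and the percentage of the group column total (one
#' decimal), plus a chi-square p-value comparing the level distribution
#' across groups. Accepts either a \code{cohort_table} with covariate
#' columns (tabulated at patient level; wound counts are summarized as
#' Single vs Multiple) or a pre-tabulated counts data.frame with columns
#' \code{descriptor}, \code{level}, \code{count_nonTBI}, \code{count_TBI}
#' and optional \code{denom_nonTBI}/\code{denom_TBI} overriding the column
#' totals (used for per-surgery rather than per-patient denominators).
#'
#' @param x A \code{cohort_table} or a counts data.frame as described.
#' @param yates Continuity correction for 2 x 2 descriptor tables.
#' @return data.frame with columns \code{descriptor}, \code{level},
#'   \code{n_nonTBI}, \code{pct_nonTBI}, \code{n_TBI}, \code{pct_TBI},
#'   \code{p} (repeated within descriptor; NA when untestable).
#' @export
characteristics_table <- function(x, yates = TRUE) {
  counts <- if (inherits(x, "cohort_table")) {
    pat <- as.data.frame(x)[!duplicated(x$patient_id),
                            intersect(c("patient_id", "group",
                                        COVARIATE_COLS), names(x))]
    blocks <- list()
    if ("wound_count" %in% names(pat)) {
      pat$wounds <- ifelse(pat$wound_count == 1L, "Single", "Multiple")
      blocks$`Number of wounds` <- "wounds"
    }
    if ("mechanism" %in% names(pat)) blocks$`Injury mechanism` <- "mechanism"
    if ("outcome" %in% names(pat)) blocks$`Final outcome` <- "outcome"
    do.call(rbind, lapply(names(blocks), function(desc) {
      col <- blocks[[desc]]
      tab <- table(pat[[col]], pat$group)
      data.frame(descriptor = desc, level = rownames(tab),
                 count_nonTBI = as.integer(tab[, "nonTBI"]),
                 count_TBI = as.integer(tab[, "TBI"]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    as.data.frame(x)
  }
  if (is.null(counts) || !nrow(counts)) {
    stop("no covariates available to summarize")
  }

  # per-descriptor totals are the natural denominator; explicit denom columns
  # (e.g. number of surgeries rather than patients) override per row
  out <- do.call(rbind, lapply(split(counts, counts$descriptor), function(b) {
    denom_non <- rep(sum(b$count_nonTBI), nrow(b))
    denom_tbi <- rep(sum(b$count_TBI), nrow(b))
    if (!is.null(b$denom_nonTBI)) {
      denom_non <- ifelse(is.na(b$denom_nonTBI), denom_non, b$denom_nonTBI)
    }
    if (!is.null(b$denom_TBI)) {
      denom_tbi <- ifelse(is.na(b$denom_TBI), denom_tbi, b$denom_TBI)
    }
    tab <- rbind(b$count_nonTBI, b$count_TBI)
    p <- if (nrow(b) >= 2L && all(rowSums(tab) > 0) &&
               all(colSums(tab) > 0)) {
      if (nrow(b) == 2L) {
        chi_square_2x2(t(tab), yates = yates)$p
      } else {
        suppressWarnings(stats::chisq.test(t(tab))$p.value)
      }
    } else NA_real_
    data.frame(descriptor = b$descriptor, level = b$level,
               n_nonTBI = b$count_nonTBI,
               pct_nonTBI = round(100 * b$count_nonTBI / denom_non, 1L),
               n_TBI = b$count_TBI,
               pct_TBI = round(100 * b$count_TBI / denom_tbi, 1L),
               p = p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
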