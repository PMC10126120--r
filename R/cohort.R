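GROUPS <- c("TBI", "nonTBI")
COMPARTMENTS <- c("serum", "effluent")
MECHANISMS <- c("Blast", "GSW")
OUTCOMES <- c("Healed", "Failed")

REQUIRED_COLS <- c("patient_id", "group", "compartment", "debridement",
                   "mediator", "value")
COVARIATE_COLS <- c("wound_count", "mechanism", "outcome")

#' Longitudinal two-compartment cohort table
#'
#' Validates a long-format table of analyte observations and attaches the
#' mediator panel. One row is one measurement of one mediator in one
#' compartment of one patient at one debridement. Patients are sampled at up
#' to \code{n_debridements} surgical debridements (indexed 1..n, roughly every
#' 3 days) in two compartments: peripheral blood serum (systemic) and wound
#' effluent (local).
#'
#' @param observations data.frame with columns \code{patient_id},
#'   \code{group} (\code{"TBI"}/\code{"nonTBI"}), \code{compartment}
#'   (\code{"serum"}/\code{"effluent"}), \code{debridement} (integer 1..n),
#'   \code{mediator}, \code{value} (pg/mL, non-negative or NA), and optional
#'   covariates \code{wound_count}, \code{mechanism} (\code{"Blast"}/
#'   \code{"GSW"}), \code{outcome} (\code{"Healed"}/\code{"Failed"}).
#' @param panel A [mediator_panel()]; rows naming mediators outside the panel
#'   are rejected.
#' @param n_debridements Number of debridement visits in the study design.
#' @return An object of class \code{cohort_table}: the validated data.frame
#'   with attributes \code{panel} and \code{n_debridements}.
#' @export
cohort_table <- function(observations, panel = default_panel(),
                         n_debridements = 5L) {
  stopifnot(inherits(panel, "mediator_panel"))
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)

  missing_cols <- setdiff(REQUIRED_COLS, names(obs))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  obs$patient_id <- as.character(obs$patient_id)
  obs$group <- as.character(obs$group)
  obs$compartment <- as.character(obs$compartment)
  obs$debridement <- as.integer(obs$debridement)
  obs$mediator <- as.character(obs$mediator)
  obs$value <- as.numeric(obs$value)

  if (nrow(obs)) {
    bad_group <- setdiff(unique(obs$group), GROUPS)
    if (length(bad_group)) {
      stop("schema error: unknown group value(s): ",
           paste(bad_group, collapse = ", "))
    }
    bad_comp <- setdiff(unique(obs$compartment), COMPARTMENTS)
    if (length(bad_comp)) {
      stop("schema error: unknown compartment value(s): ",
           paste(bad_comp, collapse = ", "))
    }
    bad_med <- setdiff(unique(obs$mediator), panel$names)
    if (length(bad_med)) {
      stop("schema error: mediator(s) not in panel: ",
           paste(bad_med, collapse = ", "))
    }
    if (any(is.na(obs$debridement)) ||
        any(obs$debridement < 1L | obs$debridement > n_debridements)) {
      stop("schema error: debridement indices must lie in 1..", n_debridements)
    }
    if (any(obs$value < 0, na.rm = TRUE)) {
      stop("schema error: negative concentrations are not allowed")
    }

    key <- paste(obs$patient_id, obs$compartment, obs$debridement,
                 obs$mediator, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- obs[duplicated(key), , drop = FALSE][1L, ]
      stop("integrity error: duplicate observation key (",
           dup$patient_id, ", ", dup$compartment, ", ", dup$debridement,
           ", ", dup$mediator, ")")
    }

    n_groups <- tapply(obs$group, obs$patient_id,
                       function(g) length(unique(g)))
    if (any(n_groups > 1L)) {
      stop("integrity error: patient(s) with more than one group label: ",
           paste(names(n_groups)[n_groups > 1L], collapse = ", "))
    }
  }

  structure(obs,
            panel = panel,
            n_debridements = as.integer(n_debridements),
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  pan <- attr(x, "panel")
  cat("Cohort table:", nrow(x), "observations,",
      length(unique(x$patient_id)), "patients,",
      length(pan$names), "mediators,",
      attr(x, "n_debridements"), "debridements\n")
  if (nrow(x)) {
    print(table(group = x$group[!duplicated(x$patient_id)]))
  }
  invisible(x)
}

#' Read a cohort from a long-format CSV file
#'
#' @param path Path to a UTF-8, comma-separated file with one observation per
#'   row and the columns documented in [cohort_table()].
#' @param panel Panel used for validation.
#' @param n_debridements Number of debridement visits in the design.
#' @return A validated \code{cohort_table}.
#' @export
load_cohort <- function(path, panel = default_panel(), n_debridements = 5L) {
  if (!file.exists(path)) stop("file not found: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"),
                         fileEncoding = "UTF-8")
  cohort_table(obs, panel = panel, n_debridements = n_debridements)
}

#' Write a cohort to CSV
#'
#' Writes the same long-format dialect [load_cohort()] reads, so that
#' write-then-load round-trips the observation multiset exactly.
#'
#' @param x A \code{cohort_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter a cohort by group, compartment and/or injury mechanism
#'
#' Filters combine with AND. The mechanism filter selects patients by their
#' recorded injury mechanism covariate, mirroring the segregation of a cohort
#' into blast and gunshot-wound subcohorts.
#'
#' @param x A \code{cohort_table}.
#' @param group Optional group filter (\code{"TBI"} or \code{"nonTBI"}).
#' @param compartment Optional compartment filter.
#' @param mechanism Optional mechanism filter (\code{"Blast"} or \code{"GSW"});
#'   requires the \code{mechanism} covariate column.
#' @param ... Ignored.
#' @return The filtered \code{cohort_table}.
#' @export
subset_cohort <- function(x, group = NULL, compartment = NULL,
                          mechanism = NULL, ...) {
  stopifnot(inherits(x, "cohort_table"))
  keep <- rep(TRUE, nrow(x))
  if (!is.null(group)) {
    if (!group %in% GROUPS) stop("unknown group filter value: ", group)
    keep <- keep & x$group == group
  }
  if (!is.null(compartment)) {
    if (!compartment %in% COMPARTMENTS) {
      stop("unknown compartment filter value: ", compartment)
    }
    keep <- keep & x$compartment == compartment
  }
  if (!is.null(mechanism)) {
    if (!mechanism %in% MECHANISMS) {
      stop("unknown mechanism filter value: ", mechanism)
    }
    if (!"mechanism" %in% names(x)) {
      stop("cohort has no mechanism covariate column")
    }
    keep <- keep & !is.na(x$mechanism) & x$mechanism == mechanism
  }
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  cohort_table(out, panel = attr(x, "panel"),
               n_debridements = attr(x, "n_debridements"))
}

#' @rdname subset_cohort
#' @export
subset.cohort_table <- function(x, group = NULL, compartment = NULL,
                                mechanism = NULL, ...) {
  subset_cohort(x, group = group, compartment = compartment,
                mechanism = mechanism)
}

# "n3-n4" -> c(3L, 4L); also accepts a length-2 integer vector
parse_interval <- function(interval) {
  if (is.character(interval)) {
    m <- regmatches(interval, regexec("^n(\\d+)-n(\\d+)$", interval))[[1L]]
    if (length(m) != 3L) stop("malformed interval label: ", interval)
    interval <- as.integer(m[2:3])
  }
  interval <- as.integer(interval)
  if (length(interval) != 2L) stop("interval must have two endpoints")
  interval
}

interval_label <- function(interval) {
  sprintf("n%d-n%d", interval[1L], interval[2L])
}

#' Interval labels for a study design
#'
#' @param n_debridements Number of debridements.
#' @return Character vector \code{"n1-n2"}, ..., of consecutive intervals.
#' @export
interval_labels <- function(n_debridements = 5L) {
  k <- seq_len(n_debridements - 1L)
  sprintf("n%d-n%d", k, k + 1L)
}

#' Mediator-by-sample matrix for one debridement interval
#'
#' Builds the value matrix from which interval correlation networks are
#' computed. Rows are panel mediators (compartment-prefixed \code{"s"}/
#' \code{"e"} when more than one compartment is requested); columns are
#' samples. A patient contributes only if it has at least one measured value
#' at both interval endpoints among the selected compartments; remaining
#' holes are NA and are handled pairwise-complete downstream.
#'
#' @param x A \code{cohort_table}.
#' @param group Patient group to use.
#' @param compartments Character vector of compartments (one for
#'   single-compartment networks, both for cross-compartment mode).
#' @param interval Consecutive pair of debridement indices, as \code{c(k,
#'   k+1)} or a label such as \code{"n3-n4"}.
#' @param method \code{"stacked"}: two columns per patient (the measured
#'   values at each endpoint); \code{"delta"}: one column per patient holding
#'   the endpoint difference level(k+1) - level(k).
#' @return Numeric matrix (mediators x samples) with attributes
#'   \code{interval}, \code{method} and \code{patients}.
#' @export
interval_matrix <- function(x, group, compartments = "serum", interval,
                            method = c("stacked", "delta")) {
  stopifnot(inherits(x, "cohort_table"))
  method <- match.arg(method)
  interval <- parse_interval(interval)
  if (interval[2L] != interval[1L] + 1L) {
    stop("interval endpoints must be consecutive debridements, got ",
         interval_label(interval))
  }
  nd <- attr(x, "n_debridements")
  if (interval[1L] < 1L || interval[2L] > nd) {
    stop("interval ", interval_label(interval), " outside design range 1..", nd)
  }
  compartments <- match.arg(compartments, COMPARTMENTS, several.ok = TRUE)

  panel <- attr(x, "panel")
  obs <- as.data.frame(x)
  obs <- obs[obs$group == group & obs$compartment %in% compartments &
               obs$debridement %in% interval & !is.na(obs$value), ,
             drop = FALSE]

  if (length(compartments) > 1L) {
    row_names <- as.vector(vapply(
      compartments,
      function(cc) paste0(substr(cc, 1L, 1L), panel$names),
      character(length(panel$names))))
    obs$row <- paste0(substr(obs$compartment, 1L, 1L), obs$mediator)
  } else {
    row_names <- panel$names
    obs$row <- obs$mediator
  }

  has_k <- unique(obs$patient_id[obs$debridement == interval[1L]])
  has_k1 <- unique(obs$patient_id[obs$debridement == interval[2L]])
  patients <- sort(intersect(has_k, has_k1))

  build_slice <- function(d) {
    m <- matrix(NA_real_, nrow = length(row_names), ncol = length(patients),
                dimnames = list(row_names, patients))
    sl <- obs[obs$debridement == d & obs$patient_id %in% patients, ,
              drop = FALSE]
    if (nrow(sl)) m[cbind(sl$row, sl$patient_id)] <- sl$value
    m
  }
  m1 <- build_slice(interval[1L])
  m2 <- build_slice(interval[2L])

  if (method == "stacked") {
    out <- cbind(m1, m2)
    if (length(patients)) {
      colnames(out) <- c(paste0(patients, ".n", interval[1L]),
                         paste0(patients, ".n", interval[2L]))
    }
  } else {
    out <- m2 - m1
    if (length(patients)) colnames(out) <- patients
  }

  if (ncol(out) < 3L) {
    stop("insufficient data: interval ", interval_label(interval),
         " has ", ncol(out), " sample column(s); at least 3 required")
  }
  attr(out, "interval") <- interval_label(interval)
  attr(out, "method") <- method
  attr(out, "patients") <- patients
  out
}
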