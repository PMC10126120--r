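#' Mediator panel definition
#'
#' A mediator panel is the ordered set of analyte names measured by the
#' multiplex immunoassay, together with the concentration unit they share.
#'
#' @param names Character vector of unique mediator identifiers.
#' @param units Concentration unit tag; the pipeline assumes \code{"pg/mL"}.
#' @return An object of class \code{mediator_panel}: a list with elements
#'   \code{names} and \code{units}.
#' @seealso [default_panel()]
#' @export
mediator_panel <- function(names, units = "pg/mL") {
  names <- as.character(names)
  if (length(names) == 0L) stop("panel must contain at least one mediator")
  if (anyDuplicated(names)) {
    stop("duplicate mediator names in panel: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  structure(list(names = names, units = units), class = "mediator_panel")
}

#' The 23-mediator Luminex cytokine/chemokine panel
#'
#' The default panel mirrors a 23-plex human cytokine Luminex kit. Greek
#' letters are transliterated to ASCII for file-format safety:
#' IFN-a2 (IFN-\eqn{\alpha}2), IFN-g (IFN-\eqn{\gamma}),
#' IL-1a/IL-1b (IL-1\eqn{\alpha}/\eqn{\beta}), MIP-1a (MIP-1\eqn{\alpha}),
#' TNF-a (TNF-\eqn{\alpha}).
#'
#' @return A \code{mediator_panel} with exactly 23 mediators.
#' @export
default_panel <- function() {
  mediator_panel(c(
    "Eotaxin", "GM-CSF", "IFN-a2", "IFN-g",
    "IL-1a", "IL-1b", "IL-2", "IL-3", "IL-4", "IL-5", "IL-6", "IL-7",
    "IL-8", "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-15", "IL-17A",
    "IP-10", "MCP-1", "MIP-1a", "TNF-a"
  ))
}

#' @export
print.mediator_panel <- function(x, ...) {
  cat("Mediator panel:", length(x$names), "analytes [", x$units, "]\n")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Write a panel definition to JSON
#'
#' @param panel A \code{mediator_panel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mediator_panel"))
  jsonlite::write_json(list(names = panel$names, units = panel$units),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
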