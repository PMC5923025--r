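#' Triage categories
#'
#' Primary MCI triage assigns each casualty to one of four categories:
#' `RED` (immediate treatment and/or transport), `YELLOW` (delayed
#' treatment and transport), `GREEN` (minor injuries) and `DEAD`
#' (black tag). `triage_categories()` returns them ordered from most to
#' least urgent, the ordering used to decide whether a mis-assignment is
#' over- or under-triage.
#'
#' @return Character vector `c("RED", "YELLOW", "GREEN", "DEAD")`.
#' @export
#' @examples
#' triage_categories()
triage_categories <- function() c("RED", "YELLOW", "GREEN", "DEAD")

#' @rdname triage_categories
#' @param category character vector of category labels.
#' @return `category_urgency()`: integer urgency rank (4 = RED most
#'   urgent, 1 = DEAD), useful for comparing assignments.
#' @export
category_urgency <- function(category) {
  rank <- c(RED = 4L, YELLOW = 3L, GREEN = 2L, DEAD = 1L)
  stopifnot(all(category %in% names(rank)))
  unname(rank[category])
}

#' @rdname triage_categories
#' @return `intervention_codes()`: the life-saving interventions a
#'   START-family primary triage algorithm can indicate.
#' @export
intervention_codes <- function() c("BLEEDING_CONTROL", "OROPHARYNGEAL_TUBE")

assert_category <- function(x, arg = deparse(substitute(x))) {
  bad <- setdiff(unique(as.character(x)), triage_categories())
  if (length(bad) > 0L) {
    stop(sprintf("invalid triage category in `%s`: %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
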