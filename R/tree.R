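#' Load a triage decision tree from a YAML configuration
#'
#' START-family triage algorithms are decision trees over a small set of
#' clinical findings (ambulation, breathing, respiratory rate, pulse
#' status, consciousness, severe bleeding). The engine is fully
#' data-driven: every finding domain, node, branch predicate, numeric
#' threshold, leaf category and intervention annotation lives in a YAML
#' file, so the same engine executes ASAV, START or any variant, and
#' every clinical cut-off is reviewable in one place.
#'
#' The configuration document has three parts:
#' \describe{
#'   \item{`findings`}{a map `finding_key -> domain`. A domain is either
#'     `type: logical`, `type: categorical` with `levels`, or
#'     `type: numeric` with `min`/`max`. Numeric branch predicates are
#'     half-open intervals `[min, max)` except that the interval ending
#'     at the domain maximum is closed.}
#'   \item{`root`}{the id of the entry node.}
#'   \item{`nodes`}{a map `id -> node`. A leaf node has `leaf: <CATEGORY>`;
#'     an internal node has `finding: <key>` and `edges`, each edge either
#'     `{value: ..., goto: id}` (logical/categorical) or
#'     `{min: ..., max: ..., goto: id}` (numeric). Any node may carry at
#'     most one `intervention` annotation (`BLEEDING_CONTROL` or
#'     `OROPHARYNGEAL_TUBE`), performed when the node is traversed.}
#' }
#'
#' Validation rejects cycles, nodes unreachable from the root,
#' references to undeclared findings or nodes, invalid leaf categories,
#' and predicates that do not partition the finding's domain (so the
#' tree is total: every complete vignette reaches a leaf).
#'
#' @param path path to a YAML tree configuration, or a name of a shipped
#'   configuration (`"asav"`, `"start_demo"`).
#' @return An object of class `triage_tree`: a list with elements
#'   `algorithm`, `findings`, `root`, `nodes`.
#' @seealso [apply_algorithm()], [asav_tree()]
#' @export
#' @examples
#' tree <- load_tree("asav")
#' tree
load_tree <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", paste0(path, ".yaml"), package = "triagesim")
    if (nzchar(shipped)) path <- shipped
  }
  if (!file.exists(path)) stop("tree configuration not found: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)
  build_tree(spec)
}

#' @rdname load_tree
#' @param spec a list with the structure described above (already parsed).
#' @export
build_tree <- function(spec) {
  for (field in c("findings", "root", "nodes")) {
    if (is.null(spec[[field]])) stop("tree spec lacks `", field, "`", call. = FALSE)
  }
  findings <- lapply(spec$findings, validate_domain)
  nodes <- spec$nodes
  if (is.null(names(nodes)) || any(!nzchar(names(nodes)))) {
    stop("every node must be named by its id", call. = FALSE)
  }
  if (!spec$root %in% names(nodes)) {
    stop("root node `", spec$root, "` is not defined", call. = FALSE)
  }
  for (id in names(nodes)) nodes[[id]] <- validate_node(id, nodes[[id]], findings, names(nodes))
  check_reachable_acyclic(spec$root, nodes)
  structure(
    list(algorithm = spec$algorithm %||% "unnamed", findings = findings,
         root = spec$root, nodes = nodes),
    class = "triage_tree")
}

validate_domain <- function(dom) {
  if (is.null(dom$type)) stop("finding domain lacks `type`", call. = FALSE)
  switch(dom$type,
    logical = dom,
    categorical = {
      if (length(dom$levels) < 2L) stop("categorical domain needs >= 2 levels", call. = FALSE)
      dom
    },
    numeric = {
      if (is.null(dom$min) || is.null(dom$max) || dom$min >= dom$max) {
        stop("numeric domain needs min < max", call. = FALSE)
      }
      dom
    },
    stop("unknown finding type: ", dom$type, call. = FALSE))
}

validate_node <- function(id, node, findings, ids) {
  if (!is.null(node$intervention) &&
      (length(node$intervention) != 1L || !node$intervention %in% intervention_codes())) {
    stop("node `", id, "`: invalid intervention annotation", call. = FALSE)
  }
  if (!is.null(node$leaf)) {
    if (!is.null(node$finding) || !is.null(node$edges)) {
      stop("node `", id, "`: a leaf cannot also test a finding", call. = FALSE)
    }
    assert_category(node$leaf, paste0("leaf of node ", id))
    return(node)
  }
  if (is.null(node$finding) || is.null(node$edges)) {
    stop("node `", id, "`: internal node needs `finding` and `edges`", call. = FALSE)
  }
  dom <- findings[[node$finding]]
  if (is.null(dom)) {
    stop("node `", id, "`: finding `", node$finding, "` is not declared", call. = FALSE)
  }
  targets <- vapply(node$edges, function(e) e$goto %||% NA_character_, character(1))
  if (anyNA(targets) || !all(targets %in% ids)) {
    stop("node `", id, "`: every edge needs a `goto` to a defined node", call. = FALSE)
  }
  check_edges_total(id, node$edges, dom)
  node
}

# Predicates must cover the whole finding domain exactly once.
check_edges_total <- function(id, edges, dom) {
  fail <- function(msg) stop("node `", id, "`: ", msg, call. = FALSE)
  if (dom$type %in% c("logical", "categorical")) {
    vals <- lapply(edges, `[[`, "value")
    if (any(vapply(vals, is.null, logical(1)))) fail("edges need `value` predicates")
    vals <- vapply(vals, as.character, character(1))
    want <- if (dom$type == "logical") c("TRUE", "FALSE") else dom$levels
    if (anyDuplicated(vals)) fail("overlapping edge predicates")
    missing <- setdiff(want, vals)
    if (length(missing) > 0L) fail(paste0("predicates do not cover domain value(s): ",
                                          paste(missing, collapse = ", ")))
    extra <- setdiff(vals, want)
    if (length(extra) > 0L) fail(paste0("predicate value(s) outside domain: ",
                                        paste(extra, collapse = ", ")))
  } else {
    lo <- vapply(edges, function(e) as.numeric(e$min %||% NA_real_), numeric(1))
    hi <- vapply(edges, function(e) as.numeric(e$max %||% NA_real_), numeric(1))
    if (anyNA(lo) || anyNA(hi)) fail("numeric edges need `min` and `max`")
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    if (lo[1] > dom$min || hi[length(hi)] < dom$max) fail("predicates do not cover the numeric domain")
    if (lo[1] < dom$min || hi[length(hi)] > dom$max) fail("predicate interval outside domain")
    if (length(lo) > 1L && any(abs(lo[-1] - hi[-length(hi)]) > 1e-9)) {
      fail("numeric predicates leave a gap or overlap")
    }
  }
  invisible(TRUE)
}

check_reachable_acyclic <- function(root, nodes) {
  state <- new.env(parent = emptyenv())  # 1 = on stack, 2 = done
  visit <- function(id) {
    s <- state[[id]]
    if (identical(s, 1L)) stop("cycle detected through node `", id, "`", call. = FALSE)
    if (identical(s, 2L)) return(invisible())
    state[[id]] <- 1L
    for (e in nodes[[id]]$edges) visit(e$goto)
    state[[id]] <- 2L
  }
  visit(root)
  seen <- ls(state)
  orphan <- setdiff(names(nodes), seen)
  if (length(orphan) > 0L) {
    stop("unreachable node(s): ", paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.triage_tree <- function(x, ...) {
  internal <- sum(vapply(x$nodes, function(n) is.null(n$leaf), logical(1)))
  cat(sprintf("<triage_tree> algorithm: %s\n", x$algorithm))
  cat(sprintf("  %d findings, %d nodes (%d decision, %d leaf), root `%s`\n",
              length(x$findings), length(x$nodes), internal,
              length(x$nodes) - internal, x$root))
  invisible(x)
}

#' The shipped ASAV configuration
#'
#' Convenience loader for the packaged transcription of the
#' Amberg-Schwandorf Algorithm for Primary Triage (ASAV), a
#' START-family tree: ambulatory patients are GREEN; patients not
#' breathing after an airway-opening maneuver are DEAD, those resuming
#' breathing receive an oropharyngeal tube and are RED; abnormal
#' respiratory rate, absent radial pulse or failure to obey commands are
#' RED; the remainder are YELLOW. Severe bleeding triggers bleeding
#' control on the way. All thresholds live in
#' `system.file("extdata", "asav.yaml", package = "triagesim")`.
#'
#' @return A `triage_tree`.
#' @export
asav_tree <- function() load_tree("asav")

#' Apply a triage algorithm to a patient vignette
#'
#' Executes the decision tree on one vignette: starting at the root, the
#' edge whose predicate matches the vignette's value for the tested
#' finding is followed until a leaf is reached. Interventions annotated
#' on traversed nodes are collected. The function is deterministic and
#' total for any vignette that supplies every finding on its path.
#'
#' @param vignette a named list (or one-row data frame) mapping finding
#'   keys to values. Extra entries are ignored; a missing tested finding
#'   is an error naming the finding.
#' @param tree a `triage_tree` from [load_tree()].
#' @return An object of class `triage_decision`: list with `category`,
#'   `interventions` (character vector), `path` (ordered node ids) and
#'   `tag` (the tag colour; `NA` for GREEN patients, who are not tagged).
#' @export
#' @examples
#' tree <- asav_tree()
#' apply_algorithm(list(can_walk = TRUE), tree)
apply_algorithm <- function(vignette, tree) {
  stopifnot(inherits(tree, "triage_tree"))
  v <- as.list(vignette)
  id <- tree$root
  path <- character(0)
  interventions <- character(0)
  repeat {
    node <- tree$nodes[[id]]
    path <- c(path, id)
    if (!is.null(node$intervention)) interventions <- union(interventions, node$intervention)
    if (!is.null(node$leaf)) {
      category <- node$leaf
      break
    }
    val <- v[[node$finding]]
    if (is.null(val) || length(val) != 1L || is.na(val)) {
      stop("vignette lacks a value for finding `", node$finding, "`", call. = FALSE)
    }
    id <- match_edge(node, val, tree$findings[[node$finding]])$goto
  }
  structure(
    list(category = category, interventions = interventions, path = path,
         tag = if (category == "GREEN") NA_character_ else category),
    class = "triage_decision")
}

match_edge <- function(node, value, dom) {
  if (dom$type %in% c("logical", "categorical")) {
    for (e in node$edges) if (as.character(e$value) == as.character(value)) return(e)
  } else {
    value <- as.numeric(value)
    if (value < dom$min || value > dom$max) {
      stop("value ", value, " for finding `", node$finding,
           "` outside declared domain [", dom$min, ", ", dom$max, "]", call. = FALSE)
    }
    for (e in node$edges) {
      if (value >= e$min && (value < e$max || (value == e$max && e$max == dom$max))) return(e)
    }
  }
  stop("no edge matches value ", value, " at node testing `", node$finding, "`",
       call. = FALSE)
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage_decision> %s (tag: %s)\n", x$category,
              if (is.na(x$tag)) "none" else x$tag))
  if (length(x$interventions) > 0)
    cat("  interventions:", paste(x$interventions, collapse = ", "), "\n")
  cat("  path:", paste(x$path, collapse = " -> "), "\n")
  invisible(x)
}

#' Enumerate all root-to-leaf outcomes of a tree
#'
#' Walks every root-to-leaf path and returns the category each path ends
#' in, together with the predicates along the way. Used as an exhaustive
#' cross-check of [apply_algorithm()] on small trees and to determine
#' which categories a tree can produce.
#'
#' @param tree a `triage_tree`.
#' @return data frame with one row per path: `leaf`, `category`,
#'   `n_decisions`, `interventions` (comma separated).
#' @export
enumerate_paths <- function(tree) {
  out <- list()
  walk <- function(id, depth, iv) {
    node <- tree$nodes[[id]]
    if (!is.null(node$intervention)) iv <- union(iv, node$intervention)
    if (!is.null(node$leaf)) {
      out[[length(out) + 1L]] <<- data.frame(
        leaf = id, category = node$leaf, n_decisions = depth,
        interventions = paste(iv, collapse = ","), stringsAsFactors = FALSE)
      return(invisible())
    }
    for (e in node$edges) walk(e$goto, depth + 1L, iv)
  }
  walk(tree$root, 0L, character(0))
  do.call(rbind, out)
}
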