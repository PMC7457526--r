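#' Penalty group structure
#'
#' Partitions the model's coefficient indices into penalized groups plus a set
#' of unpenalized indices. Every coefficient index from 1 to the total number
#' of coefficients must appear exactly once, either in one group or in the
#' unpenalized set; groups must be non-empty and pairwise disjoint.
#'
#' @param groups List of integer vectors of coefficient indices, one per
#'   penalized group (group sizes may differ). Names, if present, are kept as
#'   group labels.
#' @param unpenalized Integer vector of coefficient indices exempt from the
#'   penalty (e.g. intercept and condition dummies). Default none.
#' @param p Total number of coefficients; defaults to the largest index seen.
#' @return An object of class `group_structure` with elements `groups`,
#'   `unpenalized`, `p`, and the per-coefficient integer map `gid` (0 =
#'   unpenalized).
#' @examples
#' group_structure(list(g1 = 1:5, g2 = 6:10), unpenalized = 11L)
#' @export
group_structure <- function(groups, unpenalized = integer(0), p = NULL) {
  if (!is.list(groups)) abort("`groups` must be a list of index vectors.")
  groups <- lapply(groups, function(g) as.integer(sort(g)))
  unpenalized <- as.integer(sort(unpenalized))
  if (any(vapply(groups, length, 1L) == 0L)) {
    abort("Every penalty group must be non-empty.")
  }
  all_idx <- c(unlist(groups), unpenalized)
  if (length(all_idx) == 0L) abort("No coefficient indices supplied.")
  if (anyDuplicated(all_idx)) {
    abort("Groups and the unpenalized set must be pairwise disjoint.")
  }
  if (is.null(p)) p <- max(all_idx)
  if (!setequal(all_idx, seq_len(p))) {
    abort(sprintf(
      "Groups plus unpenalized indices must cover exactly 1..%d.", p
    ))
  }
  gid <- integer(p)
  for (g in seq_along(groups)) gid[groups[[g]]] <- g
  structure(
    list(groups = groups, unpenalized = unpenalized, p = as.integer(p),
         gid = gid),
    class = "group_structure"
  )
}

#' All-singleton group structure
#'
#' Puts every penalized coefficient in its own group, which reduces the group
#' SCAD penalty to the individual SCAD penalty of coefficient-wise penalized
#' GEE (PGEE).
#'
#' @param p Total number of coefficients.
#' @param unpenalized Indices exempt from the penalty.
#' @return A [group_structure()].
#' @export
singleton_groups <- function(p, unpenalized = integer(0)) {
  pen <- setdiff(seq_len(p), as.integer(unpenalized))
  group_structure(as.list(pen), unpenalized = unpenalized, p = p)
}

group_ids <- function(groups, p) {
  if (!inherits(groups, "group_structure")) {
    abort("`groups` must be a `group_structure` object.")
  }
  if (groups$p != p) {
    abort(sprintf(
      "Group structure covers %d coefficients but %d were supplied.",
      groups$p, p
    ))
  }
  groups$gid
}

#' Read a group structure from JSON
#'
#' Expects an object of the form
#' `{"groups": [["colA","colB"], ...], "unpenalized": ["intercept", ...]}`;
#' entries may be column names (resolved against `terms`) or 1-based indices.
#'
#' @param path Path to a JSON file.
#' @param terms Character vector of coefficient names used to resolve named
#'   entries, in model-column order.
#' @return A [group_structure()].
#' @export
read_group_structure <- function(path, terms) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  resolve <- function(entries) {
    vapply(entries, function(e) {
      if (is.numeric(e)) return(as.integer(e))
      i <- match(as.character(e), terms)
      if (is.na(i)) abort(sprintf("Unknown coefficient name \"%s\".", e))
      i
    }, 1L)
  }
  groups <- lapply(spec$groups, resolve)
  unpen <- if (is.null(spec$unpenalized)) integer(0) else
    resolve(spec$unpenalized)
  group_structure(groups, unpenalized = unpen, p = length(terms))
}

#' @export
print.group_structure <- function(x, ...) {
  cat("<group_structure>", length(x$groups), "groups,",
      length(x$unpenalized), "unpenalized,", x$p, "coefficients\n")
  sizes <- vapply(x$groups, length, 1L)
  cat("  group sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}
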