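#' Read an areal adjacency structure from a text file
#'
#' Two dialects are supported. The `"gal"` dialect is the common GeoDa-style
#' text format: a header line holding the unit count, then for each unit a
#' record line `"<id> <degree>"` followed (when degree > 0) by one line of
#' whitespace-separated neighbour ids. The `"neighbor_csv"` dialect is a
#' two-column CSV (`unit_a`, `unit_b`) of undirected neighbour pairs; a row
#' whose `unit_b` field is empty declares `unit_a` as an island (a unit with
#' no neighbours).
#'
#' The returned structure is symmetric and irreflexive by construction;
#' asymmetric GAL input is refused with an error listing the offending pairs
#' rather than silently symmetrized. Unit order is the order of first
#' appearance in the file and is the canonical index order downstream.
#'
#' @param path Path to the adjacency file.
#' @param dialect `"gal"` or `"neighbor_csv"`.
#' @return A named list of character vectors (neighbour ids per unit), with
#'   attribute `islands` holding the ids of units that have no neighbours.
#' @seealso [write_adjacency()], [multiscale_geography()]
#' @export
read_adjacency <- function(path, dialect = c("gal", "neighbor_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("adjacency file not found: ", path, call. = FALSE)
  }
  nb <- switch(dialect,
    gal = read_gal(path),
    neighbor_csv = read_neighbor_csv(path)
  )
  check_adjacency(nb, context = path)
  finish_adjacency(nb)
}

read_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("GAL parse error at line 1: empty file", call. = FALSE)
  }
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n_units <- suppressWarnings(as.integer(header[[1L]]))
  if (is.na(n_units) || n_units < 0L) {
    stop("GAL parse error at line 1: header must start with the unit count",
         call. = FALSE)
  }
  nb <- vector("list", n_units)
  ids <- character(n_units)
  ln <- 1L
  for (u in seq_len(n_units)) {
    ln <- ln + 1L
    if (ln > length(lines)) {
      stop(sprintf("GAL parse error at line %d: expected a unit record", ln),
           call. = FALSE)
    }
    rec <- strsplit(trimws(lines[[ln]]), "\\s+")[[1L]]
    if (length(rec) != 2L) {
      stop(sprintf("GAL parse error at line %d: expected '<id> <degree>'", ln),
           call. = FALSE)
    }
    deg <- suppressWarnings(as.integer(rec[[2L]]))
    if (is.na(deg) || deg < 0L) {
      stop(sprintf("GAL parse error at line %d: invalid degree '%s'",
                   ln, rec[[2L]]), call. = FALSE)
    }
    if (rec[[1L]] %in% ids[seq_len(u - 1L)]) {
      stop(sprintf("GAL parse error at line %d: duplicate unit '%s'",
                   ln, rec[[1L]]), call. = FALSE)
    }
    ids[[u]] <- rec[[1L]]
    if (deg > 0L) {
      ln <- ln + 1L
      if (ln > length(lines)) {
        stop(sprintf("GAL parse error at line %d: expected %d neighbor ids",
                     ln, deg), call. = FALSE)
      }
      nbrs <- strsplit(trimws(lines[[ln]]), "\\s+")[[1L]]
      nbrs <- nbrs[nzchar(nbrs)]
      if (length(nbrs) != deg) {
        stop(sprintf(
          "GAL parse error at line %d: expected %d neighbor ids, found %d",
          ln, deg, length(nbrs)), call. = FALSE)
      }
      nb[[u]] <- nbrs
    } else {
      nb[[u]] <- character(0)
    }
  }
  names(nb) <- ids
  nb
}

read_neighbor_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), comment.char = "#")
  if (ncol(df) < 2L) {
    stop("neighbor CSV must have two columns (unit_a, unit_b)", call. = FALSE)
  }
  a <- trimws(df[[1L]])
  b <- trimws(df[[2L]])
  # unit order: first appearance scanning rows, unit_a then unit_b
  seen <- unique(as.vector(rbind(a, b)))
  seen <- seen[nzchar(seen)]
  nb <- stats::setNames(rep(list(character(0)), length(seen)), seen)
  for (r in seq_along(a)) {
    if (!nzchar(b[[r]])) next  # island declaration
    if (a[[r]] == b[[r]]) {
      stop(sprintf("neighbor CSV row %d: unit '%s' listed as its own neighbor",
                   r, a[[r]]), call. = FALSE)
    }
    nb[[a[[r]]]] <- union(nb[[a[[r]]]], b[[r]])
    nb[[b[[r]]]] <- union(nb[[b[[r]]]], a[[r]])
  }
  nb
}

check_adjacency <- function(nb, context = "adjacency") {
  ids <- names(nb)
  selfs <- ids[vapply(ids, function(i) i %in% nb[[i]], logical(1))]
  if (length(selfs)) {
    stop(context, ": unit(s) listed as their own neighbor: ",
         paste(selfs, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(nb)), ids)
  if (length(unknown)) {
    stop(context, ": neighbor id(s) not declared as units: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- character(0)
  for (i in ids) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]])) bad <- c(bad, paste0(i, "->", j))
    }
  }
  if (length(bad)) {
    stop(context, ": asymmetric adjacency refused; offending pair(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(nb)
}

finish_adjacency <- function(nb) {
  deg <- vapply(nb, length, integer(1))
  attr(nb, "islands") <- names(nb)[deg == 0L]
  nb
}

#' Write an adjacency structure to a text file
#'
#' Inverse of [read_adjacency()] for both dialects; a read of the written
#' file returns identical neighbour sets.
#'
#' @param nb Named list of neighbour id vectors (symmetric, irreflexive).
#' @param path Output path.
#' @param dialect `"gal"` or `"neighbor_csv"`.
#' @export
write_adjacency <- function(nb, path, dialect = c("gal", "neighbor_csv")) {
  dialect <- match.arg(dialect)
  check_adjacency(nb, context = "write_adjacency")
  if (dialect == "gal") {
    lines <- as.character(length(nb))
    for (id in names(nb)) {
      lines <- c(lines, paste(id, length(nb[[id]])))
      if (length(nb[[id]]) > 0L) {
        lines <- c(lines, paste(nb[[id]], collapse = " "))
      }
    }
    writeLines(lines, path)
  } else {
    ids <- names(nb)
    rows <- list()
    for (i in ids) {
      for (j in nb[[i]]) {
        if (match(j, ids) > match(i, ids)) rows[[length(rows) + 1L]] <- c(i, j)
      }
      if (length(nb[[i]]) == 0L) rows[[length(rows) + 1L]] <- c(i, "")
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c("unit_a", "unit_b")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a fine-to-coarse nesting map
#'
#' Reads a two-column CSV (`fine_id`, `coarse_id`, header required) mapping
#' each fine-level unit to exactly one coarse-level unit. A fine unit listed
#' twice is an error; with two different parents it is reported as a nesting
#' conflict.
#'
#' @param path Path to the nesting CSV.
#' @return Named character vector: `parent[fine_id] == coarse_id`, fine ids
#'   in file order.
#' @export
read_nesting <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) {
    stop("nesting CSV must have two columns (fine_id, coarse_id)",
         call. = FALSE)
  }
  fine <- trimws(df[[1L]])
  coarse <- trimws(df[[2L]])
  dup <- unique(fine[duplicated(fine)])
  if (length(dup)) {
    conflict <- dup[vapply(dup, function(f) {
      length(unique(coarse[fine == f])) > 1L
    }, logical(1))]
    if (length(conflict)) {
      stop("nesting conflict: fine unit(s) with more than one parent: ",
           paste(conflict, collapse = ", "), call. = FALSE)
    }
    stop("duplicated fine unit(s) in nesting file: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  stats::setNames(coarse, fine)
}

#' Construct a two-level nested areal geography
#'
#' Bundles the fine- and coarse-level adjacency structures and the nesting
#' map into a single validated object. Unit order follows the adjacency
#' lists' order of first appearance and is the canonical index order for all
#' vectors downstream.
#'
#' @param fine_adjacency Named list of neighbour id vectors at the fine level.
#' @param coarse_adjacency Named list of neighbour id vectors at the coarse
#'   level.
#' @param parent Named character vector mapping each fine id to its coarse id
#'   (as returned by [read_nesting()]).
#' @return An object of class `multiscale_geography` with elements
#'   `fine_ids`, `coarse_ids`, `parent`, `fine_adjacency`, `coarse_adjacency`,
#'   `children` (list of fine ids per coarse unit) and `parent_index`
#'   (integer index of each fine unit's parent).
#' @export
multiscale_geography <- function(fine_adjacency, coarse_adjacency, parent) {
  fine_ids <- names(fine_adjacency)
  coarse_ids <- names(coarse_adjacency)
  if (is.null(fine_ids) || is.null(coarse_ids)) {
    stop("adjacency lists must be named by unit id", call. = FALSE)
  }
  missing <- setdiff(fine_ids, names(parent))
  if (length(missing)) {
    stop("fine unit(s) missing from the nesting map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unname(parent[fine_ids]), coarse_ids)
  if (length(unknown)) {
    stop("parent id(s) not present in the coarse adjacency: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  parent <- parent[fine_ids]
  children <- split(fine_ids, factor(unname(parent), levels = coarse_ids))
  geog <- structure(
    list(
      fine_ids = fine_ids,
      coarse_ids = coarse_ids,
      parent = parent,
      parent_index = match(unname(parent), coarse_ids),
      fine_adjacency = finish_adjacency(fine_adjacency),
      coarse_adjacency = finish_adjacency(coarse_adjacency),
      children = children
    ),
    class = "multiscale_geography"
  )
  geog
}

#' @export
print.multiscale_geography <- function(x, ...) {
  cat(sprintf(
    "multiscale_geography: %d fine units nested in %d coarse units\n",
    length(x$fine_ids), length(x$coarse_ids)))
  cat(sprintf("  mean children per coarse unit: %.2f\n",
              length(x$fine_ids) / length(x$coarse_ids)))
  invisible(x)
}

adjacency_components <- function(nb) {
  ids <- names(nb)
  if (length(ids) == 0L) return(integer(0))
  edges <- character(0)
  for (i in ids) if (length(nb[[i]])) {
    edges <- c(edges, as.vector(rbind(i, nb[[i]])))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (length(edges)) {
    g <- igraph::add_edges(g, match(edges, ids))
    g <- igraph::simplify(g)
  }
  comp <- igraph::components(g)
  stats::setNames(as.integer(comp$membership), ids)
}

# number of connected components of size >= 2 (the rank deficiency of the
# pairwise-difference ICAR precision; islands carry a proper prior instead)
n_nonisland_components <- function(nb) {
  m <- adjacency_components(nb)
  if (!length(m)) return(0L)
  as.integer(sum(table(m) >= 2L))
}

#' Validate a two-level geography
#'
#' Checks every structural invariant of a [multiscale_geography()]: symmetric
#' and irreflexive adjacency at both levels, a total single-parent nesting
#' map whose child sets partition the fine units, every coarse unit
#' non-empty, and N1 >= N2 >= 1. Also counts the connected components of
#' each level's adjacency graph (needed for the ICAR rank correction) and
#' flags islands.
#'
#' @param geog A `multiscale_geography`.
#' @return An object of class `geography_validation`: list with `violations`
#'   (character vector, empty iff valid), `components` (named integer vector,
#'   fine and coarse component counts) and `islands` (list of island ids per
#'   level).
#' @export
validate_geography <- function(geog) {
  v <- character(0)
  for (lev in c("fine", "coarse")) {
    nb <- geog[[paste0(lev, "_adjacency")]]
    ids <- names(nb)
    for (i in ids) {
      if (i %in% nb[[i]]) {
        v <- c(v, sprintf("%s level: unit '%s' is its own neighbor", lev, i))
      }
      for (j in setdiff(nb[[i]], i)) {
        if (!(j %in% ids)) {
          v <- c(v, sprintf("%s level: unknown neighbor '%s' of '%s'",
                            lev, j, i))
        } else if (!(i %in% nb[[j]])) {
          v <- c(v, sprintf("%s level: asymmetric pair %s->%s", lev, i, j))
        }
      }
    }
  }
  n1 <- length(geog$fine_ids)
  n2 <- length(geog$coarse_ids)
  if (!(n1 >= n2 && n2 >= 1L)) {
    v <- c(v, sprintf("level sizes violate N1 >= N2 >= 1 (N1=%d, N2=%d)",
                      n1, n2))
  }
  if (anyNA(geog$parent_index)) {
    v <- c(v, "nesting map contains parents outside the coarse level")
  }
  empty <- names(geog$children)[vapply(geog$children, length, integer(1)) == 0L]
  if (length(empty)) {
    v <- c(v, paste0("coarse unit(s) with no children: ",
                     paste(empty, collapse = ", ")))
  }
  covered <- sort(unlist(geog$children, use.names = FALSE))
  if (!identical(covered, sort(geog$fine_ids))) {
    v <- c(v, "child sets do not partition the fine units")
  }
  comp <- c(
    fine = max(c(0L, adjacency_components(geog$fine_adjacency))),
    coarse = max(c(0L, adjacency_components(geog$coarse_adjacency)))
  )
  structure(
    list(
      violations = v,
      components = comp,
      islands = list(fine = attr(geog$fine_adjacency, "islands"),
                     coarse = attr(geog$coarse_adjacency, "islands"))
    ),
    class = "geography_validation"
  )
}

#' @export
print.geography_validation <- function(x, ...) {
  if (length(x$violations) == 0L) {
    cat("geography valid;")
  } else {
    cat("geography INVALID:\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  cat(sprintf(" components: fine=%d coarse=%d\n",
              x$components[["fine"]], x$components[["coarse"]]))
  invisible(x)
}

#' Aggregate fine-level values to the coarse level
#'
#' Coarse outcomes in nested administrative data are sums of the outcomes of
#' the units nested within them (case and birth counts), while covariates
#' such as median household income are averaged. `aggregate_to_coarse`
#' performs either reduction over each coarse unit's child set.
#'
#' @param values Numeric vector of fine-level values, either named by fine id
#'   or in canonical fine order.
#' @param geog A `multiscale_geography`.
#' @param mode `"sum"` or `"mean"`.
#' @return Numeric vector in canonical coarse order, named by coarse id.
#' @export
aggregate_to_coarse <- function(values, geog, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (!is.null(names(values))) {
    missing <- setdiff(geog$fine_ids, names(values))
    if (length(missing)) {
      stop("missing value for fine unit(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    values <- values[geog$fine_ids]
  } else if (length(values) != length(geog$fine_ids)) {
    stop(sprintf("expected %d fine-level values, got %d",
                 length(geog$fine_ids), length(values)), call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing value for fine unit(s): ",
         paste(geog$fine_ids[is.na(values)], collapse = ", "), call. = FALSE)
  }
  f <- factor(unname(geog$parent), levels = geog$coarse_ids)
  out <- rowsum(as.numeric(values), f)[, 1L]
  if (mode == "mean") {
    out <- out / vapply(geog$children, length, integer(1))
  }
  stats::setNames(out[geog$coarse_ids], geog$coarse_ids)
}
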