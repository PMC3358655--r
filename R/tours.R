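# Alternating Eulerian tours of the interval-adjacency multigraph G_mu.
# A tour alternates interval and non-interval edges, so it spells a block
# sequence of the rearranged genome; tours begin and end at telomeric
# vertices, and balanced telomere-free remainders are emitted as closed
# cycles.

.mu_vector <- function(graph, mu) {
  if (inherits(mu, "multiplicity_assignment")) mu <- mu$mu
  stopifnot(length(mu) == nrow(graph$edges), all(mu >= 0),
            all(mu == round(mu)))
  as.integer(mu)
}

#' Is a multiplicity assignment Eulerizable?
#'
#' True iff the balance residuals vanish at every non-telomeric vertex, i.e.
#' the multigraph with edge multiplicities `mu` decomposes into alternating
#' tours that begin and end at telomeric vertices. Diagnostics list the
#' violating vertices and any connected component of the positive-`mu`
#' support that contains no telomeric vertex (such components admit only
#' closed cycles).
#'
#' @param graph an [`iagraph`][build_graph].
#' @param mu a `"multiplicity_assignment"` or numeric vector aligned with
#'   `graph$edges`.
#' @return list with `eulerizable` (logical), `unbalanced_vertices`
#'   (labels), `cycle_only_components` (list of vertex-label sets).
#' @export
is_eulerizable <- function(graph, mu) {
  mu <- .mu_vector(graph, mu)
  res <- balance_residuals(graph, mu)
  unbalanced <- names(res)[res != 0]

  # connected components of the mu > 0 support without a telomeric vertex
  ed <- graph$edges[mu > 0, , drop = FALSE]
  comp <- list()
  if (nrow(ed)) {
    vids <- sort(unique(c(ed$v1, ed$v2)))
    parent <- seq_along(vids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(ed))) {
      a <- find(match(ed$v1[k], vids)); b <- find(match(ed$v2[k], vids))
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_along(vids), find, integer(1))
    tel <- graph$vertices$telomeric[match(vids, graph$vertices$vid)]
    for (rt in unique(roots)) {
      members <- vids[roots == rt]
      if (!any(tel[roots == rt]))
        comp[[length(comp) + 1L]] <-
          graph$vertices$label[match(members, graph$vertices$vid)]
    }
  }
  list(eulerizable = length(unbalanced) == 0,
       unbalanced_vertices = unbalanced,
       cycle_only_components = comp)
}

# signed block for traversing interval edge of interval j starting at vertex v
.signed_block <- function(j, from_side) if (from_side == "s") j else -j

#' Extract alternating Eulerian tours
#'
#' Hierholzer-style construction: every arrival at a vertex via a
#' non-interval edge departs via the vertex's interval edge and vice versa.
#' Open tours are seeded at telomeric vertices (in graph order) while any
#' telomeric vertex has an excess of one edge type; remaining multiplicity
#' in telomere-free balanced components is emitted as closed cycles (with a
#' warning). Every edge `e` is traversed exactly `mu(e)` times in total.
#'
#' @param graph an [`iagraph`][build_graph].
#' @param mu a `"multiplicity_assignment"` or numeric vector aligned with
#'   `graph$edges`; must be Eulerizable.
#' @param seed optional integer; when given, the departing non-interval edge
#'   at branch vertices is chosen uniformly at random instead of
#'   lowest-edge-id-first.
#' @return an object of class `"tour_decomposition"`: list with `tours` and
#'   `leftover_cycles`, each a list of block sequences (elements `blocks` =
#'   signed interval indices, `edge_path` = edge ids traversed,
#'   `start_vertex`, `end_vertex`, `closed`).
#' @export
extract_tours <- function(graph, mu, seed = NULL) {
  mu <- .mu_vector(graph, mu)
  chk <- is_eulerizable(graph, mu)
  if (!chk$eulerizable)
    stop("assignment is not Eulerizable (unbalanced at: ",
         paste(chk$unbalanced_vertices, collapse = ", "), ")")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  ed <- graph$edges
  rem <- mu
  vx <- graph$vertices
  nvert <- nrow(vx)
  # per-vertex incidence: the interval edge and the non-interval edges
  iedge <- rep(NA_integer_, nvert)   # row in ed
  nonI <- vector("list", nvert)
  for (k in seq_len(nrow(ed))) {
    a <- match(ed$v1[k], vx$vid); b <- match(ed$v2[k], vx$vid)
    if (ed$type[k] == "I") {
      iedge[a] <- k; iedge[b] <- k
    } else {
      nonI[[a]] <- c(nonI[[a]], k)
      if (b != a) nonI[[b]] <- c(nonI[[b]], k)
    }
  }

  pick_nonI <- function(vrow) {
    cand <- nonI[[vrow]]
    cand <- cand[rem[cand] > 0]
    if (!length(cand)) return(NA_integer_)
    if (is.null(seed)) min(cand) else cand[sample.int(length(cand), 1)]
  }

  walk <- function(vrow, expect) {
    blocks <- integer(0); path <- integer(0)
    start_label <- vx$label[vrow]
    repeat {
      if (expect == "I") {
        k <- iedge[vrow]
        if (is.na(k) || rem[k] == 0) break
        rem[k] <<- rem[k] - 1L
        path <- c(path, ed$id[k])
        j <- ed$interval[k]
        blocks <- c(blocks, .signed_block(j, vx$side[vrow]))
        vrow <- match(if (ed$v1[k] == vx$vid[vrow]) ed$v2[k] else ed$v1[k],
                      vx$vid)
        expect <- "N"
      } else {
        k <- pick_nonI(vrow)
        if (is.na(k)) break
        rem[k] <<- rem[k] - 1L
        path <- c(path, ed$id[k])
        if (ed$v1[k] != ed$v2[k])
          vrow <- match(if (ed$v1[k] == vx$vid[vrow]) ed$v2[k] else ed$v1[k],
                        vx$vid)
        expect <- "I"
      }
    }
    list(blocks = blocks, edge_path = path, start_vertex = start_label,
         end_vertex = vx$label[vrow], closed = FALSE)
  }

  excess <- function(vrow) {
    a <- if (is.na(iedge[vrow])) 0L else rem[iedge[vrow]]
    b <- sum(rem[nonI[[vrow]]])
    a - b
  }

  tours <- list()
  tel_rows <- which(vx$telomeric)
  repeat {
    started <- FALSE
    for (vrow in tel_rows) {
      while (excess(vrow) > 0) {
        tours[[length(tours) + 1L]] <- walk(vrow, "I"); started <- TRUE
      }
      while (excess(vrow) < 0) {
        tours[[length(tours) + 1L]] <- walk(vrow, "N"); started <- TRUE
      }
    }
    if (!started) break
  }

  cycles <- list()
  repeat {
    cand <- which(!is.na(iedge))
    cand <- cand[rem[iedge[cand]] > 0]
    if (!length(cand)) break
    cyc <- walk(cand[1], "I")
    cyc$closed <- TRUE
    cycles[[length(cycles) + 1L]] <- cyc
  }
  if (any(rem > 0))
    stop("internal error: undistributed multiplicity remains")
  if (length(cycles))
    warning(length(cycles),
            " balanced telomere-free component(s) emitted as closed cycles")

  structure(list(tours = tours, leftover_cycles = cycles),
            class = "tour_decomposition")
}

#' @export
print.tour_decomposition <- function(x, graph = NULL, ...) {
  cat("Tour decomposition:", length(x$tours), "open tour(s),",
      length(x$leftover_cycles), "closed cycle(s)\n")
  nm <- if (!is.null(graph)) graph$intervals$name else NULL
  for (t in x$tours)
    cat(" ", spell_genome(t, names = nm), "\n")
  for (t in x$leftover_cycles)
    cat(" ", spell_genome(t, names = nm), "(cycle)\n")
  invisible(x)
}

#' Spell the block sequence of a tour
#'
#' Renders the signed blocks of a tour as text, e.g. `"A -B C D C D"`:
#' a block traversed against reference orientation is prefixed with `-`.
#' Reversing a tour renders the sign-flipped mirror of the sequence.
#'
#' @param tour a block sequence from [extract_tours()] (or a bare vector of
#'   signed interval indices).
#' @param names optional character vector of interval names (position =
#'   interval index); indices are printed when missing.
#' @return a single string (empty for an empty tour).
#' @export
spell_genome <- function(tour, names = NULL) {
  blocks <- if (is.list(tour)) tour$blocks else tour
  if (!length(blocks)) return("")
  lab <- if (is.null(names)) as.character(abs(blocks)) else names[abs(blocks)]
  paste(ifelse(blocks < 0, paste0("-", lab), lab), collapse = " ")
}

#' Reverse a tour
#'
#' @param tour a block sequence from [extract_tours()].
#' @return the tour traversed in the opposite direction (blocks reversed and
#'   sign-flipped).
#' @export
reverse_tour <- function(tour) {
  if (is.list(tour)) {
    out <- tour
    out$blocks <- rev(-tour$blocks)
    out$edge_path <- rev(tour$edge_path)
    out$start_vertex <- tour$end_vertex
    out$end_vertex <- tour$start_vertex
    out
  } else rev(-tour)
}

#' Per-edge traversal counts of a tour decomposition
#'
#' @param decomposition a `"tour_decomposition"`.
#' @param graph the graph it was extracted from.
#' @return integer vector aligned with `graph$edges`: how many times each
#'   edge is traversed over all tours and cycles.
#' @export
tour_edge_counts <- function(decomposition, graph) {
  counts <- integer(nrow(graph$edges))
  for (t in c(decomposition$tours, decomposition$leftover_cycles)) {
    tb <- tabulate(match(t$edge_path, graph$edges$id), nrow(graph$edges))
    counts <- counts + tb
  }
  counts
}
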