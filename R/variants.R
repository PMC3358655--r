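# Classification of variant edges: geometry, reciprocal partnerships,
# triviality, and the usage-association test.

.edge_row <- function(graph, edge) {
  if (length(edge) == 1 && is.numeric(edge)) {
    k <- match(edge, graph$edges$id)
    if (is.na(k)) stop("no edge with id ", edge)
    return(k)
  }
  stop("edge must be an edge id")
}

# endpoint descriptors: interval index, side, chrom (NA for sigma vertices)
.endpoint_info <- function(graph, vid) {
  k <- match(vid, graph$vertices$vid)
  list(interval = graph$vertices$interval[k], side = graph$vertices$side[k],
       chrom = graph$vertices$chrom[k], sigma = graph$vertices$sigma[k])
}

#' Classify the geometry of a variant edge
#'
#' Assigns each variant edge the rearrangement geometry implied by its
#' endpoint orientations: intra-chromosomal `t_p`--`s_q` (forward) edges are
#' deletion-type, `s_p`--`t_q` (back) edges tandem-duplication-type,
#' same-side (`t`--`t` or `s`--`s`) edges inversion-type, and self-junctions
#' inverted-repeat loops (the breakage/fusion/bridge signature).
#' Inter-chromosomal edges with opposite end types are classical
#' translocations; with matching end types, Robertsonian translocations.
#' Telomere-loss edges are reported as `"telomere-loss"`, not classified.
#'
#' @param graph an [`iagraph`][build_graph].
#' @param edge a variant edge id (or vector of ids).
#' @return character vector of geometries.
#' @export
classify_geometry <- function(graph, edge) {
  vapply(edge, function(e) {
    k <- .edge_row(graph, e)
    if (graph$edges$type[k] != "V")
      stop("edge ", e, " is not a variant edge")
    a <- .endpoint_info(graph, graph$edges$v1[k])
    b <- .endpoint_info(graph, graph$edges$v2[k])
    if (isTRUE(a$sigma) || isTRUE(b$sigma)) return("telomere-loss")
    if (graph$edges$v1[k] == graph$edges$v2[k]) return("inverted-repeat-loop")
    if (a$chrom == b$chrom) {
      # canonical order guarantees a$interval <= b$interval
      if (a$side == b$side) return("inversion-type")
      if (a$side == "t" && b$side == "s") return("deletion-type")
      return("tandem-duplication-type")
    }
    if (a$side != b$side) return("classical-translocation")
    "Robertsonian-translocation"
  }, character(1))
}

# breakpoint of a vertex: the boundary it sits on, identified by the index
# of the interval to the left of the cut; NA for chromosome-terminal and
# sigma vertices. t_p -> breakpoint p (left flank), s_{p+1} -> breakpoint p
# (right flank).
.vertex_breakpoint <- function(graph, vid) {
  k <- match(vid, graph$vertices$vid)
  v <- graph$vertices[k, ]
  if (isTRUE(v$sigma)) return(c(bp = NA_integer_, flank = NA_integer_))
  iv <- graph$intervals
  j <- v$interval
  chrom_idx <- iv$index[iv$chrom == iv$chrom[j]]
  if (v$side == "t") {
    if (j == max(chrom_idx)) return(c(bp = NA_integer_, flank = NA_integer_))
    return(c(bp = j, flank = 0L))              # left flank of breakpoint j
  }
  if (j == min(chrom_idx)) return(c(bp = NA_integer_, flank = NA_integer_))
  c(bp = j - 1L, flank = 1L)                   # right flank of breakpoint j-1
}

#' Find reciprocal partnerships among variant edges
#'
#' Two variant edges are partners when their four endpoints cover the four
#' vertices \eqn{\{t_p, s_{p+1}, t_q, s_{q+1}\}} of the same two breakpoints
#' with no endpoint shared (e.g. the two junctions of a reciprocal
#' translocation or inversion). When several pairings are possible at a
#' breakpoint the lexicographically smallest pair of edge ids is chosen;
#' every other variant edge is non-reciprocal.
#'
#' @param graph an [`iagraph`][build_graph].
#' @return data frame with one row per partnership: `edge1`, `edge2`
#'   (edge ids, `edge1 < edge2`), and the two breakpoint left-interval
#'   indices `p` and `q`.
#' @export
find_reciprocal_pairs <- function(graph) {
  ed <- graph$edges
  vrows <- which(ed$type == "V" & ed$v1 != ed$v2)
  info <- lapply(vrows, function(k) {
    sig <- graph$vertices$sigma[match(c(ed$v1[k], ed$v2[k]),
                                      graph$vertices$vid)]
    if (any(sig)) return(NULL)
    b1 <- .vertex_breakpoint(graph, ed$v1[k])
    b2 <- .vertex_breakpoint(graph, ed$v2[k])
    if (is.na(b1["bp"]) || is.na(b2["bp"]) || b1["bp"] == b2["bp"])
      return(NULL)
    # order the two breakpoints so the key is canonical
    if (b1["bp"] > b2["bp"]) { tmp <- b1; b1 <- b2; b2 <- tmp }
    data.frame(edge = ed$id[k], p = b1["bp"], q = b2["bp"],
               fp = b1["flank"], fq = b2["flank"])
  })
  info <- do.call(rbind, info)
  out <- data.frame(edge1 = integer(0), edge2 = integer(0),
                    p = integer(0), q = integer(0))
  if (is.null(info) || nrow(info) < 2) return(out)
  key <- paste(info$p, info$q)
  for (kk in unique(key)) {
    grp <- info[key == kk, , drop = FALSE]
    grp <- grp[order(grp$edge), ]
    taken <- rep(FALSE, nrow(grp))
    for (i in seq_len(nrow(grp))) {
      if (taken[i]) next
      # partner must take the opposite flank at both breakpoints
      js <- which(!taken & grp$fp != grp$fp[i] & grp$fq != grp$fq[i])
      js <- js[js > i]
      if (length(js)) {
        j <- js[1]
        taken[i] <- taken[j] <- TRUE
        out <- rbind(out, data.frame(edge1 = grp$edge[i], edge2 = grp$edge[j],
                                     p = grp$p[i], q = grp$q[i]))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Is a reciprocal pair trivial?
#'
#' A reciprocal pair is trivial when the two variant edges have equal
#' multiplicities and both flanking interval-edge pairs have equal
#' multiplicities: \eqn{\mu(A) = \mu(A')}, \eqn{\mu(I_p) = \mu(I_{p+1})} and
#' \eqn{\mu(I_q) = \mu(I_{q+1})}. Zeroing both edges of a trivial pair and
#' adding their multiplicity to the two incident reference edges leaves the
#' likelihood objective and the balance constraints unchanged.
#'
#' @param graph an [`iagraph`][build_graph].
#' @param pair one row of [find_reciprocal_pairs()] output (or a list with
#'   `edge1`, `edge2`, `p`, `q`).
#' @param mu a `"multiplicity_assignment"` or numeric vector aligned with
#'   `graph$edges`.
#' @return logical.
#' @export
is_trivial <- function(graph, pair, mu) {
  mu <- .mu_vector(graph, mu)
  e1 <- match(pair$edge1, graph$edges$id)
  e2 <- match(pair$edge2, graph$edges$id)
  iid <- .interval_edge_ids(graph)
  mu_I <- mu[match(iid, graph$edges$id)]
  p <- as.integer(pair$p); q <- as.integer(pair$q)
  mu[e1] == mu[e2] && mu_I[p] == mu_I[p + 1] && mu_I[q] == mu_I[q + 1]
}

#' Annotate variant edges
#'
#' Combines geometry classification, reciprocal partnership, triviality and
#' usage (`mu > 0`) into one table.
#'
#' @param graph an [`iagraph`][build_graph].
#' @param mu a `"multiplicity_assignment"` or numeric vector aligned with
#'   `graph$edges`.
#' @return data frame with columns `edge`, `geometry`, `reciprocal_partner`,
#'   `trivial` (NA for non-reciprocal edges), `used`, `mu`.
#' @export
annotate_variants <- function(graph, mu) {
  mu <- .mu_vector(graph, mu)
  vrows <- which(graph$edges$type == "V")
  if (!length(vrows))
    return(data.frame(edge = integer(0), geometry = character(0),
                      reciprocal_partner = integer(0), trivial = logical(0),
                      used = logical(0), mu = integer(0)))
  ids <- graph$edges$id[vrows]
  pairs <- find_reciprocal_pairs(graph)
  partner <- rep(NA_integer_, length(ids))
  trivial <- rep(NA, length(ids))
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      tr <- is_trivial(graph, pairs[i, ], mu)
      k1 <- match(pairs$edge1[i], ids); k2 <- match(pairs$edge2[i], ids)
      partner[k1] <- pairs$edge2[i]; partner[k2] <- pairs$edge1[i]
      trivial[k1] <- trivial[k2] <- tr
    }
  }
  data.frame(edge = ids,
             geometry = classify_geometry(graph, ids),
             reciprocal_partner = partner, trivial = trivial,
             used = mu[vrows] > 0, mu = mu[vrows])
}

#' Two-sided Fisher exact test of a 2x2 usage table
#'
#' Tests association between rows (non-trivial reciprocal vs non-reciprocal)
#' and columns (used vs unused) by summation of hypergeometric probabilities
#' no larger than the observed table's.
#'
#' @param tab 2x2 matrix of counts: rows = (non-trivial reciprocal,
#'   non-reciprocal), columns = (used, unused).
#' @return list with `p` and `degenerate` (TRUE when a margin is empty, in
#'   which case `p = 1`).
#' @export
usage_fisher_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(tab)$p.value, degenerate = FALSE)
}

#' Association between reciprocality and usage, per variant class
#'
#' For each geometry class, builds the 2x2 table of (non-trivial reciprocal
#' vs non-reciprocal) by (used vs unused) variant edges and computes the
#' two-sided Fisher exact p-value; trivial reciprocal pairs are excluded
#' from the reciprocal rows but reported in the `R_all` columns.
#'
#' @param annotations output of [annotate_variants()].
#' @param classes geometry classes to test (default: inversions and the two
#'   translocation classes, each tested separately).
#' @return data frame with per-class counts `R_all_used`, `R_all_unused`,
#'   `R_nontriv_used`, `R_nontriv_unused`, `NR_used`, `NR_unused`, the
#'   Fisher `p_value`, and a `degenerate` flag (empty margin, p reported
#'   as 1).
#' @export
usage_association_test <- function(annotations,
                                   classes = c("inversion-type",
                                               "classical-translocation",
                                               "Robertsonian-translocation")) {
  out <- lapply(classes, function(cl) {
    a <- annotations[annotations$geometry == cl, , drop = FALSE]
    rec <- !is.na(a$reciprocal_partner)
    nontriv <- rec & !a$trivial
    nonrec <- !rec
    tab <- matrix(c(sum(nontriv & a$used), sum(nontriv & !a$used),
                    sum(nonrec & a$used), sum(nonrec & !a$used)),
                  2, 2, byrow = TRUE)
    ft <- usage_fisher_test(tab)
    data.frame(class = cl,
               R_all_used = sum(rec & a$used),
               R_all_unused = sum(rec & !a$used),
               R_nontriv_used = tab[1, 1], R_nontriv_unused = tab[1, 2],
               NR_used = tab[2, 1], NR_unused = tab[2, 2],
               p_value = ft$p, degenerate = ft$degenerate)
  })
  do.call(rbind, out)
}
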