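# Interval-adjacency model: reference partitioning, adjacency filtering and
# construction of the (multichromosomal) interval-adjacency graph.
#
# Coordinates are 0-based half-open internally; conversion to/from 1-based
# inclusive happens only in the I/O layer (see read_clusters()).

# vertex id convention: interval j has start vertex 2j-1 and end vertex 2j;
# sigma vertices (telomere loss) are appended after 2n.
.vid <- function(index, side) as.integer(2L * index - (side == "s"))

.check_chrom_lengths <- function(chrom_lengths) {
  if (is.numeric(chrom_lengths) && !is.null(names(chrom_lengths))) {
    chrom_lengths <- data.frame(chrom = names(chrom_lengths),
                                length = as.numeric(chrom_lengths),
                                stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chrom_lengths),
            all(c("chrom", "length") %in% names(chrom_lengths)))
  if (anyDuplicated(chrom_lengths$chrom))
    stop("duplicated chromosome names in chrom_lengths")
  if (any(chrom_lengths$length <= 0))
    stop("chromosome lengths must be positive")
  chrom_lengths
}

#' Partition the reference genome at adjacency breakpoints
#'
#' Cuts each chromosome at the breakpoint coordinates of the supplied
#' adjacencies, producing a tiling sequence of intervals. Breakpoints that
#' would create an interval shorter than `min_interval_len` are rejected and
#' the adjacencies that depend on them are dropped (when two breakpoints are
#' too close, the later one in coordinate order loses). Interval indices are
#' global and consecutive within each chromosome, in the order chromosomes
#' appear in `chrom_lengths`.
#'
#' @param chrom_lengths data frame with columns `chrom` and `length` (or a
#'   named numeric vector) giving reference chromosome lengths in bases.
#' @param adjacencies data frame of candidate novel adjacencies with columns
#'   `chrom1`, `cut1`, `side1`, `chrom2`, `cut2`, `side2`, `support`
#'   (0-based cut coordinates; sides in `{"s","e"}`), as returned by
#'   [read_clusters()] or [filter_adjacencies()]. May be `NULL` or empty.
#' @param min_interval_len minimum interval length in bases (default 8000);
#'   shorter intervals are not allowed to form.
#' @return an object of class `"prego_partition"`: a list with elements
#'   `intervals` (data frame `chrom`, `start`, `end`, `index`, `length`,
#'   `name`), `adjacencies` (surviving adjacencies mapped to
#'   `(index, side)` endpoint pairs), `dropped` (dropped adjacencies with a
#'   `reason` column) and `chrom_lengths`.
#' @seealso [build_graph()], [filter_adjacencies()]
#' @export
partition_reference <- function(chrom_lengths, adjacencies = NULL,
                                min_interval_len = 8000) {
  chrom_lengths <- .check_chrom_lengths(chrom_lengths)
  stopifnot(min_interval_len >= 1)
  if (is.null(adjacencies))
    adjacencies <- empty_adjacencies()
  if (nrow(adjacencies) > 0) {
    if (is.null(adjacencies$id)) adjacencies$id <- seq_len(nrow(adjacencies))
    bad <- !(adjacencies$chrom1 %in% chrom_lengths$chrom) |
           !(adjacencies$chrom2 %in% chrom_lengths$chrom)
    if (any(bad))
      stop("unknown chromosome name in adjacencies: ",
           paste(unique(c(adjacencies$chrom1[bad], adjacencies$chrom2[bad])),
                 collapse = ", "))
    len1 <- chrom_lengths$length[match(adjacencies$chrom1, chrom_lengths$chrom)]
    len2 <- chrom_lengths$length[match(adjacencies$chrom2, chrom_lengths$chrom)]
    out1 <- adjacencies$cut1 < 0 | adjacencies$cut1 > len1
    out2 <- adjacencies$cut2 < 0 | adjacencies$cut2 > len2
    if (any(out1 | out2))
      stop("breakpoint coordinate outside chromosome (adjacency id ",
           paste(adjacencies$id[out1 | out2], collapse = ", "), ")")
    if (!all(adjacencies$side1 %in% c("s", "e")) ||
        !all(adjacencies$side2 %in% c("s", "e")))
      stop("adjacency sides must be 's' or 'e'")
    # an end-side breakpoint needs a segment ending at the cut, a start-side
    # one a segment beginning there
    deg <- (adjacencies$side1 == "e" & adjacencies$cut1 == 0) |
           (adjacencies$side1 == "s" & adjacencies$cut1 == len1) |
           (adjacencies$side2 == "e" & adjacencies$cut2 == 0) |
           (adjacencies$side2 == "s" & adjacencies$cut2 == len2)
    if (any(deg))
      stop("breakpoint side incompatible with chromosome boundary ",
           "(adjacency id ", paste(adjacencies$id[deg], collapse = ", "), ")")
  }

  # greedy left-to-right acceptance of cut coordinates per chromosome
  rejected_cuts <- list()
  accepted_cuts <- list()
  for (k in seq_len(nrow(chrom_lengths))) {
    chrom <- chrom_lengths$chrom[k]
    len <- chrom_lengths$length[k]
    cuts <- sort(unique(c(
      adjacencies$cut1[adjacencies$chrom1 == chrom],
      adjacencies$cut2[adjacencies$chrom2 == chrom])))
    # chromosome boundaries are existing interval ends, never new cuts
    cuts <- cuts[cuts > 0 & cuts < len]
    acc <- numeric(0)
    prev <- 0
    rej <- numeric(0)
    for (cut in cuts) {
      if (cut - prev >= min_interval_len && len - cut >= min_interval_len) {
        acc <- c(acc, cut)
        prev <- cut
      } else {
        rej <- c(rej, cut)
      }
    }
    accepted_cuts[[chrom]] <- acc
    rejected_cuts[[chrom]] <- rej
  }

  dropped <- NULL
  if (nrow(adjacencies) > 0) {
    uses_rejected <- mapply(function(c1, x1, c2, x2) {
      x1 %in% rejected_cuts[[c1]] || x2 %in% rejected_cuts[[c2]]
    }, adjacencies$chrom1, adjacencies$cut1,
       adjacencies$chrom2, adjacencies$cut2)
    dropped <- adjacencies[uses_rejected, , drop = FALSE]
    if (nrow(dropped)) dropped$reason <- "min-interval"
    adjacencies <- adjacencies[!uses_rejected, , drop = FALSE]
    # accepted cuts no longer referenced by any surviving adjacency are removed
    for (chrom in names(accepted_cuts)) {
      used <- c(adjacencies$cut1[adjacencies$chrom1 == chrom],
                adjacencies$cut2[adjacencies$chrom2 == chrom])
      accepted_cuts[[chrom]] <-
        accepted_cuts[[chrom]][accepted_cuts[[chrom]] %in% used]
    }
  }

  # intervals tile each chromosome between consecutive accepted cuts
  ivs <- lapply(seq_len(nrow(chrom_lengths)), function(k) {
    chrom <- chrom_lengths$chrom[k]
    b <- c(0, accepted_cuts[[chrom]], chrom_lengths$length[k])
    data.frame(chrom = chrom, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, ivs)
  intervals$index <- seq_len(nrow(intervals))
  intervals$length <- intervals$end - intervals$start
  intervals$name <- as.character(intervals$index)
  rownames(intervals) <- NULL

  # map adjacency breakpoints to (interval index, side) endpoints
  if (nrow(adjacencies) > 0) {
    map_end <- function(chrom, cut, side) {
      if (side == "e") {
        j <- which(intervals$chrom == chrom & intervals$end == cut)
      } else {
        j <- which(intervals$chrom == chrom & intervals$start == cut)
      }
      if (length(j) != 1)
        stop("breakpoint does not match an interval boundary (", chrom, ":",
             cut, " side ", side, ")")
      intervals$index[j]
    }
    adjacencies$index1 <- mapply(map_end, adjacencies$chrom1,
                                 adjacencies$cut1, adjacencies$side1)
    adjacencies$index2 <- mapply(map_end, adjacencies$chrom2,
                                 adjacencies$cut2, adjacencies$side2)
    # canonical endpoint order so every adjacency has a unique key
    v1 <- .vid(adjacencies$index1, ifelse(adjacencies$side1 == "s", "s", "t"))
    v2 <- .vid(adjacencies$index2, ifelse(adjacencies$side2 == "s", "s", "t"))
    swap <- v1 > v2
    if (any(swap)) {
      tmp <- adjacencies[swap, c("chrom1", "cut1", "side1", "index1")]
      adjacencies[swap, c("chrom1", "cut1", "side1", "index1")] <-
        adjacencies[swap, c("chrom2", "cut2", "side2", "index2")]
      adjacencies[swap, c("chrom2", "cut2", "side2", "index2")] <- tmp
    }
  } else {
    adjacencies$index1 <- integer(0)
    adjacencies$index2 <- integer(0)
  }
  if (is.null(adjacencies$source) && nrow(adjacencies) >= 0)
    adjacencies$source <- rep("measured", nrow(adjacencies))

  structure(list(intervals = intervals, adjacencies = adjacencies,
                 dropped = dropped, chrom_lengths = chrom_lengths),
            class = "prego_partition")
}

#' @export
print.prego_partition <- function(x, ...) {
  cat("Reference partition:", nrow(x$intervals), "intervals on",
      nrow(x$chrom_lengths), "chromosomes;",
      nrow(x$adjacencies), "adjacencies",
      if (!is.null(x$dropped) && nrow(x$dropped))
        paste0("(", nrow(x$dropped), " dropped)") else "", "\n")
  invisible(x)
}

#' An empty adjacency table with the canonical columns
#' @return zero-row data frame with the adjacency columns.
#' @export
empty_adjacencies <- function() {
  data.frame(id = integer(0), chrom1 = character(0), cut1 = numeric(0),
             side1 = character(0), chrom2 = character(0), cut2 = numeric(0),
             side2 = character(0), support = numeric(0),
             source = character(0), stringsAsFactors = FALSE)
}

.breakpoint_centromere_dist <- function(chrom, cut, centromeres) {
  rows <- centromeres[centromeres$chrom == chrom, , drop = FALSE]
  if (nrow(rows) == 0) return(Inf)
  min(pmax(0, rows$start - cut, cut - rows$end))
}

#' Filter candidate adjacency clusters
#'
#' Applies the somatic-call filters to clusters of discordant read pairs:
#' minimum supporting-pair count, minimum distance of both breakpoints from
#' annotated centromeres, and removal of clusters that coincide with a
#' cluster from the matched normal sample (coordinate overlap within
#' `normal_slop` bases on both breakpoints, with matching breakpoint sides).
#'
#' @param clusters data frame of candidate adjacencies (see
#'   [read_clusters()]).
#' @param min_support minimum number of supporting discordant pairs
#'   (default 5).
#' @param centromeres optional data frame `chrom`, `start`, `end` of
#'   centromere regions (0-based half-open); `NULL` disables the filter.
#' @param centromere_margin minimum distance in bases of each breakpoint from
#'   any centromere region (default 1e6).
#' @param normal_clusters optional data frame of clusters from the matched
#'   normal sample in the same format; tumor clusters matching one are
#'   removed.
#' @param normal_slop coordinate tolerance in bases for matching a normal
#'   cluster (default 1000).
#' @param verbose if `TRUE`, print one line per dropped cluster naming the
#'   filter that removed it.
#' @return the surviving clusters, with the dropped rows (and a `reason`
#'   column) available as `attr(, "dropped")`.
#' @export
filter_adjacencies <- function(clusters, min_support = 5, centromeres = NULL,
                               centromere_margin = 1e6,
                               normal_clusters = NULL, normal_slop = 1000,
                               verbose = FALSE) {
  if (is.null(clusters) || nrow(clusters) == 0) {
    out <- empty_adjacencies()
    attr(out, "dropped") <- empty_adjacencies()
    return(out)
  }
  if (is.null(clusters$id)) clusters$id <- seq_len(nrow(clusters))
  reason <- rep(NA_character_, nrow(clusters))

  low <- clusters$support < min_support
  reason[low & is.na(reason)] <- "support"

  if (!is.null(centromeres) && nrow(centromeres) > 0) {
    near <- vapply(seq_len(nrow(clusters)), function(i) {
      d1 <- .breakpoint_centromere_dist(clusters$chrom1[i], clusters$cut1[i],
                                        centromeres)
      d2 <- .breakpoint_centromere_dist(clusters$chrom2[i], clusters$cut2[i],
                                        centromeres)
      min(d1, d2) < centromere_margin
    }, logical(1))
    reason[near & is.na(reason)] <- "centromere"
  }

  if (!is.null(normal_clusters) && nrow(normal_clusters) > 0) {
    in_normal <- vapply(seq_len(nrow(clusters)), function(i) {
      hit <- normal_clusters$chrom1 == clusters$chrom1[i] &
        normal_clusters$chrom2 == clusters$chrom2[i] &
        normal_clusters$side1 == clusters$side1[i] &
        normal_clusters$side2 == clusters$side2[i] &
        abs(normal_clusters$cut1 - clusters$cut1[i]) <= normal_slop &
        abs(normal_clusters$cut2 - clusters$cut2[i]) <= normal_slop
      any(hit)
    }, logical(1))
    reason[in_normal & is.na(reason)] <- "normal-overlap"
  }

  dropped <- clusters[!is.na(reason), , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!is.na(reason)]
  if (verbose && nrow(dropped))
    for (i in seq_len(nrow(dropped)))
      message("dropped cluster ", dropped$id[i], ": ", dropped$reason[i])
  kept <- clusters[is.na(reason), , drop = FALSE]
  attr(kept, "dropped") <- dropped
  kept
}

#' Build the interval-adjacency graph
#'
#' Constructs the multichromosomal interval-adjacency graph from a reference
#' partition: one interval edge \eqn{(s_j, t_j)} per interval, one reference
#' edge \eqn{(t_j, s_{j+1})} per pair of consecutive intervals on the same
#' chromosome, and one variant edge per accepted novel adjacency (endpoint
#' side `"s"` maps to the start vertex, `"e"` to the end vertex). Identical
#' adjacencies are collapsed to a single variant edge with summed support.
#' The telomeric vertex set `T` consists of the two terminal vertices of each
#' chromosome.
#'
#' @param intervals a `"prego_partition"` object, or the `intervals` data
#'   frame from one.
#' @param adjacencies adjacency data frame with `index1`, `side1`, `index2`,
#'   `side2`, `support` columns; ignored when `intervals` is a partition
#'   (taken from it).
#' @return an object of class `"iagraph"`: a list with `intervals`,
#'   `vertices` (with `telomeric` and `sigma` flags) and `edges` (columns
#'   `id`, `type` in `{"I","R","V"}`, `v1`, `v2`, `interval`, `support`,
#'   `source`).
#' @export
build_graph <- function(intervals, adjacencies = NULL) {
  if (inherits(intervals, "prego_partition")) {
    adjacencies <- intervals$adjacencies
    intervals <- intervals$intervals
  }
  if (is.null(adjacencies)) adjacencies <- empty_adjacencies()
  n <- nrow(intervals)
  stopifnot(n >= 1, all(intervals$index == seq_len(n)))

  if (nrow(adjacencies) > 0 &&
      (any(adjacencies$index1 > n) || any(adjacencies$index2 > n) ||
       any(adjacencies$index1 < 1) || any(adjacencies$index2 < 1)))
    stop("adjacency references an interval outside the partition")

  vertices <- data.frame(
    vid = seq_len(2L * n),
    interval = rep(intervals$index, each = 2),
    side = rep(c("s", "t"), n),
    chrom = rep(intervals$chrom, each = 2),
    stringsAsFactors = FALSE)
  vertices$label <- paste0(vertices$side, vertices$interval)
  first <- !duplicated(intervals$chrom)
  last <- !duplicated(intervals$chrom, fromLast = TRUE)
  vertices$telomeric <- (vertices$side == "s" &
                           vertices$interval %in% intervals$index[first]) |
                        (vertices$side == "t" &
                           vertices$interval %in% intervals$index[last])
  vertices$sigma <- FALSE

  e_I <- data.frame(type = "I", v1 = .vid(intervals$index, "s"),
                    v2 = .vid(intervals$index, "t"),
                    interval = intervals$index, support = NA_real_,
                    source = NA_character_, stringsAsFactors = FALSE)
  same_chrom <- intervals$chrom[-n] == intervals$chrom[-1]
  left <- intervals$index[-n][same_chrom]
  e_R <- if (length(left))
    data.frame(type = "R", v1 = .vid(left, "t"), v2 = .vid(left + 1L, "s"),
               interval = NA_integer_, support = NA_real_,
               source = NA_character_, stringsAsFactors = FALSE)
  else NULL

  e_V <- NULL
  if (nrow(adjacencies) > 0) {
    av1 <- .vid(adjacencies$index1, ifelse(adjacencies$side1 == "s", "s", "t"))
    av2 <- .vid(adjacencies$index2, ifelse(adjacencies$side2 == "s", "s", "t"))
    lo <- pmin(av1, av2); hi <- pmax(av1, av2)
    key <- paste(lo, hi)
    support <- tapply(adjacencies$support, key, sum)
    source <- tapply(adjacencies$source, key, function(s)
      paste(sort(unique(s)), collapse = "+"))
    u <- !duplicated(key)
    ord <- order(lo[u], hi[u])
    ukey <- key[u][ord]
    e_V <- data.frame(type = "V", v1 = lo[u][ord], v2 = hi[u][ord],
                      interval = NA_integer_,
                      support = as.numeric(support[ukey]),
                      source = as.character(source[ukey]),
                      stringsAsFactors = FALSE)
  }

  edges <- rbind(e_I, e_R, e_V)
  edges$id <- seq_len(nrow(edges))
  edges <- edges[, c("id", "type", "v1", "v2", "interval", "support", "source")]
  rownames(edges) <- NULL

  structure(list(intervals = intervals, vertices = vertices, edges = edges),
            class = "iagraph")
}

#' @export
print.iagraph <- function(x, ...) {
  tab <- table(factor(x$edges$type, levels = c("I", "R", "V")))
  cat("Interval-adjacency graph:", nrow(x$intervals), "intervals on",
      length(unique(x$intervals$chrom)), "chromosomes\n")
  cat("  edges: ", tab[["I"]], " interval, ", tab[["R"]], " reference, ",
      tab[["V"]], " variant; |T| = ", sum(x$vertices$telomeric), "\n", sep = "")
  if (any(x$vertices$sigma))
    cat("  telomere-loss vertices:",
        paste(x$vertices$label[x$vertices$sigma], collapse = ", "), "\n")
  invisible(x)
}

# interval edge id for each interval index (I edges are constructed first)
.interval_edge_ids <- function(graph) {
  ids <- graph$edges$id[graph$edges$type == "I"]
  ids[order(graph$edges$interval[graph$edges$type == "I"])]
}

#' Detect telomere loss from coverage drops
#'
#' Scans each chromosome for a sharp drop in length-normalized read depth
#' (`r_j / L_j`) at an interval boundary such that the lower-depth side runs
#' to a chromosome end with no variant edge attached anywhere on that arm.
#' Such a drop is interpreted as loss of the telomere: a new telomeric
#' `sigma` vertex is added with a variant edge to the boundary vertex of the
#' retained (higher-depth) interval, and the displaced chromosome-end vertex
#' leaves the telomeric set (so the balance constraints force multiplicity 0
#' on the lost arm). When several nested boundaries qualify at the same
#' chromosome end, the one closest to that end (forcing the smallest arm to
#' zero) is used. If no drop is found the graph is returned unchanged.
#'
#' @param graph an [`iagraph`][build_graph] object.
#' @param depth a [depth_profile()] aligned with `graph`'s intervals.
#' @param drop_ratio_threshold boundaries where
#'   `min(d_j, d_{j+1}) / max(d_j, d_{j+1})` is below this value qualify as
#'   drops (default 0.5).
#' @return the graph, possibly with added sigma vertices and variant edges.
#' @export
detect_telomere_loss <- function(graph, depth, drop_ratio_threshold = 0.5) {
  stopifnot(inherits(graph, "iagraph"))
  iv <- graph$intervals
  stopifnot(length(depth$r) == nrow(iv))
  d <- depth$r / iv$length

  vtouch <- c(graph$edges$v1[graph$edges$type == "V"],
              graph$edges$v2[graph$edges$type == "V"])

  losses <- list()   # list of (attach_vid, displaced_vid)
  for (chrom in unique(iv$chrom)) {
    idx <- iv$index[iv$chrom == chrom]
    nc <- length(idx)
    if (nc < 2) next
    dc <- d[idx]
    ratio <- pmin(dc[-nc], dc[-1]) / pmax(dc[-nc], dc[-1])
    ratio[!is.finite(ratio)] <- 1   # both depths zero: no evidence of a drop
    qualifies <- ratio < drop_ratio_threshold

    arm_has_variant <- function(from, to) {  # positions within chromosome
      vids <- c(.vid(idx[from:to], "s"), .vid(idx[from:to], "t"))
      any(vids %in% vtouch)
    }
    # right end: drop going outward, lost arm = b+1 .. nc
    right <- which(qualifies & dc[-1] < dc[-nc])
    right <- right[!vapply(right, function(b) arm_has_variant(b + 1, nc),
                           logical(1))]
    if (length(right))
      losses[[length(losses) + 1L]] <-
        c(attach = .vid(idx[max(right)], "t"),
          displaced = .vid(idx[nc], "t"))
    # left end: drop going outward, lost arm = 1 .. b
    lft <- which(qualifies & dc[-nc] < dc[-1])
    lft <- lft[!vapply(lft, function(b) arm_has_variant(1, b), logical(1))]
    if (length(lft))
      losses[[length(losses) + 1L]] <-
        c(attach = .vid(idx[min(lft) + 1L], "s"),
          displaced = .vid(idx[1], "s"))
  }
  if (!length(losses)) return(graph)

  for (k in seq_along(losses)) {
    svid <- max(graph$vertices$vid) + 1L
    graph$vertices <- rbind(graph$vertices, data.frame(
      vid = svid, interval = NA_integer_, side = NA_character_,
      chrom = NA_character_,
      label = paste0("sigma", sum(graph$vertices$sigma) + 1L),
      telomeric = TRUE, sigma = TRUE, stringsAsFactors = FALSE))
    graph$vertices$telomeric[graph$vertices$vid == losses[[k]]["displaced"]] <-
      FALSE
    graph$edges <- rbind(graph$edges, data.frame(
      id = max(graph$edges$id) + 1L, type = "V",
      v1 = unname(losses[[k]]["attach"]), v2 = svid,
      interval = NA_integer_, support = NA_real_,
      source = "telomere-loss", stringsAsFactors = FALSE))
  }
  rownames(graph$vertices) <- rownames(graph$edges) <- NULL
  graph
}
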