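# Readers and writers for the plain-text interchange formats. All files
# carry a `#prego-format=1` stamp; writers are deterministic (edges sorted
# by type then id), readers reject rather than guess on malformed input.
# File coordinates are 1-based inclusive; conversion to the internal
# 0-based half-open representation happens here and only here.

.FORMAT_STAMP <- "#prego-format=1"

.read_stamped <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != .FORMAT_STAMP)
    stop("missing or mismatched format stamp in ", path,
         " (expected ", .FORMAT_STAMP, ")")
  lines[-1]
}

.parse_tsv <- function(lines, what, required, path) {
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("no header line in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  body <- lines[-1]
  if (!length(body)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                  header), stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop("malformed line ", bad[1] + 2, " in ", path, " (", what,
         "): expected ", length(header), " fields")
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- header
  out
}

#' Read chromosome lengths
#'
#' Accepts a two-column TSV (`chrom`, `length`) or a samtools `.fai` index
#' (first two columns used). No format stamp is required.
#'
#' @param path file path.
#' @return data frame `chrom`, `length`.
#' @export
read_chrom_lengths <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    length = as.numeric(tab[[2]]),
                    stringsAsFactors = FALSE)
  .check_chrom_lengths(out)
}

#' Read candidate adjacency clusters (BEDPE-like TSV)
#'
#' Required columns: `chrom1`, `pos1`, `side1`, `chrom2`, `pos2`, `side2`,
#' `support`. Positions are 1-based; `side = "e"` marks the junction using
#' the *end* of the segment terminating at `pos` (internal cut coordinate
#' `pos`), `side = "s"` the *start* of the segment beginning at `pos`
#' (internal cut coordinate `pos - 1`). Malformed lines are rejected with
#' their line number.
#'
#' @param path file path (stamped with `#prego-format=1`).
#' @return cluster data frame with internal 0-based `cut1`/`cut2` columns.
#' @export
read_clusters <- function(path) {
  tab <- .parse_tsv(.read_stamped(path), "clusters",
                    c("chrom1", "pos1", "side1", "chrom2", "pos2", "side2",
                      "support"), path)
  if (nrow(tab) == 0) return(empty_adjacencies())
  bad <- which(!(tab$side1 %in% c("s", "e")) | !(tab$side2 %in% c("s", "e")))
  if (length(bad))
    stop("invalid side token on line ", bad[1] + 2, " of ", path,
         " (must be 's' or 'e')")
  support <- suppressWarnings(as.numeric(tab$support))
  pos1 <- suppressWarnings(as.numeric(tab$pos1))
  pos2 <- suppressWarnings(as.numeric(tab$pos2))
  bad <- which(is.na(support) | is.na(pos1) | is.na(pos2))
  if (length(bad))
    stop("non-numeric field on line ", bad[1] + 2, " of ", path)
  if (any(support < 1)) stop("cluster support must be >= 1 in ", path)
  data.frame(id = seq_len(nrow(tab)),
             chrom1 = tab$chrom1,
             cut1 = ifelse(tab$side1 == "e", pos1, pos1 - 1),
             side1 = tab$side1,
             chrom2 = tab$chrom2,
             cut2 = ifelse(tab$side2 == "e", pos2, pos2 - 1),
             side2 = tab$side2,
             support = support,
             source = if (!is.null(tab$source)) tab$source else "measured",
             stringsAsFactors = FALSE)
}

#' Write adjacency clusters
#'
#' Inverse of [read_clusters()] (round-trip identity on the records).
#'
#' @param clusters cluster data frame with internal cut coordinates.
#' @param path output path.
#' @export
write_clusters <- function(clusters, path) {
  pos1 <- ifelse(clusters$side1 == "e", clusters$cut1, clusters$cut1 + 1)
  pos2 <- ifelse(clusters$side2 == "e", clusters$cut2, clusters$cut2 + 1)
  out <- data.frame(chrom1 = clusters$chrom1, pos1 = pos1,
                    side1 = clusters$side1, chrom2 = clusters$chrom2,
                    pos2 = pos2, side2 = clusters$side2,
                    support = clusters$support,
                    source = if (!is.null(clusters$source)) clusters$source
                             else "measured")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.FORMAT_STAMP, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-interval depth table
#'
#' TSV with columns `index` and `r` (concordant-pair count per interval).
#'
#' @param path file path.
#' @return numeric vector of counts ordered by interval index.
#' @export
read_depth <- function(path) {
  tab <- .parse_tsv(.read_stamped(path), "depth", c("index", "r"), path)
  idx <- as.integer(tab$index)
  r <- as.numeric(tab$r)
  if (anyNA(idx) || anyNA(r)) stop("non-numeric depth record in ", path)
  r[order(idx)]
}

#' Write a per-interval depth table
#' @param r numeric vector of counts (position = interval index).
#' @param path output path.
#' @export
write_depth <- function(r, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.FORMAT_STAMP, con)
  utils::write.table(data.frame(index = seq_along(r), r = r), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read centromere (or other exclusion) regions from BED
#'
#' Standard BED coordinates (0-based half-open), no stamp required.
#'
#' @param path file path.
#' @return data frame `chrom`, `start`, `end`.
#' @export
read_centromeres <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  data.frame(chrom = as.character(tab[[1]]), start = as.numeric(tab[[2]]),
             end = as.numeric(tab[[3]]), stringsAsFactors = FALSE)
}

#' Write an interval-adjacency graph
#'
#' Single self-contained stamped TSV with three sections (`intervals`,
#' `vertices`, `edges`); [read_graph()] restores the graph exactly
#' (round-trip identity on the edge lists, including sigma vertices and
#' telomeric flags).
#'
#' @param graph an [`iagraph`][build_graph].
#' @param path output path.
#' @export
write_graph <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.FORMAT_STAMP, con)
  writeLines("#section=intervals", con)
  utils::write.table(graph$intervals, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("#section=vertices", con)
  utils::write.table(graph$vertices, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("#section=edges", con)
  ed <- graph$edges[order(match(graph$edges$type, c("I", "R", "V")),
                          graph$edges$id), ]
  utils::write.table(ed, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interval-adjacency graph written by [write_graph()]
#' @param path file path.
#' @return an [`iagraph`][build_graph].
#' @export
read_graph <- function(path) {
  lines <- .read_stamped(path)
  marks <- grep("^#section=", lines)
  if (length(marks) != 3) stop("expected 3 sections in ", path)
  names(marks) <- sub("^#section=", "", lines[marks])
  bounds <- c(marks, length(lines) + 1)
  section <- function(nm) {
    i <- which(names(marks) == nm)
    .parse_tsv(lines[(marks[i] + 1):(bounds[i + 1] - 1)], nm, character(0),
               path)
  }
  iv <- section("intervals")
  for (cc in c("start", "end", "index", "length")) iv[[cc]] <- as.numeric(iv[[cc]])
  iv$index <- as.integer(iv$index)
  vx <- section("vertices")
  vx$vid <- as.integer(vx$vid)
  vx$interval <- suppressWarnings(as.integer(vx$interval))
  vx$telomeric <- as.logical(vx$telomeric)
  vx$sigma <- as.logical(vx$sigma)
  vx$side[vx$side == "NA"] <- NA_character_
  vx$chrom[vx$chrom == "NA"] <- NA_character_
  ed <- section("edges")
  for (cc in c("id", "v1", "v2")) ed[[cc]] <- as.integer(ed[[cc]])
  ed$interval <- suppressWarnings(as.integer(ed$interval))
  ed$support <- suppressWarnings(as.numeric(ed$support))
  ed$source[ed$source == "NA"] <- NA_character_
  ed <- ed[order(ed$id), ]
  rownames(iv) <- rownames(vx) <- rownames(ed) <- NULL
  structure(list(intervals = iv, vertices = vx, edges = ed),
            class = "iagraph")
}

#' Write a multiplicity assignment
#'
#' Stamped TSV with columns `id`, `type`, `mu`, rows sorted by edge type
#' then id.
#'
#' @param mu a `"multiplicity_assignment"` or numeric vector aligned with
#'   `graph$edges`.
#' @param graph the graph the assignment lives on.
#' @param path output path.
#' @export
write_mu <- function(mu, graph, path) {
  mu <- .mu_vector(graph, mu)
  out <- data.frame(id = graph$edges$id, type = graph$edges$type, mu = mu)
  out <- out[order(match(out$type, c("I", "R", "V")), out$id), ]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.FORMAT_STAMP, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multiplicity assignment written by [write_mu()]
#' @param path file path.
#' @return integer vector named by edge id, ordered by id.
#' @export
read_mu <- function(path) {
  tab <- .parse_tsv(.read_stamped(path), "mu", c("id", "type", "mu"), path)
  mu <- as.integer(tab$mu)
  id <- as.integer(tab$id)
  if (anyNA(mu) || anyNA(id)) stop("non-integer multiplicity record in ", path)
  stats::setNames(mu[order(id)], sort(id))
}

#' Write variant annotations
#' @param annotations output of [annotate_variants()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.FORMAT_STAMP, con)
  utils::write.table(annotations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a graph (and optional multiplicities) to GraphViz DOT
#'
#' Interval edges are drawn bold, reference edges solid, variant edges
#' dashed red; edge labels carry the multiplicity when `mu` is given.
#'
#' @param graph an [`iagraph`][build_graph].
#' @param path output path.
#' @param mu optional assignment for edge labels.
#' @export
write_dot <- function(graph, path, mu = NULL) {
  if (!is.null(mu)) mu <- .mu_vector(graph, mu)
  lab <- graph$vertices$label
  names(lab) <- graph$vertices$vid
  style <- c(I = "[style=bold]", R = "[color=grey50]",
             V = "[style=dashed,color=firebrick]")
  lines <- c("graph G {", "  node [shape=point];")
  for (k in seq_len(nrow(graph$edges))) {
    e <- graph$edges[k, ]
    s <- style[[e$type]]
    if (!is.null(mu))
      s <- sub("\\]$", paste0(',label="', mu[k], '"]'), s)
    lines <- c(lines, paste0('  "', lab[[as.character(e$v1)]], '" -- "',
                             lab[[as.character(e$v2)]], '" ', s, ";"))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
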