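# Top-level model fit: interval-adjacency graph + Poisson read-depth
# likelihood -> integer copy numbers, in the classic fitted-model idiom.

#' Fit the genome-reconstruction model
#'
#' The one-stop fitting function: given an interval-adjacency graph and a
#' read-depth profile, finds the maximum-likelihood integer multiplicity
#' assignment (the inferred copy number of interval `j` is the multiplicity
#' of its interval edge) and returns a fitted-model object with the usual
#' accessor methods.
#'
#' The model: concordant-pair counts `r_j` are independent Poisson with
#' mean `lambda_j * mu_j / tau`, `lambda_j = N L_j / L_R`; multiplicities
#' are non-negative integers tied together by the copy-number balance
#' conditions at every non-telomeric vertex. See [solve_multiplicities()]
#' for the optimizer.
#'
#' @param graph an [`iagraph`][build_graph] (or a `"prego_partition"`,
#'   which is converted with [build_graph()]).
#' @param depth a [depth_profile()], or a numeric vector of per-interval
#'   concordant counts.
#' @param tau expected copies of an interval in an unrearranged sample
#'   (default 2).
#' @param mu_max global multiplicity cap (default 50).
#' @param epsilon_copies surrogate copy value for the log term at
#'   multiplicity 0 (default 0.05).
#' @param fixed_interval_counts optional integer vector pinning the
#'   interval copy numbers (perfect-data mode).
#' @param prefer_sparse prefer co-optimal solutions with smaller total
#'   variant-edge multiplicity.
#' @param max_states dynamic-programming state-space guard.
#' @return an object of class `"prego_fit"` with components `graph`,
#'   `depth`, `params`, `assignment` (see [solve_multiplicities()]) and
#'   `call`. Methods: [print()], [summary()], [coef()], [fitted()],
#'   [predict()], [residuals()], [simulate()], [plot()].
#' @examples
#' chrom <- data.frame(chrom = "chr1", length = 100000)
#' adj <- data.frame(chrom1 = "chr1", cut1 = 30000, side1 = "e",
#'                   chrom2 = "chr1", cut2 = 60000, side2 = "s",
#'                   support = 8, source = "measured")
#' part <- partition_reference(chrom, adj, min_interval_len = 1000)
#' g <- build_graph(part)
#' d <- depth_profile(part, r = c(3000, 1500, 4000))
#' fit <- prego(g, d)
#' coef(fit)             # inferred copy numbers
#' @export
prego <- function(graph, depth, tau = 2, mu_max = 50, epsilon_copies = 0.05,
                  fixed_interval_counts = NULL, prefer_sparse = FALSE,
                  max_states = 5e6) {
  cl <- match.call()
  if (inherits(graph, "prego_partition")) graph <- build_graph(graph)
  stopifnot(inherits(graph, "iagraph"))
  if (!inherits(depth, "depth_profile"))
    depth <- depth_profile(graph, depth, tau = tau)
  params <- likelihood_params(depth, mu_max = mu_max,
                              epsilon_copies = epsilon_copies)
  assignment <- solve_multiplicities(graph, depth, params,
                                     fixed_interval_counts =
                                       fixed_interval_counts,
                                     prefer_sparse = prefer_sparse,
                                     max_states = max_states)
  structure(list(graph = graph, depth = depth, params = params,
                 assignment = assignment, call = cl),
            class = "prego_fit")
}

#' @export
print.prego_fit <- function(x, ...) {
  cat("Cancer-genome reconstruction fit\n")
  cat("Call: "); print(x$call)
  if (x$assignment$solver_status != "optimal") {
    cat("Status:", x$assignment$solver_status, "\n")
    return(invisible(x))
  }
  ed <- x$graph$edges
  used <- sum(ed$type == "V" & x$assignment$mu > 0)
  cat(nrow(x$graph$intervals), "intervals,",
      sum(ed$type == "V"), "variant edges (", used, "used );",
      "objective", format(x$assignment$objective_value, digits = 8), "\n")
  cat("Copy numbers:\n")
  print(table(copy = x$assignment$chat))
  invisible(x)
}

#' @export
coef.prego_fit <- function(object, type = c("intervals", "edges"), ...) {
  type <- match.arg(type)
  if (type == "intervals") object$assignment$chat else object$assignment$mu
}

#' @export
fitted.prego_fit <- function(object, ...) {
  object$params$lambda * object$assignment$chat / object$params$tau
}

#' @export
predict.prego_fit <- function(object, mu = NULL, ...) {
  if (is.null(mu)) return(fitted(object))
  stopifnot(length(mu) == length(object$params$lambda))
  object$params$lambda * mu / object$params$tau
}

#' Residuals of a reconstruction fit
#'
#' `"pearson"` (default) and `"response"` compare observed counts with
#' their fitted Poisson means (the mean for copy 0 uses the
#' `epsilon_copies` surrogate so the residual is finite); `"balance"`
#' returns the integer copy-number balance residuals per non-telomeric
#' vertex (all zero for any feasible fit).
#'
#' @param object a `"prego_fit"`.
#' @param type residual type.
#' @param ... unused.
#' @export
residuals.prego_fit <- function(object,
                                type = c("pearson", "response", "balance"),
                                ...) {
  type <- match.arg(type)
  if (type == "balance")
    return(balance_residuals(object$graph, object$assignment))
  mu_eff <- pmax(object$assignment$chat, object$params$epsilon_copies)
  m <- object$params$lambda * mu_eff / object$params$tau
  r <- object$depth$r
  if (type == "response") r - m else (r - m) / sqrt(pmax(m, 1e-12))
}

#' @export
summary.prego_fit <- function(object, ...) {
  ann <- annotate_variants(object$graph, object$assignment)
  eul <- is_eulerizable(object$graph, object$assignment)
  out <- list(fit = object, annotations = ann,
              association = if (nrow(ann)) usage_association_test(ann),
              eulerizable = eul$eulerizable)
  class(out) <- "summary.prego_fit"
  out
}

#' @export
print.summary.prego_fit <- function(x, ...) {
  print(x$fit)
  cat("\nEulerizable:", x$eulerizable, "\n")
  if (nrow(x$annotations)) {
    cat("\nVariant edges by geometry:\n")
    print(table(x$annotations$geometry, ifelse(x$annotations$used,
                                               "used", "unused")))
    if (!is.null(x$association)) {
      cat("\nReciprocality vs usage (Fisher, two-sided):\n")
      print(x$association, row.names = FALSE, digits = 3)
    }
  }
  invisible(x)
}

#' Simulate read depths from a fitted reconstruction
#'
#' Draws new per-interval concordant counts from the fitted Poisson model
#' (mean `lambda_j * chat_j / tau`).
#'
#' @param object a `"prego_fit"`.
#' @param nsim number of replicate depth vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated counts.
#' @export
simulate.prego_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- fitted(object)
  out <- as.data.frame(replicate(nsim, stats::rpois(length(m), m)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot observed versus inferred copy number along the genome
#'
#' Shows the depth-implied copy estimate `tau * r_j / lambda_j` per
#' interval (points, at interval midpoints) and the inferred integer copy
#' number (steps) along the concatenated genome, with chromosome
#' boundaries marked.
#'
#' @param x a `"prego_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prego_fit <- function(x, ...) {
  iv <- x$graph$intervals
  offs <- c(0, cumsum(tapply(iv$end, iv$chrom, max)[unique(iv$chrom)]))
  names(offs) <- c(unique(iv$chrom), "end")
  mid <- (iv$start + iv$end) / 2 + offs[iv$chrom]
  obs <- x$params$tau * x$depth$r / pmax(x$params$lambda, 1e-12)
  graphics::plot(mid, obs, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "genome position (bp, concatenated)",
                 ylab = "copy number", ...)
  graphics::segments(iv$start + offs[iv$chrom], x$assignment$chat,
                     iv$end + offs[iv$chrom], x$assignment$chat,
                     col = "firebrick", lwd = 2)
  graphics::abline(v = offs[-1], col = "grey80", lty = 3)
  invisible(x)
}

#' Reconstruct block sequences from a fit
#'
#' Extracts the alternating Eulerian tours of the fitted multigraph and
#' returns the tour decomposition (see [extract_tours()]).
#'
#' @param fit a `"prego_fit"` with an optimal assignment.
#' @param seed optional seed for randomized edge choice at branch vertices.
#' @export
reconstruct_genome <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "prego_fit"),
            fit$assignment$solver_status == "optimal")
  extract_tours(fit$graph, fit$assignment, seed = seed)
}
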