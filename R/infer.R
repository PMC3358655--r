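# Maximum-likelihood integer multiplicity assignment under the Poisson
# read-depth model, subject to the copy-number balance constraints.

#' Per-interval read-depth profile
#'
#' Bundles the per-interval concordant-pair counts with the quantities the
#' likelihood needs: the total count `N`, the reference length `L_R`, the
#' Poisson rate scale `lambda_j = N * L_j / L_R`, and the ploidy constant
#' `tau` (expected copies of each interval in an unrearranged sample).
#'
#' @param intervals interval data frame (or a `"prego_partition"` /
#'   `"iagraph"` object).
#' @param r numeric vector of concordant-pair counts, aligned with the
#'   intervals.
#' @param tau expected copy number of an unrearranged interval (default 2,
#'   diploid).
#' @return an object of class `"depth_profile"` with elements `r`, `N`,
#'   `L_R`, `tau`, `lambda`.
#' @export
depth_profile <- function(intervals, r, tau = 2) {
  if (inherits(intervals, "prego_partition") || inherits(intervals, "iagraph"))
    intervals <- intervals$intervals
  stopifnot(length(r) == nrow(intervals))
  if (any(r < 0)) stop("read counts must be non-negative")
  L <- intervals$length
  if (any(L <= 0)) stop("degenerate interval of length 0")
  L_R <- sum(L)
  if (L_R == 0) stop("total reference length is zero")
  N <- sum(r)
  structure(list(r = as.numeric(r), N = N, L_R = L_R, tau = tau,
                 lambda = N * L / L_R),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("Depth profile: ", length(x$r), " intervals, N = ", format(x$N),
      " concordant pairs, tau = ", x$tau, "\n", sep = "")
  invisible(x)
}

#' Likelihood parameters for multiplicity inference
#'
#' @param depth a [depth_profile()].
#' @param mu_max global cap on any edge multiplicity (default 50); the
#'   per-interval bound is `min(mu_max, max(10, ceiling(4 * tau * r_j /
#'   lambda_j)))`.
#' @param epsilon_copies surrogate copy value at which the log term is
#'   evaluated for multiplicity 0 (default 0.05), so that homozygous
#'   deletion remains selectable but is strongly penalized where reads are
#'   observed.
#' @return an object of class `"likelihood_params"`.
#' @export
likelihood_params <- function(depth, mu_max = 50, epsilon_copies = 0.05) {
  stopifnot(inherits(depth, "depth_profile"))
  if (mu_max < depth$tau) stop("mu_max must be at least tau")
  stopifnot(epsilon_copies > 0)
  structure(list(lambda = depth$lambda, tau = depth$tau, mu_max = mu_max,
                 epsilon_copies = epsilon_copies, r = depth$r),
            class = "likelihood_params")
}

#' Expected read count for an interval at a given multiplicity
#'
#' Returns `N * L_j / L_R * mu_j / tau`, the expected number of concordant
#' pairs aligning within interval `j` when it appears `mu_j` times in the
#' genome.
#'
#' @param params a [likelihood_params()] (or [depth_profile()]).
#' @param j interval index.
#' @param mu_j non-negative multiplicity.
#' @export
expected_depth <- function(params, j, mu_j) {
  if (inherits(params, "depth_profile")) params <- likelihood_params(params)
  stopifnot(mu_j >= 0)
  params$lambda[j] * mu_j / params$tau
}

# one interval's objective term, tabulated over mu = 0..hi
.interval_cost <- function(lambda_j, r_j, tau, eps, hi) {
  mu <- 0:hi
  rate <- lambda_j * mu / tau
  log_at <- lambda_j * pmax(mu, eps) / tau   # mu = 0 uses the surrogate
  term <- if (r_j == 0) rate else rate - r_j * log(log_at)
  # lambda = 0 kills the log term
  term[!is.finite(term)] <- 0
  term
}

#' Negative Poisson log-likelihood of interval multiplicities
#'
#' Evaluates \eqn{\sum_j \lambda_j \mu_j / \tau - r_j \log(\lambda_j \mu_j /
#' \tau)} (constant terms omitted). The log term at \eqn{\mu_j = 0} is
#' evaluated at the `epsilon_copies` surrogate.
#'
#' @param params a [likelihood_params()].
#' @param mu_intervals integer vector of interval multiplicities.
#' @param r concordant counts (defaults to those stored in `params`).
#' @return the objective value (lower is more likely).
#' @export
neg_log_likelihood <- function(params, mu_intervals, r = params$r) {
  stopifnot(inherits(params, "likelihood_params"))
  if (any(r < 0)) stop("read counts must be non-negative")
  stopifnot(length(mu_intervals) == length(r),
            all(mu_intervals >= 0), all(mu_intervals == round(mu_intervals)))
  lam <- params$lambda
  rate <- lam * mu_intervals / params$tau
  log_at <- lam * pmax(mu_intervals, params$epsilon_copies) / params$tau
  term <- rate - r * ifelse(r == 0, 0, log(log_at))
  term[!is.finite(term)] <- 0
  sum(term)
}

# per-edge domains (lo/hi) and cost tables shared by the DP solver and the
# brute-force oracle
.edge_domains <- function(graph, params, fixed_interval_counts = NULL,
                          prefer_sparse = FALSE) {
  edges <- graph$edges
  n <- nrow(graph$intervals)
  tau <- params$tau
  hi_I <- pmin(params$mu_max,
               pmax(10, ceiling(4 * tau * params$r /
                                  pmax(params$lambda, .Machine$double.eps))))
  hi_I[!is.finite(hi_I)] <- params$mu_max
  lo_I <- rep(0L, n)
  if (!is.null(fixed_interval_counts)) {
    stopifnot(length(fixed_interval_counts) == n,
              all(fixed_interval_counts >= 0),
              all(fixed_interval_counts == round(fixed_interval_counts)))
    lo_I <- hi_I <- as.integer(fixed_interval_counts)
  }
  # bound at each vertex = bound of its interval edge (sigma: unbounded)
  vmax <- rep(NA_real_, max(graph$vertices$vid))
  vmax[.vid(seq_len(n), "s")] <- hi_I
  vmax[.vid(seq_len(n), "t")] <- hi_I

  lo <- integer(nrow(edges)); hi <- integer(nrow(edges))
  cost <- vector("list", nrow(edges))
  eps <- params$epsilon_copies
  for (i in seq_len(nrow(edges))) {
    if (edges$type[i] == "I") {
      j <- edges$interval[i]
      lo[i] <- lo_I[j]; hi[i] <- as.integer(hi_I[j])
      cost[[i]] <- .interval_cost(params$lambda[j], params$r[j], tau, eps,
                                  hi[i])
    } else {
      b <- c(vmax[edges$v1[i]], vmax[edges$v2[i]])
      b <- b[!is.na(b)]
      cap <- if (length(b)) min(b) else params$mu_max
      if (edges$v1[i] == edges$v2[i]) cap <- floor(cap / 2)
      lo[i] <- 0L; hi[i] <- as.integer(cap)
      cost[[i]] <- if (prefer_sparse && edges$type[i] == "V")
        (0:hi[i]) * attr(prefer_sparse, "weight", exact = TRUE) %||% 0
      else rep(0, hi[i] + 1)
    }
  }
  list(lo = lo, hi = hi, cost = cost)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vertex processing order: natural genome order, sigma vertices inserted
# right after their attachment vertex so sigma edges close immediately
.vertex_order <- function(graph) {
  base <- sort(graph$vertices$vid[!graph$vertices$sigma])
  sig <- graph$vertices$vid[graph$vertices$sigma]
  if (!length(sig)) return(base)
  ve <- graph$edges
  attach_at <- vapply(sig, function(sv) {
    e <- which(ve$v1 == sv | ve$v2 == sv)[1]
    other <- if (ve$v1[e] == sv) ve$v2[e] else ve$v1[e]
    other
  }, numeric(1))
  out <- integer(0)
  for (v in base) {
    out <- c(out, v, sig[attach_at == v])
  }
  c(out, sig[!(attach_at %in% base)])
}

#' Maximum-likelihood multiplicity assignment
#'
#' Finds the integer edge multiplicities minimizing the negative Poisson
#' log-likelihood of the observed read depths subject to the copy-number
#' balance constraints (interval multiplicity equals reference plus variant
#' multiplicities at every non-telomeric vertex, loops counted twice) and
#' `0 <= mu(e) <= mu_max`. The objective is tabulated at every integer
#' multiplicity and minimized exactly by dynamic programming over a cut of
#' the graph, so the result is the true discrete optimum; reference and
#' variant edges carry no objective term.
#'
#' @param graph an [`iagraph`][build_graph].
#' @param depth a [depth_profile()] aligned with the graph's intervals.
#' @param params optional [likelihood_params()]; built from `depth` with
#'   defaults if missing.
#' @param fixed_interval_counts optional integer vector `c_j` pinning every
#'   interval-edge multiplicity (perfect-data mode); inconsistent counts are
#'   reported as infeasible, never relaxed.
#' @param prefer_sparse if `TRUE`, break ties among co-optimal solutions
#'   toward smaller total variant-edge multiplicity (a secondary objective
#'   with weight far below the smallest objective gap).
#' @param max_states guard on the dynamic-programming state space
#'   (default 5e6).
#' @return an object of class `"multiplicity_assignment"`: list with `mu`
#'   (integer per edge, named by edge id), `chat` (inferred interval copy
#'   numbers), `objective_value` (value of the likelihood objective),
#'   `solver_status` (`"optimal"` or `"infeasible"`).
#' @seealso [brute_force_oracle()], [balance_residuals()]
#' @export
solve_multiplicities <- function(graph, depth, params = NULL,
                                 fixed_interval_counts = NULL,
                                 prefer_sparse = FALSE, max_states = 5e6) {
  stopifnot(inherits(graph, "iagraph"))
  if (is.null(params)) params <- likelihood_params(depth)
  stopifnot(length(params$lambda) == nrow(graph$intervals))

  if (isTRUE(prefer_sparse)) {
    # weight small enough never to override a real objective difference
    scale <- max(1, sum(abs(params$r)))
    attr(prefer_sparse, "weight") <- 1e-6 * scale /
      max(1, sum(graph$edges$type == "V")) / max(1, params$mu_max)
  }
  dom <- .edge_domains(graph, params, fixed_interval_counts, prefer_sparse)

  vids <- graph$vertices$vid
  vmap <- match(seq_len(max(vids)), vids)        # vid -> row
  ord0 <- match(.vertex_order(graph), vids) - 1L # 0-based rows in order
  res <- .dp_solve_cpp(
    v1 = match(graph$edges$v1, vids) - 1L,
    v2 = match(graph$edges$v2, vids) - 1L,
    type = graph$edges$type,
    lo = dom$lo, hi = dom$hi, cost = dom$cost,
    order = ord0, telomeric = graph$vertices$telomeric,
    max_states = max_states)

  if (res$status != "optimal") {
    return(structure(list(mu = NULL, chat = NULL, objective_value = NA_real_,
                          solver_status = "infeasible"),
                     class = "multiplicity_assignment"))
  }
  mu <- as.integer(res$mu)
  names(mu) <- graph$edges$id
  isI <- graph$edges$type == "I"
  chat <- mu[isI][order(graph$edges$interval[isI])]
  names(chat) <- graph$intervals$index
  obj <- neg_log_likelihood(params, chat)
  structure(list(mu = mu, chat = chat, objective_value = obj,
                 solver_status = "optimal"),
            class = "multiplicity_assignment")
}

#' @export
print.multiplicity_assignment <- function(x, ...) {
  if (x$solver_status != "optimal") {
    cat("Multiplicity assignment: ", x$solver_status, "\n", sep = "")
    return(invisible(x))
  }
  cat("Multiplicity assignment (", x$solver_status, "): ",
      length(x$mu), " edges, objective ",
      format(x$objective_value, digits = 8), "\n", sep = "")
  cat("  interval copy numbers: ",
      paste(utils::head(x$chat, 10), collapse = " "),
      if (length(x$chat) > 10) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Balance residuals of a multiplicity assignment
#'
#' For every non-telomeric vertex `v`, the residual
#' \eqn{\mu(e_I(v)) - \mu(e_R(v)) - \sum_{a \in E_A(v)} \mu(a)} (a loop at
#' `v` counts twice). All residuals are zero iff the assignment is feasible.
#'
#' @param graph an [`iagraph`][build_graph].
#' @param mu a `"multiplicity_assignment"` or a numeric vector aligned with
#'   `graph$edges`.
#' @return named integer vector of residuals, one per non-telomeric vertex
#'   (names are vertex labels).
#' @export
balance_residuals <- function(graph, mu) {
  if (inherits(mu, "multiplicity_assignment")) mu <- mu$mu
  stopifnot(length(mu) == nrow(graph$edges))
  B <- .balance_matrix(graph)
  res <- as.integer(round(B %*% mu))
  names(res) <- rownames(B)
  res
}

# constraint matrix: rows = non-telomeric vertices, columns = edges
.balance_matrix <- function(graph) {
  vt <- graph$vertices[!graph$vertices$telomeric, , drop = FALSE]
  ed <- graph$edges
  B <- matrix(0, nrow(vt), nrow(ed),
              dimnames = list(vt$label, ed$id))
  for (i in seq_len(nrow(ed))) {
    coef <- if (ed$type[i] == "I") 1 else -1
    if (ed$v1[i] == ed$v2[i]) {
      k <- match(ed$v1[i], vt$vid)
      if (!is.na(k)) B[k, i] <- B[k, i] - 2
    } else {
      for (v in c(ed$v1[i], ed$v2[i])) {
        k <- match(v, vt$vid)
        if (!is.na(k)) B[k, i] <- B[k, i] + coef
      }
    }
  }
  B
}

#' Exhaustive-search oracle for multiplicity assignment
#'
#' Enumerates every integer assignment within the edge domains, filters by
#' the balance constraints, and returns the minimum-objective assignment
#' together with all co-optimal assignments. Intended as an independent
#' check of [solve_multiplicities()] on small graphs; refuses instances
#' whose state space exceeds `guard`.
#'
#' @inheritParams solve_multiplicities
#' @param guard maximum number of enumerated states (default 1e7).
#' @param tol co-optimality tolerance on the objective (default 1e-9,
#'   relative to the scale of the optimum).
#' @return a `"multiplicity_assignment"` with an extra element `optima`: a
#'   matrix whose rows are all co-optimal assignments.
#' @export
brute_force_oracle <- function(graph, depth, params = NULL,
                               fixed_interval_counts = NULL, guard = 1e7,
                               tol = 1e-9) {
  stopifnot(inherits(graph, "iagraph"))
  if (is.null(params)) params <- likelihood_params(depth)
  dom <- .edge_domains(graph, params, fixed_interval_counts)
  sizes <- dom$hi - dom$lo + 1
  nstates <- prod(sizes)
  if (nstates > guard)
    stop("state space too large for enumeration (", format(nstates), " > ",
         format(guard), ")")
  ne <- nrow(graph$edges)
  B <- .balance_matrix(graph)
  costm <- matrix(0, max(dom$hi) + 1, ne)
  for (i in seq_len(ne)) costm[seq_len(dom$hi[i] + 1), i] <- dom$cost[[i]]

  best <- Inf
  best_mu <- NULL
  optima <- list()
  chunk <- 100000L
  for (start in seq(0, nstates - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, nstates - 1)
    m <- matrix(0L, length(idx), ne)
    rem <- idx
    for (i in seq_len(ne)) {
      m[, i] <- dom$lo[i] + rem %% sizes[i]
      rem <- rem %/% sizes[i]
    }
    feas <- rowSums(abs(m %*% t(B))) == 0
    if (!any(feas)) next
    mf <- m[feas, , drop = FALSE]
    obj <- numeric(nrow(mf))
    for (i in seq_len(ne)) obj <- obj + costm[mf[, i] + 1, i]
    scale_tol <- tol * max(1, abs(min(obj, best)))
    if (min(obj) < best - scale_tol) {
      best <- min(obj)
      best_mu <- mf[which.min(obj), ]
      optima <- list()
    }
    keep <- obj <= best + scale_tol
    if (any(keep)) optima[[length(optima) + 1]] <- mf[keep, , drop = FALSE]
    best <- min(best, min(obj))
  }
  if (is.null(best_mu)) {
    return(structure(list(mu = NULL, chat = NULL, objective_value = NA_real_,
                          solver_status = "infeasible", optima = NULL),
                     class = "multiplicity_assignment"))
  }
  optima <- do.call(rbind, optima)
  storage.mode(optima) <- "integer"
  # re-filter at the final optimum (earlier chunks may have kept looser rows)
  optima <- optima[abs(apply(optima, 1, function(m) {
    o <- 0; for (i in seq_len(ne)) o <- o + costm[m[i] + 1, i]; o
  }) - best) <= tol * max(1, abs(best)), , drop = FALSE]
  colnames(optima) <- graph$edges$id
  mu <- as.integer(best_mu)
  names(mu) <- graph$edges$id
  isI <- graph$edges$type == "I"
  chat <- mu[isI][order(graph$edges$interval[isI])]
  names(chat) <- graph$intervals$index
  structure(list(mu = mu, chat = chat,
                 objective_value = neg_log_likelihood(params, chat),
                 solver_status = "optimal", optima = optima),
            class = "multiplicity_assignment")
}
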