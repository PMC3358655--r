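# Deletion-genome simulator: diploid genomes with homozygous and
# heterozygous deletions, injected false adjacencies, fragment-sampling
# read depth with contamination and per-interval Gaussian count noise, and
# multiplicity-recovery scoring over a (rho, phi) error grid.

# autosome length proportions (human-like), scaled to a configurable total
.AUTOSOME_PROP <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
                    134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Autosome-proportioned chromosome lengths
#'
#' @param total total genome length in bases (default 3e8, a scaled-down
#'   genome that keeps full error-grid experiments fast; use ~2.9e9 for
#'   full-genome scale).
#' @return data frame `chrom`, `length` with 22 chromosomes.
#' @export
sim_chrom_lengths <- function(total = 3e8) {
  len <- round(.AUTOSOME_PROP / sum(.AUTOSOME_PROP) * total)
  data.frame(chrom = paste0("chr", seq_along(len)), length = len,
             stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Defaults reproduce the reference study conditions: 100 homozygous and 100
#' heterozygous deletions with lengths Normal(10 kb, 1 kb) distributed over
#' 22 autosome-proportioned chromosomes, 50 false deletion adjacencies, 30x
#' physical coverage with fragment lengths Normal(200, 10), contamination
#' fraction `rho` and depth-noise scale `phi` (per-interval Gaussian noise
#' with variance `phi * r_j`), averaged over 10 trials.
#'
#' @param n_hom_del,n_het_del numbers of homozygous / heterozygous
#'   deletions.
#' @param del_len_mean,del_len_sd deletion length distribution (bases).
#' @param n_false_adjacencies number of injected false adjacencies.
#' @param coverage physical coverage (fold).
#' @param frag_len_mean,frag_len_sd fragment (read-interval) length
#'   distribution (bases).
#' @param rho contamination fraction in `[0, 1]`: proportion of
#'   read-intervals drawn from the unrearranged diploid reference.
#' @param phi depth-noise variance scale (>= 0).
#' @param n_trials trials to average in [run_grid()].
#' @param genome data frame of chromosome lengths (default
#'   [sim_chrom_lengths()]).
#' @return an object of class `"sim_params"`.
#' @export
sim_params <- function(n_hom_del = 100, n_het_del = 100,
                       del_len_mean = 10000, del_len_sd = 1000,
                       n_false_adjacencies = 50, coverage = 30,
                       frag_len_mean = 200, frag_len_sd = 10,
                       rho = 0, phi = 0, n_trials = 10,
                       genome = sim_chrom_lengths()) {
  stopifnot(n_hom_del >= 0, n_het_del >= 0, n_false_adjacencies >= 0,
            rho >= 0, rho <= 1, phi >= 0, coverage > 0, n_trials >= 1)
  structure(list(n_hom_del = n_hom_del, n_het_del = n_het_del,
                 del_len_mean = del_len_mean, del_len_sd = del_len_sd,
                 n_false_adjacencies = n_false_adjacencies,
                 coverage = coverage, frag_len_mean = frag_len_mean,
                 frag_len_sd = frag_len_sd, rho = rho, phi = phi,
                 n_trials = n_trials, genome = genome),
            class = "sim_params")
}

# place n disjoint segments of ~Normal(len_mean, len_sd) on the genome,
# separated from each other and from chromosome ends by >= margin
.place_deletions <- function(genome, n, len_mean, len_sd, margin) {
  if (n == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  placed <- vector("list", n)
  occupied <- lapply(genome$chrom, function(ch) cbind(numeric(0), numeric(0)))
  names(occupied) <- genome$chrom
  max_tries <- 1000 * n
  tries <- 0
  k <- 0
  while (k < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("genome too small for the requested deletions")
    len <- max(2 * margin, round(stats::rnorm(1, len_mean, len_sd)))
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    L <- genome$length[ci]
    if (L < len + 2 * margin) next
    start <- floor(stats::runif(1, margin, L - len - margin))
    occ <- occupied[[genome$chrom[ci]]]
    if (nrow(occ) &&
        any(start - margin < occ[, 2] & start + len + margin > occ[, 1]))
      next
    k <- k + 1
    placed[[k]] <- data.frame(chrom = genome$chrom[ci], start = start,
                              end = start + len, stringsAsFactors = FALSE)
    occupied[[genome$chrom[ci]]] <- rbind(occ, c(start, start + len))
  }
  do.call(rbind, placed)
}

#' Simulate a rearranged diploid deletion genome
#'
#' Generates a diploid genome carrying `n_hom_del` deletions on both
#' haplotypes and `n_het_del` on one, plus `n_false_adjacencies` false
#' deletion adjacencies each splitting one interval into three subintervals.
#' Returns the induced reference partition, the interval-adjacency graph,
#' and the ground truth: interval copy numbers (2 outside deletions, 1
#' inside heterozygous, 0 inside homozygous) and variant-edge multiplicities
#' (2 for homozygous junctions, 1 heterozygous, 0 false). Ground-truth
#' balance is asserted at generation.
#'
#' @param params a [sim_params()] object.
#' @param seed optional RNG seed for reproducible genomes.
#' @return an object of class `"sim_genome"`: list with `partition`,
#'   `graph`, `truth` (elements `true_mu`, `copy`, `false_edge_ids`,
#'   `het_edge_ids`, `hom_edge_ids`, `deletions`) and `params`.
#' @export
simulate_genome <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  genome <- params$genome
  margin <- params$frag_len_mean

  n_del <- params$n_hom_del + params$n_het_del
  dels <- .place_deletions(genome, n_del, params$del_len_mean,
                           params$del_len_sd, margin)
  if (n_del > 0) {
    zyg <- sample(rep(c("hom", "het"),
                      c(params$n_hom_del, params$n_het_del)))
    dels$zygosity <- zyg
  } else dels$zygosity <- character(0)

  adj <- data.frame(chrom1 = dels$chrom, cut1 = dels$start,
                    side1 = rep("e", nrow(dels)),
                    chrom2 = dels$chrom, cut2 = dels$end,
                    side2 = rep("s", nrow(dels)),
                    support = rep(10, nrow(dels)),
                    source = rep("simulated-true", nrow(dels)),
                    sim_mu = ifelse(dels$zygosity == "hom", 2L, 1L),
                    stringsAsFactors = FALSE)

  # false adjacencies split an interval of the deletion-induced partition
  # into three subintervals, each at least one fragment length long
  if (params$n_false_adjacencies > 0) {
    part0 <- partition_reference(genome, adj, min_interval_len = 1)
    iv0 <- part0$intervals
    mid_len <- pmax(2 * margin,
                    round(stats::rnorm(params$n_false_adjacencies,
                                       params$del_len_mean,
                                       params$del_len_sd)))
    false_list <- vector("list", params$n_false_adjacencies)
    taken <- cbind(iv0$start, iv0$end)  # shrink hosts as cuts are placed
    for (i in seq_len(params$n_false_adjacencies)) {
      need <- mid_len[i] + 2 * margin
      hosts <- which(taken[, 2] - taken[, 1] >= need)
      if (!length(hosts)) stop("no interval long enough for false adjacency")
      h <- hosts[sample.int(length(hosts), 1)]
      x1 <- floor(stats::runif(1, taken[h, 1] + margin,
                               taken[h, 2] - margin - mid_len[i]))
      x2 <- x1 + mid_len[i]
      false_list[[i]] <- data.frame(
        chrom1 = iv0$chrom[h], cut1 = x1, side1 = "e",
        chrom2 = iv0$chrom[h], cut2 = x2, side2 = "s",
        support = 10, source = "simulated-false", sim_mu = 0L,
        stringsAsFactors = FALSE)
      # keep later false cuts off this stretch: split the host record
      taken <- rbind(taken, c(x2, taken[h, 2]))
      taken[h, 2] <- x1
      iv0 <- rbind(iv0, iv0[h, ])
    }
    adj <- rbind(adj, do.call(rbind, false_list))
  }

  part <- partition_reference(genome, adj, min_interval_len = 1)
  stopifnot(is.null(part$dropped) || nrow(part$dropped) == 0)
  graph <- build_graph(part)
  iv <- graph$intervals

  # true copy number per interval: containment in a deletion region
  copy <- rep(2L, nrow(iv))
  if (nrow(dels)) {
    for (i in seq_len(nrow(dels))) {
      inside <- iv$chrom == dels$chrom[i] & iv$start >= dels$start[i] &
        iv$end <= dels$end[i]
      copy[inside] <- copy[inside] - ifelse(dels$zygosity[i] == "hom", 2L, 1L)
    }
  }

  # ground-truth edge multiplicities
  ed <- graph$edges
  true_mu <- integer(nrow(ed))
  true_mu[ed$type == "I"] <- copy[ed$interval[ed$type == "I"]]
  # variant edges: locate by canonical endpoint pair
  adj_mu <- part$adjacencies$sim_mu
  av1 <- .vid(part$adjacencies$index1,
              ifelse(part$adjacencies$side1 == "s", "s", "t"))
  av2 <- .vid(part$adjacencies$index2,
              ifelse(part$adjacencies$side2 == "s", "s", "t"))
  vkey <- paste(pmin(av1, av2), pmax(av1, av2))
  ekey <- paste(ed$v1, ed$v2)
  vmatch <- match(vkey, ekey)
  stopifnot(!anyNA(vmatch))
  true_mu[vmatch] <- adj_mu
  false_edge_ids <- ed$id[vmatch[part$adjacencies$source ==
                                   "simulated-false"]]
  het_edge_ids <- ed$id[vmatch[part$adjacencies$source == "simulated-true" &
                                 adj_mu == 1]]
  hom_edge_ids <- ed$id[vmatch[part$adjacencies$source == "simulated-true" &
                                 adj_mu == 2]]
  # reference edges from balance at their left (t) vertex
  vrows <- which(ed$type == "V")
  vsum_at <- function(v) {
    hits <- vrows[ed$v1[vrows] == v | ed$v2[vrows] == v]
    sum(true_mu[hits] * ifelse(ed$v1[hits] == ed$v2[hits], 2, 1))
  }
  for (k in which(ed$type == "R")) {
    tv <- ed$v1[k]                       # t_j
    j <- graph$vertices$interval[match(tv, graph$vertices$vid)]
    true_mu[k] <- copy[j] - vsum_at(tv)
  }
  stopifnot(all(true_mu >= 0))
  stopifnot(all(balance_residuals(graph, true_mu) == 0))

  structure(list(partition = part, graph = graph,
                 truth = list(true_mu = stats::setNames(true_mu, ed$id),
                              copy = copy,
                              false_edge_ids = false_edge_ids,
                              het_edge_ids = het_edge_ids,
                              hom_edge_ids = hom_edge_ids,
                              deletions = dels),
                 params = params),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Simulated deletion genome:", nrow(x$truth$deletions), "deletions (",
      sum(x$truth$deletions$zygosity == "hom"), "hom /",
      sum(x$truth$deletions$zygosity == "het"), "het ),",
      length(x$truth$false_edge_ids), "false adjacencies,",
      nrow(x$graph$intervals), "intervals\n")
  invisible(x)
}

#' Simulate per-interval read depth
#'
#' Draws read-intervals (fragments) at `coverage`-fold physical coverage:
#' with probability `rho` a fragment comes from the unrearranged diploid
#' reference, otherwise from the rearranged genome; a fragment increments
#' `r_j` iff it lies entirely within one copy of reference interval `j`.
#' Finally per-interval Gaussian noise with variance `phi * r_j` is added
#' and counts are rounded and clamped at zero. In fast mode (default) the
#' counts are drawn directly from Poisson distributions with the equivalent
#' per-interval means, which uniform placement makes exact in distribution
#' up to fragment-length jitter.
#'
#' @param sim a [`sim_genome`][simulate_genome].
#' @param rho,phi error parameters; default from `sim$params`.
#' @param fast logical: Poisson sampling (default) or explicit fragment
#'   enumeration.
#' @param seed optional RNG seed.
#' @return a [depth_profile()]; the pre-noise counts are attached as
#'   `attr(, "r_prenoise")`.
#' @export
simulate_depth <- function(sim, rho = sim$params$rho, phi = sim$params$phi,
                           fast = TRUE, seed = NULL) {
  stopifnot(inherits(sim, "sim_genome"), rho >= 0, rho <= 1, phi >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- sim$params
  iv <- sim$graph$intervals
  copy <- sim$truth$copy
  L <- iv$length
  fbar <- p$frag_len_mean
  eff <- pmax(0, L - fbar)             # placements fully inside an interval
  C_len <- sum(copy * L)               # rearranged genome length (total DNA)
  n_frag <- round(p$coverage * C_len / fbar)

  p_cancer <- copy * eff / C_len       # per fragment, one interval copy
  p_ref <- 2 * eff / (2 * sum(L))
  if (fast) {
    lam <- n_frag * ((1 - rho) * p_cancer + rho * p_ref)
    r <- stats::rpois(length(L), lam)
  } else {
    n_ref <- stats::rbinom(1, n_frag, rho)
    n_can <- n_frag - n_ref
    count_src <- function(n, weights) {
      if (n == 0) return(integer(length(L)))
      j <- sample.int(length(L), n, replace = TRUE, prob = weights)
      pos <- floor(stats::runif(n, 0, L[j]))
      len <- pmax(1, round(stats::rnorm(n, fbar, p$frag_len_sd)))
      ok <- pos + len <= L[j]
      tabulate(j[ok], length(L))
    }
    r <- count_src(n_can, copy * L) + count_src(n_ref, 2 * L)
  }
  r_prenoise <- r
  if (phi > 0) {
    r <- pmax(0, round(r + stats::rnorm(length(r), 0, sqrt(phi * r))))
  }
  out <- depth_profile(iv, r)
  attr(out, "r_prenoise") <- r_prenoise
  out
}

#' Score multiplicity recovery against ground truth
#'
#' Percent of edges whose inferred multiplicity equals the true one:
#' overall, for interval edges, and for reference + variant edges; plus a
#' confusion tally of the heterozygous-deletion variant edges by called
#' multiplicity.
#'
#' @param true_mu ground-truth multiplicities (a `sim_genome`'s
#'   `truth$true_mu`, or the `sim_genome` itself).
#' @param inferred_mu a `"multiplicity_assignment"` or aligned numeric
#'   vector.
#' @param graph the shared graph (taken from `true_mu` when it is a
#'   `sim_genome`).
#' @return list with `pct_all`, `pct_interval`, `pct_refvar` (percentages)
#'   and `het_confusion` (named counts of het edges called at 0, 1, 2, >2).
#' @export
score_recovery <- function(true_mu, inferred_mu, graph = NULL) {
  het_ids <- NULL
  if (inherits(true_mu, "sim_genome")) {
    graph <- true_mu$graph
    het_ids <- true_mu$truth$het_edge_ids
    true_mu <- true_mu$truth$true_mu
  }
  if (is.null(graph)) stop("graph required when true_mu is a bare vector")
  if (inherits(inferred_mu, "multiplicity_assignment"))
    inferred_mu <- inferred_mu$mu
  if (length(true_mu) != nrow(graph$edges) ||
      length(inferred_mu) != nrow(graph$edges))
    stop("assignments are not on the same graph")
  eq <- true_mu == inferred_mu
  isI <- graph$edges$type == "I"
  out <- list(pct_all = 100 * mean(eq),
              pct_interval = 100 * mean(eq[isI]),
              pct_refvar = 100 * mean(eq[!isI]))
  if (!is.null(het_ids) && length(het_ids)) {
    called <- inferred_mu[match(het_ids, graph$edges$id)]
    out$het_confusion <- c(`0` = sum(called == 0), `1` = sum(called == 1),
                           `2` = sum(called == 2), `>2` = sum(called > 2))
  }
  out
}

#' Robustness grid over contamination and depth noise
#'
#' For each `(rho, phi)` cell, runs `n_trials` simulate-infer-score rounds
#' (trial genomes are shared across cells; depths are redrawn per cell) and
#' records the mean percent of correctly assigned edges per class. Reports
#' the maximum drop of each class mean relative to the noise-free
#' `(rho = 0, phi = 0)` cell.
#'
#' @param params a [sim_params()].
#' @param rho_values,phi_values grid values (defaults
#'   `c(0, 0.1, 0.2, 0.4)` and `c(0, 25, 100, 400)`).
#' @param seed RNG seed driving the whole experiment.
#' @param n_trials trials per cell (default `params$n_trials`).
#' @param fast passed to [simulate_depth()].
#' @param mu_max,max_states passed to the solver.
#' @return an object of class `"prego_grid"`: list with `table` (one row
#'   per cell: `rho`, `phi` and mean percentages) and `max_drop` (named
#'   vector, in percentage points, per class).
#' @export
run_grid <- function(params = sim_params(),
                     rho_values = c(0, 0.1, 0.2, 0.4),
                     phi_values = c(0, 25, 100, 400),
                     seed = 1, n_trials = params$n_trials, fast = TRUE,
                     mu_max = 50, max_states = 5e6) {
  set.seed(seed)
  genomes <- lapply(seq_len(n_trials), function(i) simulate_genome(params))
  cells <- expand.grid(phi = phi_values, rho = rho_values)[, c("rho", "phi")]
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    acc <- matrix(NA_real_, n_trials, 3)
    for (ti in seq_len(n_trials)) {
      sim <- genomes[[ti]]
      depth <- simulate_depth(sim, rho = cells$rho[ci], phi = cells$phi[ci],
                              fast = fast)
      prm <- likelihood_params(depth, mu_max = mu_max)
      fit <- solve_multiplicities(sim$graph, depth, prm,
                                  max_states = max_states)
      sc <- score_recovery(sim, fit)
      acc[ti, ] <- c(sc$pct_all, sc$pct_interval, sc$pct_refvar)
    }
    res[[ci]] <- data.frame(rho = cells$rho[ci], phi = cells$phi[ci],
                            pct_all = mean(acc[, 1]),
                            pct_interval = mean(acc[, 2]),
                            pct_refvar = mean(acc[, 3]))
  }
  tab <- do.call(rbind, res)
  base <- tab[tab$rho == 0 & tab$phi == 0, ]
  max_drop <- c(
    all = max(base$pct_all - tab$pct_all),
    interval = max(base$pct_interval - tab$pct_interval),
    refvar = max(base$pct_refvar - tab$pct_refvar))
  structure(list(table = tab, max_drop = max_drop, seed = seed,
                 n_trials = n_trials,
                 n_edges = mean(vapply(genomes, function(s)
                   nrow(s$graph$edges), numeric(1)))),
            class = "prego_grid")
}

#' @export
print.prego_grid <- function(x, ...) {
  cat("Robustness grid (", x$n_trials, " trials per cell):\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat("max drop vs (rho=0, phi=0), percentage points:\n")
  print(round(x$max_drop, 2))
  invisible(x)
}
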