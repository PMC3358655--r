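# Shared fixtures and independent oracles, all built in code.

# Four-interval toy chromosome whose junctions admit the reconstruction
# "A -B C D C D": intervals A,B (10 kb) and C,D (30 kb), variant edges
# t1-t2 (inversion-type), s2-s3 (inversion-type), t4-s3 (back edge), and
# depths proportional to copy numbers (1,1,2,2).
fig_toy <- function() {
  iv <- data.frame(chrom = "chr1", start = c(0, 10000, 20000, 50000),
                   end = c(10000, 20000, 50000, 80000), index = 1:4,
                   length = c(10000, 10000, 30000, 30000),
                   name = c("A", "B", "C", "D"), stringsAsFactors = FALSE)
  adj <- data.frame(index1 = c(1, 2, 3), side1 = c("e", "s", "s"),
                    index2 = c(2, 3, 4), side2 = c("e", "s", "e"),
                    support = 5, source = "measured",
                    stringsAsFactors = FALSE)
  graph <- build_graph(iv, adj)
  depth <- depth_profile(iv, r = c(100, 100, 600, 600))
  # edge order: I1..I4, R1..R3, V(t1,t2), V(s2,s3), V(s3,t4)
  mu_caption <- c(1, 1, 2, 2, 0, 0, 2, 1, 1, 1)
  list(graph = graph, intervals = iv, depth = depth,
       mu_caption = mu_caption)
}

# random small interval-adjacency graph with <= max_edges edges and random
# depths; used for solver-vs-oracle and tour property tests
rand_iagraph <- function(max_edges = 6) {
  repeat {
    n_chrom <- sample(1:2, 1)
    n_int <- sample(n_chrom:3, 1)
    chrom <- sort(sample(paste0("c", seq_len(n_chrom)), n_int,
                         replace = TRUE))
    if (length(unique(chrom)) < n_chrom) next
    len <- sample(1000:5000, n_int, replace = TRUE)
    start <- unlist(lapply(split(len, chrom), function(l)
      c(0, cumsum(l))[seq_along(l)]), use.names = FALSE)
    iv <- data.frame(chrom = chrom, start = start, end = start + len,
                     index = seq_len(n_int), length = len,
                     name = as.character(seq_len(n_int)),
                     stringsAsFactors = FALSE)
    budget <- max_edges - n_int - (n_int - n_chrom)
    if (budget < 0) next
    n_var <- sample(0:budget, 1)
    adj <- NULL
    if (n_var > 0)
      adj <- data.frame(index1 = sample(n_int, n_var, replace = TRUE),
                        side1 = sample(c("s", "e"), n_var, replace = TRUE),
                        index2 = sample(n_int, n_var, replace = TRUE),
                        side2 = sample(c("s", "e"), n_var, replace = TRUE),
                        support = 1, source = "measured",
                        stringsAsFactors = FALSE)
    g <- build_graph(iv, adj)
    r <- sample(0:100, n_int, replace = TRUE)
    if (sum(r) == 0) r[1] <- 10
    return(list(graph = g, depth = depth_profile(iv, r)))
  }
}

# small deletion genome for recovery tests
mini_sim_params <- function() {
  sim_params(n_hom_del = 3, n_het_del = 3, n_false_adjacencies = 2,
             genome = data.frame(chrom = c("c1", "c2"),
                                 length = c(4e6, 3e6)))
}

# per-interval expected fragment counts at rho = 0 (coverage * copy *
# contained-placement fraction), derived from first principles
expected_counts <- function(sim) {
  iv <- sim$graph$intervals
  f <- sim$params$frag_len_mean
  round(sim$params$coverage * sim$truth$copy * pmax(0, iv$length - f) / f)
}

# two-sided Fisher p by direct hypergeometric enumeration (independent of
# stats::fisher.test): sum of P(tables with same margins) <= P(observed)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
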