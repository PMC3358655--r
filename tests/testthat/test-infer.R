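# Poisson likelihood, multiplicity inference, and the brute-force oracle.

test_that("expected depth follows N * L_j / L_R * mu / tau", {
  iv <- data.frame(chrom = "c", start = c(0, 100), end = c(100, 1000),
                   index = 1:2, length = c(100, 900), name = c("1", "2"))
  d <- depth_profile(iv, r = c(100, 900))       # N = 1000, lambda_1 = 100
  p <- likelihood_params(d)
  expect_equal(expected_depth(p, 1, 2), 100)
  expect_equal(expected_depth(p, 1, 0), 0)

  iv2 <- data.frame(chrom = "c", start = c(0, 30), end = c(30, 300),
                    index = 1:2, length = c(30, 270), name = c("1", "2"))
  d2 <- depth_profile(iv2, r = c(45, 405))      # N = 450, lambda_1 = 45
  expect_equal(expected_depth(likelihood_params(d2), 1, 3), 67.5)
})

test_that("negative log-likelihood matches its closed form", {
  iv <- data.frame(chrom = "c", start = 0, end = 100, index = 1,
                   length = 100, name = "1")
  d <- depth_profile(iv, r = 10)                # lambda = 10
  p <- likelihood_params(d)
  expect_equal(neg_log_likelihood(p, 2), 10 - 10 * log(10),
               tolerance = 1e-10)
  # all-zero counts with mu = 0: empty objective
  d0 <- depth_profile(iv, r = 0)
  expect_equal(neg_log_likelihood(likelihood_params(d0), 0), 0)
  expect_error(neg_log_likelihood(p, 2, r = -1), "non-negative")
})

test_that("the discrete per-interval optimum neighbors the continuous one", {
  set.seed(42)
  for (i in 1:20) {
    lam <- runif(1, 5, 200); r <- sample(1:400, 1); tau <- 2
    cost <- prego:::.interval_cost(lam, r, tau, 0.05, 30)
    best <- which.min(cost) - 1
    mu_cont <- tau * r / lam
    if (best > 0 && best < 30)
      expect_lte(abs(best - mu_cont), 1)
  }
})

test_that("balance residuals count loops twice and vanish for solver output", {
  iv <- data.frame(chrom = "c", start = c(0, 100, 200),
                   end = c(100, 200, 300), index = 1:3, length = 100,
                   name = as.character(1:3))
  # self-loop at t2 plus chain
  adj <- data.frame(index1 = 2, side1 = "e", index2 = 2, side2 = "e",
                    support = 1, source = "measured")
  g <- build_graph(iv, adj)
  # mu: I = (1,3,1), R = (1,1), loop = 1 -> residual at t2: 3 - 1 - 2*1 = 0
  mu <- c(1, 3, 1, 1, 1, 1)
  res <- balance_residuals(g, mu)
  expect_equal(unname(res[["t2"]]), 0)
  # drop the loop: residual 2 at t2
  mu2 <- c(1, 3, 1, 1, 1, 0)
  expect_equal(unname(balance_residuals(g, mu2)[["t2"]]), 2)

  d <- depth_profile(iv, c(50, 150, 50))
  fit <- solve_multiplicities(g, d)
  expect_true(all(balance_residuals(g, fit) == 0))
})

test_that("solver equals exhaustive enumeration on random small graphs", {
  set.seed(101)
  for (i in 1:60) {
    inst <- rand_iagraph(max_edges = 6)
    p <- likelihood_params(inst$depth, mu_max = 4)
    fit <- solve_multiplicities(inst$graph, inst$depth, p)
    orc <- brute_force_oracle(inst$graph, inst$depth, p)
    expect_equal(fit$solver_status, orc$solver_status)
    expect_equal(fit$objective_value, orc$objective_value,
                 tolerance = 1e-9)
    # solver optimum is in the oracle's co-optimal set
    expect_true(any(apply(orc$optima, 1, function(m)
      all(m == unname(fit$mu)))))
  }
})

test_that("fixed interval counts are honored or reported infeasible", {
  toy <- fig_toy()
  fit <- solve_multiplicities(toy$graph, toy$depth,
                              fixed_interval_counts = c(1, 1, 2, 2))
  expect_equal(fit$solver_status, "optimal")
  expect_equal(unname(fit$chat), c(1, 1, 2, 2))
  # odd copy at an isolated boundary with no junction: infeasible
  iv <- data.frame(chrom = "c", start = c(0, 100), end = c(100, 200),
                   index = 1:2, length = 100, name = c("1", "2"))
  g <- build_graph(iv, NULL)
  d <- depth_profile(iv, c(50, 50))
  bad <- solve_multiplicities(g, d, fixed_interval_counts = c(1, 2))
  expect_equal(bad$solver_status, "infeasible")
})

test_that("uniform depth with no variants recovers mu = tau everywhere", {
  iv <- data.frame(chrom = "c", start = c(0, 1000, 3000),
                   end = c(1000, 3000, 6000), index = 1:3,
                   length = c(1000, 2000, 3000), name = as.character(1:3))
  r <- c(100, 200, 300)                       # r_j = lambda_j exactly
  d <- depth_profile(iv, r)
  fit <- solve_multiplicities(build_graph(iv, NULL), d)
  expect_true(all(fit$mu == 2))
})

test_that("doubling all counts leaves the optimum unchanged", {
  set.seed(77)
  for (i in 1:10) {
    inst <- rand_iagraph(max_edges = 6)
    p1 <- likelihood_params(inst$depth, mu_max = 4)
    f1 <- solve_multiplicities(inst$graph, inst$depth, p1)
    d2 <- depth_profile(inst$graph$intervals, 2 * inst$depth$r)
    f2 <- solve_multiplicities(inst$graph, d2,
                               likelihood_params(d2, mu_max = 4))
    expect_identical(f1$mu, f2$mu)
  }
})

test_that("co-optimal solutions exist for a trivial reciprocal pair", {
  iv <- data.frame(chrom = "c", start = c(0, 1000, 2000, 3000),
                   end = c(1000, 2000, 3000, 4000), index = 1:4,
                   length = 1000, name = as.character(1:4))
  adj <- data.frame(index1 = c(1, 2), side1 = c("e", "s"),
                    index2 = c(3, 4), side2 = c("e", "s"),
                    support = 5, source = "measured")
  g <- build_graph(iv, adj)
  d <- depth_profile(iv, c(100, 100, 100, 100))
  orc <- brute_force_oracle(g, d, likelihood_params(d, mu_max = 3))
  expect_gte(nrow(orc$optima), 2)
})

test_that("prefer_sparse breaks ties toward unused variant edges", {
  toy <- fig_toy()
  fit <- solve_multiplicities(toy$graph, toy$depth, prefer_sparse = TRUE)
  ed <- toy$graph$edges
  # the inversion-like pair can be zeroed without changing the objective
  expect_equal(sum(fit$mu[ed$type == "V"] > 0), 1)
  expect_equal(unname(fit$chat), c(1, 1, 2, 2))
})

test_that("the oracle refuses oversized state spaces", {
  toy <- fig_toy()
  expect_error(brute_force_oracle(toy$graph, toy$depth,
                                  likelihood_params(toy$depth, mu_max = 50),
                                  guard = 1000),
               "state space too large")
})
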