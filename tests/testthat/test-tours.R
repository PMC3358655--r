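# Eulerizability and alternating tour extraction.

test_that("eulerizability mirrors the balance residuals", {
  toy <- fig_toy()
  expect_true(is_eulerizable(toy$graph, toy$mu_caption)$eulerizable)

  # zero an internal reference edge under mu(I) = 1 everywhere: unbalanced
  iv <- data.frame(chrom = "c", start = c(0, 100), end = c(100, 200),
                   index = 1:2, length = 100, name = c("1", "2"))
  g <- build_graph(iv, NULL)
  chk <- is_eulerizable(g, c(1, 1, 0))
  expect_false(chk$eulerizable)
  expect_setequal(chk$unbalanced_vertices, c("t1", "s2"))
  expect_error(extract_tours(g, c(1, 1, 0)), "not Eulerizable")
})

test_that("the toy instance decomposes into the expected block sequence", {
  toy <- fig_toy()
  td <- extract_tours(toy$graph, toy$mu_caption)
  expect_length(td$tours, 1)
  expect_length(td$leftover_cycles, 0)
  expect_equal(spell_genome(td$tours[[1]], toy$intervals$name),
               "A -B C D C D")
  expect_equal(tour_edge_counts(td, toy$graph),
               as.integer(toy$mu_caption))
})

test_that("single interval gives the single-block tour", {
  iv <- data.frame(chrom = "c", start = 0, end = 10, index = 1, length = 10,
                   name = "I")
  g <- build_graph(iv, NULL)
  td <- extract_tours(g, 1)
  expect_length(td$tours, 1)
  expect_equal(td$tours[[1]]$blocks, 1)
  expect_equal(spell_genome(td$tours[[1]], "I"), "I")
  expect_equal(spell_genome(list(blocks = integer(0))), "")
})

test_that("a reciprocal translocation with unit multiplicities yields two covering tours", {
  iv <- data.frame(chrom = c("a", "a", "b", "b"),
                   start = c(0, 100, 0, 100), end = c(100, 200, 100, 200),
                   index = 1:4, length = 100, name = c("A1", "A2", "B1", "B2"))
  adj <- data.frame(index1 = c(1, 2), side1 = c("e", "s"),
                    index2 = c(4, 3), side2 = c("s", "e"),
                    support = 5, source = "measured")
  g <- build_graph(iv, adj)
  # all interval and variant edges 1, reference edges 0
  mu <- ifelse(g$edges$type == "R", 0, 1)
  td <- extract_tours(g, mu)
  expect_length(td$tours, 2)
  expect_length(td$leftover_cycles, 0)
  expect_equal(tour_edge_counts(td, g), as.integer(mu))
})

test_that("tours alternate interval and non-interval edges and conserve multiplicity", {
  set.seed(202)
  for (i in 1:40) {
    inst <- rand_iagraph(max_edges = 6)
    fit <- solve_multiplicities(inst$graph, inst$depth,
                                likelihood_params(inst$depth, mu_max = 4))
    td <- suppressWarnings(extract_tours(inst$graph, fit))
    expect_equal(tour_edge_counts(td, inst$graph),
                 as.integer(unname(fit$mu)))
    for (t in c(td$tours, td$leftover_cycles)) {
      types <- inst$graph$edges$type[match(t$edge_path,
                                           inst$graph$edges$id)]
      isI <- types == "I"
      if (length(isI) > 1)
        expect_true(all(isI[-1] != isI[-length(isI)]))
    }
  }
})

test_that("eulerizable assignments extract cleanly and unbalanced ones are rejected", {
  set.seed(303)
  for (i in 1:50) {
    inst <- rand_iagraph(max_edges = 6)
    mu <- sample(0:3, nrow(inst$graph$edges), replace = TRUE)
    ok <- is_eulerizable(inst$graph, mu)$eulerizable
    if (ok) {
      td <- suppressWarnings(extract_tours(inst$graph, mu))
      expect_equal(tour_edge_counts(td, inst$graph), as.integer(mu))
    } else {
      expect_error(extract_tours(inst$graph, mu), "not Eulerizable")
    }
  }
})

test_that("reconstructed genome length equals the copy-weighted interval sum", {
  set.seed(404)
  for (i in 1:10) {
    inst <- rand_iagraph(max_edges = 6)
    fit <- solve_multiplicities(inst$graph, inst$depth,
                                likelihood_params(inst$depth, mu_max = 4))
    td <- suppressWarnings(extract_tours(inst$graph, fit))
    L <- inst$graph$intervals$length
    tot <- sum(vapply(c(td$tours, td$leftover_cycles), function(t)
      sum(L[abs(t$blocks)]), numeric(1)))
    expect_equal(tot, sum(fit$chat * L))
  }
})

test_that("reversing a tour mirrors and sign-flips its spelling", {
  toy <- fig_toy()
  td <- extract_tours(toy$graph, toy$mu_caption)
  t1 <- td$tours[[1]]
  expect_equal(reverse_tour(t1)$blocks, rev(-t1$blocks))
  expect_equal(spell_genome(reverse_tour(t1), toy$intervals$name),
               "-D -C -D -C B -A")
})

test_that("balanced telomere-free remainders are emitted as closed cycles", {
  # tandem-duplication back edge traversed without touching telomeres:
  # interval 2 amplified as a separate circle
  iv <- data.frame(chrom = "c", start = c(0, 100, 200),
                   end = c(100, 200, 300), index = 1:3, length = 100,
                   name = c("A", "B", "C"))
  adj <- data.frame(index1 = 2, side1 = "s", index2 = 2, side2 = "e",
                    support = 5, source = "measured")
  g <- build_graph(iv, adj)
  # linear genome A B C plus one extra circular copy of B
  mu <- c(1, 2, 1, 1, 1, 1)
  expect_true(is_eulerizable(g, mu)$eulerizable)
  expect_warning(td <- extract_tours(g, mu), "closed cycle")
  expect_length(td$tours, 1)
  expect_length(td$leftover_cycles, 1)
  expect_true(td$leftover_cycles[[1]]$closed)
  expect_equal(tour_edge_counts(td, g), as.integer(mu))
})

test_that("seeded extraction is reproducible", {
  toy <- fig_toy()
  a <- extract_tours(toy$graph, toy$mu_caption, seed = 9)
  b <- extract_tours(toy$graph, toy$mu_caption, seed = 9)
  expect_identical(a, b)
})
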