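# Variant-edge geometry, reciprocal partnerships, triviality, and the
# usage-association Fisher test.

# one chromosome, six intervals: enough room for every intra-chromosomal
# geometry
geo_fixture <- function(adj) {
  n <- 6
  iv <- data.frame(chrom = "c", start = (0:(n - 1)) * 100,
                   end = (1:n) * 100, index = 1:n, length = 100,
                   name = as.character(1:n))
  build_graph(iv, adj)
}

test_that("variant geometries follow endpoint orientations", {
  adj <- data.frame(
    index1 = c(2, 2, 2, 3, 2), side1 = c("e", "s", "e", "e", "e"),
    index2 = c(4, 4, 4, 3, 2), side2 = c("s", "e", "e", "e", "e"),
    support = 5, source = "measured")
  # rows: t2-s4 deletion, s2-t4 tandem-dup, t2-t4 inversion, t3-t3 loop,
  # t2-t2 loop
  g <- geo_fixture(adj[1:4, ])
  ids <- g$edges$id[g$edges$type == "V"]
  geo <- classify_geometry(g, ids)
  expect_setequal(unname(geo), c("deletion-type", "tandem-duplication-type",
                                 "inversion-type", "inverted-repeat-loop"))
  loop <- g$edges$id[g$edges$type == "V" & g$edges$v1 == g$edges$v2]
  expect_equal(unname(classify_geometry(g, loop)), "inverted-repeat-loop")

  # translocations: opposite end types classical, same types Robertsonian
  iv2 <- data.frame(chrom = c("a", "a", "b", "b"),
                    start = c(0, 100, 0, 100), end = c(100, 200, 100, 200),
                    index = 1:4, length = 100, name = as.character(1:4))
  adj2 <- data.frame(index1 = c(1, 1), side1 = c("e", "e"),
                     index2 = c(4, 3), side2 = c("s", "e"),
                     support = 5, source = "measured")
  g2 <- build_graph(iv2, adj2)
  ids2 <- g2$edges$id[g2$edges$type == "V"]
  geo2 <- classify_geometry(g2, ids2)
  expect_setequal(unname(geo2),
                  c("classical-translocation", "Robertsonian-translocation"))
  expect_error(classify_geometry(g2, g2$edges$id[1]), "not a variant edge")
})

test_that("sigma edges are reported as telomere loss, not classified", {
  iv <- data.frame(chrom = "c", start = c(0, 100), end = c(100, 200),
                   index = 1:2, length = 100, name = c("1", "2"))
  g <- detect_telomere_loss(build_graph(iv, NULL),
                            depth_profile(iv, c(1000, 1)), 0.5)
  sid <- g$edges$id[g$edges$source == "telomere-loss" &
                      !is.na(g$edges$source)]
  expect_equal(unname(classify_geometry(g, sid)), "telomere-loss")
})

test_that("reciprocal partners cover the four free ends of two breakpoints", {
  # inversion pair: (t2, t4) and (s3, s5) share breakpoints 2 and 4
  adj <- data.frame(index1 = c(2, 3), side1 = c("e", "s"),
                    index2 = c(4, 5), side2 = c("e", "s"),
                    support = 5, source = "measured")
  g <- geo_fixture(adj)
  pairs <- find_reciprocal_pairs(g)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$p, 2)
  expect_equal(pairs$q, 4)

  # lone deletion edge: non-reciprocal
  lone <- geo_fixture(data.frame(index1 = 2, side1 = "e", index2 = 4,
                                 side2 = "s", support = 5,
                                 source = "measured"))
  expect_equal(nrow(find_reciprocal_pairs(lone)), 0)

  # three candidates at the same two breakpoints: one deterministic pair
  adj3 <- data.frame(index1 = c(2, 3, 2), side1 = c("e", "s", "e"),
                     index2 = c(4, 5, 5), side2 = c("e", "s", "s"),
                     support = 5, source = "measured")
  g3 <- geo_fixture(adj3)
  pairs3 <- find_reciprocal_pairs(g3)
  expect_equal(nrow(pairs3), 1)
  ann3 <- annotate_variants(g3, rep(1, nrow(g3$edges)))
  expect_equal(sum(!is.na(ann3$reciprocal_partner)), 2)
  # partnership is symmetric
  a <- ann3[!is.na(ann3$reciprocal_partner), ]
  expect_equal(a$reciprocal_partner[1], a$edge[2])
  expect_equal(a$reciprocal_partner[2], a$edge[1])
})

trivial_fixture <- function() {
  adj <- data.frame(index1 = c(2, 3), side1 = c("e", "s"),
                    index2 = c(4, 5), side2 = c("e", "s"),
                    support = 5, source = "measured")
  geo_fixture(adj)
}

test_that("triviality requires equal variant and flanking interval multiplicities", {
  g <- trivial_fixture()
  pair <- find_reciprocal_pairs(g)
  ne <- nrow(g$edges)
  vrows <- which(g$edges$type == "V")
  mu <- rep(2L, ne); mu[vrows] <- 1L
  # balance the references: mu(R) = 1 at the four breakpoint boundaries
  rrows <- which(g$edges$type == "R")
  mu[rrows[c(2, 4)]] <- 1L
  expect_true(all(balance_residuals(g, mu) == 0))
  expect_true(is_trivial(g, pair, mu))
  mu2 <- mu; mu2[vrows[1]] <- 2L
  expect_false(is_trivial(g, pair, mu2))
})

test_that("zeroing a trivial pair preserves balance and the objective exactly", {
  g <- trivial_fixture()
  iv <- g$intervals
  d <- depth_profile(iv, r = rep(100, nrow(iv)))
  p <- likelihood_params(d)
  vrows <- which(g$edges$type == "V")
  rrows <- which(g$edges$type == "R")
  mu <- rep(2L, nrow(g$edges)); mu[vrows] <- 1L; mu[rrows[c(2, 4)]] <- 1L
  k <- mu[vrows[1]]
  mu0 <- mu
  mu0[vrows] <- 0L
  mu0[rrows[c(2, 4)]] <- mu0[rrows[c(2, 4)]] + k
  expect_true(all(balance_residuals(g, mu) == 0))
  expect_true(all(balance_residuals(g, mu0) == 0))
  iord <- order(g$edges$interval[g$edges$type == "I"])
  chat <- mu[g$edges$type == "I"][iord]
  chat0 <- mu0[g$edges$type == "I"][iord]
  expect_equal(neg_log_likelihood(p, chat), neg_log_likelihood(p, chat0),
               tolerance = 1e-9)
})

test_that("the Fisher test agrees with hypergeometric enumeration", {
  set.seed(500)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    tab <- matrix(cells, 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(usage_fisher_test(tab)$p, 1)
    } else {
      expect_equal(usage_fisher_test(tab)$p, fisher_oracle(tab),
                   tolerance = 1e-9)
    }
  }
  # empty table: degenerate, p = 1
  res <- usage_fisher_test(matrix(0, 2, 2))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("the per-class association table assembles counts correctly", {
  g <- trivial_fixture()
  vrows <- which(g$edges$type == "V")
  rrows <- which(g$edges$type == "R")
  mu <- rep(2L, nrow(g$edges)); mu[vrows] <- 1L; mu[rrows[c(2, 4)]] <- 1L
  ann <- annotate_variants(g, mu)
  res <- usage_association_test(ann)
  inv <- res[res$class == "inversion-type", ]
  # the pair is trivial and used: counted in R_all, excluded from non-triv
  expect_equal(inv$R_all_used, 2)
  expect_equal(inv$R_nontriv_used + inv$R_nontriv_unused, 0)
  expect_true(inv$degenerate)
  expect_equal(inv$p_value, 1)
})
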