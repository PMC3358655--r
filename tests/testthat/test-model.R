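# Reference partitioning, adjacency filtering, graph construction and
# telomere-loss detection.

chrom1 <- data.frame(chrom = "chr1", length = 100)

adj_at <- function(cuts, sides = c("e", "s"), chrom = "chr1",
                   support = 5) {
  data.frame(chrom1 = chrom, cut1 = cuts[1], side1 = sides[1],
             chrom2 = chrom, cut2 = cuts[2], side2 = sides[2],
             support = support, source = "measured",
             stringsAsFactors = FALSE)
}

test_that("breakpoints cut chromosomes into tiling intervals", {
  part <- partition_reference(chrom1, adj_at(c(40, 70)),
                              min_interval_len = 1)
  expect_equal(part$intervals$start, c(0, 40, 70))
  expect_equal(part$intervals$end, c(40, 70, 100))
  expect_equal(sum(part$intervals$length), 100)

  # no adjacencies: one interval per chromosome
  two <- data.frame(chrom = c("a", "b"), length = c(50, 60))
  part2 <- partition_reference(two, NULL)
  expect_equal(nrow(part2$intervals), 2)
  expect_equal(part2$intervals$length, c(50, 60))
})

test_that("breakpoints violating the minimum interval length are rejected with their adjacency", {
  part <- partition_reference(chrom1, adj_at(c(40, 44)),
                              min_interval_len = 8000)
  expect_equal(nrow(part$intervals), 1)
  expect_equal(nrow(part$adjacencies), 0)
  expect_equal(nrow(part$dropped), 1)
  expect_equal(part$dropped$reason, "min-interval")
})

test_that("partition rejects coordinates outside the chromosome", {
  expect_error(partition_reference(chrom1, adj_at(c(40, 140))),
               "outside chromosome")
  bad <- adj_at(c(40, 70)); bad$chrom2 <- "chrX"
  expect_error(partition_reference(chrom1, bad), "unknown chromosome")
})

test_that("adjacency filters apply support, centromere and normal predicates", {
  cl <- rbind(adj_at(c(1e6, 2e6), support = 5),
              adj_at(c(5e6, 6e6), support = 10),
              adj_at(c(8e6, 9e6), support = 2))
  # support alone
  expect_equal(nrow(filter_adjacencies(adj_at(c(10, 20), support = 4),
                                       min_support = 5)), 0)
  # no centromere file: filter is a no-op
  expect_equal(nrow(filter_adjacencies(cl, min_support = 1)), 3)
  # support >= 5 and first cluster within 1 Mb of a centromere: 1 survivor
  cents <- data.frame(chrom = "chr1", start = 1.5e6, end = 1.6e6)
  kept <- filter_adjacencies(cl, min_support = 5, centromeres = cents)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$cut1, 5e6)
  expect_setequal(attr(kept, "dropped")$reason, c("centromere", "support"))
  # matched-normal overlap removal
  kept2 <- filter_adjacencies(cl, min_support = 1,
                              normal_clusters = adj_at(c(5e6 + 100, 6e6)),
                              normal_slop = 1000)
  expect_equal(nrow(kept2), 2)
})

test_that("graph construction follows the incidence rules", {
  toy <- fig_toy()
  g <- toy$graph
  ed <- g$edges
  expect_equal(sum(ed$type == "I"), 4)
  expect_equal(sum(ed$type == "R"), 3)
  expect_equal(sum(ed$type == "V"), 3)
  # every non-sigma vertex incident to exactly one interval edge
  for (v in g$vertices$vid) {
    icnt <- sum((ed$v1 == v | ed$v2 == v) & ed$type == "I")
    expect_equal(icnt, 1)
  }
  expect_equal(sum(g$vertices$telomeric), 2)

  # single interval: no reference or variant edges
  iv1 <- data.frame(chrom = "c", start = 0, end = 10, index = 1, length = 10,
                    name = "1")
  g1 <- build_graph(iv1, NULL)
  expect_equal(g1$edges$type, "I")
  expect_true(all(g1$vertices$telomeric))

  # two chromosomes, one inter-chromosomal adjacency: |T| = 4, one V edge
  iv2 <- data.frame(chrom = c("a", "a", "b"), start = c(0, 10, 0),
                    end = c(10, 20, 30), index = 1:3,
                    length = c(10, 10, 30), name = as.character(1:3))
  adj2 <- data.frame(index1 = 1, side1 = "e", index2 = 3, side2 = "s",
                     support = 5, source = "measured")
  g2 <- build_graph(iv2, adj2)
  expect_equal(sum(g2$vertices$telomeric), 4)
  vv <- g2$edges[g2$edges$type == "V", ]
  expect_equal(nrow(vv), 1)
  ch <- g2$vertices$chrom[match(c(vv$v1, vv$v2), g2$vertices$vid)]
  expect_equal(sort(ch), c("a", "b"))
  expect_equal(sum(g2$edges$type == "R"),
               nrow(iv2) - length(unique(iv2$chrom)))

  # duplicate adjacencies collapse with summed support
  g3 <- build_graph(iv2, rbind(adj2, adj2))
  expect_equal(sum(g3$edges$type == "V"), 1)
  expect_equal(g3$edges$support[g3$edges$type == "V"], 10)
})

test_that("graph construction rejects adjacencies to missing intervals", {
  iv1 <- data.frame(chrom = "c", start = 0, end = 10, index = 1, length = 10,
                    name = "1")
  adj <- data.frame(index1 = 1, side1 = "e", index2 = 2, side2 = "s",
                    support = 5, source = "measured")
  expect_error(build_graph(iv1, adj), "outside the partition")
})

test_that("telomere loss adds a sigma vertex on a qualifying coverage drop", {
  iv <- data.frame(chrom = "chr1", start = c(0, 50000),
                   end = c(50000, 100000), index = 1:2, length = 50000,
                   name = c("A", "B"))
  g <- build_graph(iv, NULL)

  # uniform depth: unchanged
  expect_identical(detect_telomere_loss(g, depth_profile(iv, c(500, 500))),
                   g)

  # sharp right-end drop: sigma added, displaced terminal leaves T
  dep <- depth_profile(iv, c(5000, 50))
  g2 <- detect_telomere_loss(g, dep, 0.5)
  expect_true(any(g2$vertices$sigma))
  expect_equal(sum(g2$vertices$telomeric), 2)      # parity preserved
  expect_false(g2$vertices$telomeric[g2$vertices$label == "t2"])
  sv <- g2$vertices$vid[g2$vertices$sigma]
  se <- g2$edges[g2$edges$v2 == sv | g2$edges$v1 == sv, ]
  expect_equal(nrow(se), 1)
  expect_equal(se$source, "telomere-loss")
  # edge attaches to the boundary vertex of the retained interval (t1)
  other <- setdiff(c(se$v1, se$v2), sv)
  expect_equal(g2$vertices$label[match(other, g2$vertices$vid)], "t1")

  # a variant edge on the lost arm explains the drop: no sigma
  iv3 <- data.frame(chrom = "chr1", start = c(0, 40000, 80000),
                    end = c(40000, 80000, 120000), index = 1:3,
                    length = 40000, name = c("A", "B", "C"))
  adj3 <- data.frame(index1 = 2, side1 = "s", index2 = 3, side2 = "s",
                     support = 5, source = "measured")
  g3 <- build_graph(iv3, adj3)
  dep3 <- depth_profile(iv3, c(4000, 100, 100))
  expect_identical(detect_telomere_loss(g3, dep3, 0.5), g3)
})

test_that("inference remains feasible after the sigma extension and forces the lost arm to zero", {
  iv <- data.frame(chrom = "chr1", start = c(0, 50000),
                   end = c(50000, 100000), index = 1:2, length = 50000,
                   name = c("A", "B"))
  g <- build_graph(iv, NULL)
  dep <- depth_profile(iv, c(5000, 40))
  g2 <- detect_telomere_loss(g, dep, 0.5)
  fit <- solve_multiplicities(g2, dep)
  expect_equal(fit$solver_status, "optimal")
  expect_equal(unname(fit$chat[2]), 0)
  td <- extract_tours(g2, fit)
  expect_true(all(vapply(td$tours, function(t)
    t$end_vertex == "sigma1" || t$start_vertex == "sigma1", logical(1))))
})
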