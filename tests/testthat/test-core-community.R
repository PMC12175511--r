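test_that("occupancy is the detection fraction within a location", {
  counts <- matrix(c(1L, 0L, 1L, 1L, 0L,
                     0L, 0L, 0L, 0L, 0L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("b1", "b2"), paste0("s", 1:5)))
  x <- OtuExperiment(counts, domain = c(b1 = "bacteria", b2 = "bacteria"))
  occ <- occupancy(x, grouping = rep("D", 5))
  expect_equal(occ$fraction["b1", "D"], 0.6)
  expect_equal(occ$fraction["b2", "D"], 0)

  # 10 of 50 samples -> 0.2
  m <- matrix(0L, 1, 50, dimnames = list("b1", paste0("s", 1:50)))
  m[1, 1:10] <- 3L
  x2 <- OtuExperiment(m, domain = c(b1 = "bacteria"))
  expect_equal(occupancy(x2, grouping = rep("D", 50))$fraction[1, 1], 0.2)

  # invariance to rescaling a sample's counts
  x3 <- randomTable(seed = 8)
  o1 <- occupancy(x3)$fraction
  m3 <- otuCounts(x3)
  m3[, 1] <- m3[, 1] * 7L
  x4 <- OtuExperiment(m3, domain = taxonDomain(x3),
                      sample_data = sampleData(x3))
  expect_identical(occupancy(x4)$fraction, o1)

  expect_error(occupancy(x3, grouping = rep(NA, ncol(x3))))
})

test_that("core partition matches brute-force set algebra", {
  # explicit set example: core is the common element
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("b", "e"))
  # emulate with a table: taxon present >= once in the location iff in set
  taxa <- sort(unique(unlist(sets)))
  counts <- sapply(names(sets), function(l)
    as.integer(taxa %in% sets[[l]]))
  rownames(counts) <- taxa
  colnames(counts) <- paste0(names(sets), "1")
  dom <- setNames(rep("bacteria", length(taxa)), taxa)
  x <- OtuExperiment(counts, domain = dom)
  part <- corePartition(x, thresholds = c(bacteria = 1),
                        grouping = names(sets))
  expect_identical(part$core, "b")
  bf <- bruteVennCounts(sets)
  expect_equal(part$venn_counts[names(bf)], c(bf),
               ignore_attr = TRUE)
  expect_equal(sum(part$venn_counts), length(unique(unlist(sets))))

  expect_error(corePartition(x, thresholds = c(fungi = 1),
                             grouping = names(sets)), "threshold")
})

test_that("random tables give Venn counts consistent with set algebra", {
  for (seed in 1:5) {
    x <- randomTable(n_taxa = 40, n_samples = 16, n_loc = 4, seed = seed,
                     depth = 300)
    part <- corePartition(x, thresholds = c(bacteria = 2, fungi = 2))
    bf <- bruteVennCounts(part$retained)
    expect_equal(part$venn_counts[names(bf)], c(bf), ignore_attr = TRUE)
    expect_equal(sum(part$venn_counts),
                 length(unique(unlist(part$retained))))
    # core is inside every location's retained set
    for (l in names(part$retained))
      expect_true(all(part$core %in% part$retained[[l]]))
    expect_identical(part$core, Reduce(intersect, part$retained))
  }
})

test_that("known per-location passing pattern yields the expected core", {
  # construct 4 locations x 4 samples; exactly 7 of 20 taxa pass a
  # >=2-samples threshold in every location
  set.seed(77)
  taxa <- sprintf("b%02d", 1:20)
  locs <- c("D", "G", "M", "T")
  counts <- matrix(0L, 20, 16,
                   dimnames = list(taxa, paste0(rep(locs, each = 4), 1:4)))
  grouping <- rep(locs, each = 4)
  core_taxa <- taxa[1:7]
  for (t in core_taxa)
    for (l in locs)
      counts[t, which(grouping == l)[1:2]] <- 5L
  for (t in taxa[8:20]) {
    l <- sample(locs, 1)       # passes in only one location
    counts[t, which(grouping == l)[1:2]] <- 5L
  }
  x <- OtuExperiment(counts, domain = setNames(rep("bacteria", 20), taxa))
  part <- corePartition(x, thresholds = c(bacteria = 2),
                        grouping = grouping)
  expect_setequal(part$core, core_taxa)
  expect_equal(length(part$core), 7)
})

test_that("core abundance fractions use domain-specific denominators", {
  counts <- matrix(c(30L, 70L, 10L, 90L), nrow = 2,
                   dimnames = list(c("b1", "b2"), c("s1", "s2")))
  x <- OtuExperiment(counts, domain = c(b1 = "bacteria", b2 = "bacteria"))
  f <- coreAbundanceFraction(x, "b1")
  expect_equal(unname(f$per_sample[, "bacteria"]), c(0.3, 0.1))

  y <- tinyTable()
  all_f <- coreAbundanceFraction(y, rownames(y))
  expect_true(all(all_f$per_sample == 1))
  expect_warning(none <- coreAbundanceFraction(y, character()), "empty")
  expect_true(all(none$per_sample == 0))
})

test_that("abundance-occupancy relation recovers monotone and null patterns", {
  # monotone: abundance ranks == occupancy ranks -> rho 1
  set.seed(12)
  n <- 10
  counts <- matrix(0L, n, 10,
                   dimnames = list(sprintf("b%02d", 1:n), paste0("s", 1:10)))
  for (i in 1:n) counts[i, seq_len(i)] <- 1L + i
  x <- OtuExperiment(counts,
                     domain = setNames(rep("bacteria", n), rownames(counts)),
                     sample_data = data.frame(
                       sample_id = colnames(counts), location = "D",
                       plot = rep(1:5, 2), subsample = rep(c("A", "B"), 5)))
  ao <- abundanceOccupancy(x, "D")
  expect_gt(ao$rho, 0.9)
  expect_true(all(ao$table$occupancy >= 0 & ao$table$occupancy <= 1))
  expect_equal(ao$table$ratio,
               ao$table$occupancy / ao$table$mean_abundance)

  # permutation oracle: shuffled pairings give mean rho approx 0
  set.seed(99)
  rhos <- replicate(500, {
    a <- runif(50); o <- sample(runif(50))
    suppressWarnings(cor(a, o, method = "spearman"))
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("alpha diversity matches closed forms and the tree oracle", {
  counts <- matrix(25L, 4, 1, dimnames = list(paste0("b", 1:4), "s1"))
  x <- OtuExperiment(counts,
                     domain = setNames(rep("bacteria", 4), rownames(counts)))
  a <- alphaDiversity(x)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$evenness, 1, tolerance = 1e-12)
  expect_equal(a$simpson, 1 - 4 * 0.25^2, tolerance = 1e-12)

  one <- OtuExperiment(matrix(9L, 1, 1, dimnames = list("b1", "s1")),
                       domain = c(b1 = "bacteria"))
  a1 <- alphaDiversity(one)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$simpson, 0)
  expect_true(is.na(a1$evenness))  # single-taxon sample flagged

  # Faith PD on a 3-tip star tree, branch lengths 1, community of 2 tips
  tr <- ape::read.tree(text = "(b1:1,b2:1,b3:1);")
  m <- matrix(c(1L, 1L, 0L), 3, 1, dimnames = list(paste0("b", 1:3), "s1"))
  xs <- OtuExperiment(m, domain = setNames(rep("bacteria", 3),
                                           rownames(m)))
  expect_equal(alphaDiversity(xs, tree = tr)$faith_pd, 2)
})

test_that("Shannon is maximal exactly at the uniform distribution", {
  set.seed(21)
  for (i in 1:20) {
    p <- rgamma(10, 1); p <- p / sum(p)
    counts <- matrix(as.integer(round(p * 1e6)), 10, 1,
                     dimnames = list(paste0("b", 1:10), "s1"))
    x <- OtuExperiment(counts, domain = setNames(rep("bacteria", 10),
                                                 rownames(counts)))
    expect_lte(alphaDiversity(x)$shannon, log(10) + 1e-9)
  }
})
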