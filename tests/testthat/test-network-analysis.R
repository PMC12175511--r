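domains6 <- c(b1 = "bacteria", b2 = "bacteria", b3 = "bacteria",
              f1 = "fungi", f2 = "fungi", f3 = "fungi")

test_that("cross-domain edge extraction removes within-domain edges", {
  g <- tinyGraph(rbind(c("b1", "b2"), c("b1", "f1"), c("f1", "f2")),
                 domains6)
  bf <- extractBfEdges(g)
  expect_equal(igraph::ecount(bf), 1)
  el <- igraph::as_edgelist(bf)
  expect_setequal(as.vector(el), c("b1", "f1"))
  expect_equal(igraph::vcount(bf), igraph::vcount(g))  # nodes retained
  expect_true(igraph::V(bf)$isolated[match("f2", igraph::V(bf)$name)])

  allb <- tinyGraph(rbind(c("b1", "b2"), c("b2", "b3")), domains6)
  expect_equal(igraph::ecount(extractBfEdges(allb)), 0)
})

test_that("extraction fraction equals a brute-force count on random graphs", {
  set.seed(2)
  for (i in 1:5) {
    n <- 30
    ids <- sprintf("n%02d", 1:n)
    dom <- setNames(sample(c("bacteria", "fungi"), n, replace = TRUE,
                           prob = c(0.7, 0.3)), ids)
    g <- igraph::sample_gnm(n, 60)
    igraph::V(g)$name <- ids
    igraph::V(g)$domain <- unname(dom)
    el <- igraph::as_edgelist(g)
    brute <- sum(dom[el[, 1]] != dom[el[, 2]])
    expect_equal(igraph::ecount(extractBfEdges(g)), brute)
  }
})

test_that("network statistics follow the density identities", {
  tri <- tinyGraph(rbind(c("b1", "b2"), c("b2", "f1"), c("b1", "f1")),
                   domains6[c("b1", "b2", "f1")])
  s <- networkStats(tri)
  expect_equal(s$linkage_density, 2)
  expect_equal(s$edge_density, 100)
  expect_equal(s$n_nodes, s$n_bacteria + s$n_fungi)
  expect_equal(s$max_degree, 2)

  # a graph of published scale: N = 1950 (1527 B + 423 F), E = 10651
  set.seed(8)
  big <- igraph::sample_gnm(1950, 10651)
  igraph::V(big)$name <- sprintf("o%04d", 1:1950)
  igraph::V(big)$domain <- rep(c("bacteria", "fungi"), c(1527, 423))
  sb <- networkStats(big, modules = FALSE)
  expect_equal(round(sb$linkage_density, 1), 10.9)
  expect_equal(round(sb$edge_density, 2), 0.56)
  expect_equal(sb$n_nodes, 1950)
  expect_error(networkStats(igraph::make_empty_graph(0)), "empty")
})

test_that("module detection resolves planted structure", {
  # two 8-cliques joined by one edge -> 2 modules
  cl <- igraph::make_full_graph(8)
  two <- igraph::disjoint_union(cl, cl)
  two <- igraph::add_edges(two, c(1, 9))
  igraph::V(two)$name <- paste0("n", 1:16)
  igraph::V(two)$domain <- "bacteria"
  expect_equal(detectModules(two)$n_modules, 2)

  full <- igraph::make_full_graph(10)
  igraph::V(full)$name <- paste0("n", 1:10)
  igraph::V(full)$domain <- "bacteria"
  expect_equal(detectModules(full)$n_modules, 1)

  # planted partition: 2 blocks of 30, p_in 0.5, p_out 0.01
  set.seed(17)
  pp <- igraph::sample_sbm(60, matrix(c(0.5, 0.01, 0.01, 0.5), 2),
                           c(30, 30))
  igraph::V(pp)$name <- paste0("n", 1:60)
  igraph::V(pp)$domain <- "bacteria"
  memb <- detectModules(pp)$membership
  truth <- setNames(rep(1:2, each = 30), paste0("n", 1:60))
  cmp <- compareModules(memb, truth)
  expect_gte(cmp$score, 0.9)
})

test_that("module comparison scores identical, nested and disjoint cases", {
  p1 <- setNames(c(1, 1, 2, 2, 3), paste0("n", 1:5))
  expect_equal(compareModules(p1, p1)$score, 1)

  singletons <- setNames(1:6, paste0("n", 1:6))
  oneblock <- setNames(rep(1, 6), paste0("n", 1:6))
  expect_equal(compareModules(singletons, oneblock)$score, 1 / 6)

  pa <- setNames(c(1, 2), c("a", "b"))
  pb <- setNames(c(1, 2), c("c", "d"))
  expect_warning(r <- compareModules(pa, pb), "no nodes|share no")
  expect_equal(r$score, 0)
  expect_true(r$disjoint)
})

test_that("degree-preserving nulls conserve the degree multiset", {
  path <- tinyGraph(rbind(c("b1", "b2"), c("b2", "f1")),
                    domains6[c("b1", "b2", "f1")])
  reps <- randomNetworks(path, 20, "rewire", seed = 3)
  for (r in reps) {
    expect_equal(sort(igraph::degree(r)), sort(igraph::degree(path)))
    expect_false(igraph::any_loop(r))
    expect_false(igraph::any_multiple(r))
  }
  expect_error(randomNetworks(tinyGraph(rbind(c("b1", "f1")),
                                        domains6[c("b1", "f1")]),
                              5, "rewire"), "2 edges")
})

test_that("ER nulls keep node set and edge count and sample uniformly", {
  set.seed(4)
  g <- igraph::sample_gnm(10, 15)
  igraph::V(g)$name <- paste0("n", 1:10)
  igraph::V(g)$domain <- rep(c("bacteria", "fungi"), 5)
  reps <- randomNetworks(g, 30, "er", seed = 1)
  for (r in reps[1:5]) {
    expect_equal(igraph::vcount(r), 10)
    expect_equal(igraph::ecount(r), 15)
    expect_false(igraph::any_loop(r))
    expect_setequal(igraph::V(r)$name, igraph::V(g)$name)
  }

  # edge-inclusion frequencies uniform on a 4-node graph within 3 sigma
  g4 <- igraph::sample_gnm(4, 3)
  igraph::V(g4)$name <- paste0("n", 1:4)
  igraph::V(g4)$domain <- "bacteria"
  draws <- randomNetworks(g4, 999, "er", seed = 7)
  keys <- unlist(lapply(draws, micAssembly:::.edgeKeys))
  tab <- table(keys)
  p_edge <- 3 / 6
  sigma <- sqrt(999 * p_edge * (1 - p_edge))
  expect_equal(length(tab), 6)  # all pairs realized
  expect_true(all(abs(tab - 999 * p_edge) <= 3 * sigma))
})

test_that("shared associations equal the brute-force intersection", {
  dm <- c(f1 = "fungi", f2 = "fungi", b1 = "bacteria", b2 = "bacteria",
          b3 = "bacteria")
  n1 <- tinyGraph(rbind(c("f1", "b1"), c("f2", "b2")), dm)
  n2 <- tinyGraph(rbind(c("f1", "b1"), c("f2", "b3")), dm)
  sh <- sharedAssociations(list(A = n1, B = n2))
  expect_equal(nrow(sh), 1)
  expect_setequal(unlist(sh), c("b1", "f1"))
  expect_equal(nrow(sharedAssociations(list(A = n1, B = n1))), 2)

  set.seed(11)
  sim <- simulateNetworks(locations = c("A", "B", "C"),
                          nodes_per_location = 40,
                          edges_per_location = 80, seed = 3)
  keys <- lapply(sim$networks, micAssembly:::.edgeKeys)
  brute <- length(Reduce(intersect, keys))
  expect_equal(nrow(sharedAssociations(sim$networks)), brute)
})

test_that("empirical p follows the +1 permutation formula", {
  expect_equal(micAssembly:::.empiricalP(5, c(rep(5, 499), rep(0, 500))),
               0.5)
  expect_equal(micAssembly:::.empiricalP(10, rep(0, 999)), 1 / 1000)
  expect_equal(micAssembly:::.empiricalP(0, rep(1, 999)), 1)
  expect_gt(micAssembly:::.empiricalP(100, rep(0, 999)), 0)
})

test_that("shared-edge test detects planted signal and is calm on noise", {
  sim <- simulateNetworks(n_planted_shared = 20, seed = 5)
  st <- sharedEdgeTest(sim$networks, n = 199, seed = 2)
  expect_gte(st$observed_shared, 20)
  expect_lte(st$p_value, 0.005)

  sim0 <- simulateNetworks(n_planted_shared = 0, seed = 6)
  st0 <- sharedEdgeTest(sim0$networks, n = 99, seed = 2)
  expect_gte(st0$p_value, 0.5)
  expect_identical(st0$null_model, "rewire")
})

test_that("NCM classes map onto nodes with a conserved contingency", {
  dm <- c(f1 = "fungi", b1 = "bacteria", b2 = "bacteria")
  g <- tinyGraph(rbind(c("f1", "b1"), c("f1", "b2")), dm)
  fit_df <- data.frame(p = seq(0.01, 0.1, length.out = 12),
                       f_obs = rep(0.5, 12))
  fit <- suppressWarnings(ncmFit(fit_df, d = 1e-3, n_samples = 20))
  # overwrite classes deterministically via the otu slot
  fit@otu$taxon_id <- c("f1", "b1", "b2", sprintf("zz%02d", 1:9))
  fit@otu$class <- c("above", "neutral", "above", rep("neutral", 9))
  res <- attachNcmClasses(g, fit)
  expect_equal(unname(res$node_classes[c("f1", "b1", "b2")]),
               c("above", "neutral", "above"))
  expect_equal(res$pair_counts["neutral", "above"], 1)
  expect_equal(res$pair_counts["above", "above"], 1)
  expect_equal(sum(res$pair_counts), igraph::ecount(g))
  # per-domain percentages sum to 100
  for (d in unique(res$domain_percent$domain))
    expect_equal(sum(res$domain_percent$percent[
      res$domain_percent$domain == d]), 100, tolerance = 1e-9)

  # all-neutral: a single cell holds every edge
  fit@otu$class <- rep("neutral", 12)
  res2 <- attachNcmClasses(g, fit)
  expect_equal(res2$pair_counts["neutral", "neutral"],
               igraph::ecount(g))

  # unassigned nodes are flagged but conservation holds
  fit@otu <- fit@otu[fit@otu$taxon_id != "b2", ]
  res3 <- attachNcmClasses(g, fit)
  expect_equal(unname(res3$node_classes["b2"]), "unassigned")
  expect_equal(sum(res3$pair_counts), igraph::ecount(g))
})

test_that("naive inference finds planted correlation and little noise", {
  set.seed(23)
  n <- 200
  base <- rlnorm(n, 5, 0.4)
  counts <- rbind(b1 = round(base * 3), b2 = round(base * 5),
                  matrix(rpois(8 * n, 40), 8,
                         dimnames = list(paste0("f", 1:8), NULL)))
  colnames(counts) <- paste0("s", 1:n)
  storage.mode(counts) <- "integer"
  dom <- setNames(c("bacteria", "bacteria", rep("fungi", 8)),
                  rownames(counts))
  x <- OtuExperiment(counts, domain = dom)
  g <- naiveNetworkInference(x, threshold = 0.9)
  keys <- micAssembly:::.edgeKeys(g)
  expect_true("b1\rb2" %in% keys)

  noise <- matrix(rpois(10 * n, 40), 10,
                  dimnames = list(paste0("b", 1:10), paste0("s", 1:n)))
  storage.mode(noise) <- "integer"
  xn <- OtuExperiment(noise, domain = setNames(rep("bacteria", 10),
                                               rownames(noise)))
  gn <- naiveNetworkInference(xn, threshold = 0.9)
  expect_lte(igraph::ecount(gn), 1)
  expect_error(naiveNetworkInference(x, threshold = 1.2), "threshold")

  # round-trips through the edge-list format
  dir <- withr::local_tempdir()
  writeNetwork(g, file.path(dir, "g.tsv"))
  g2 <- readNetwork(file.path(dir, "g.tsv"), dom)
  expect_setequal(micAssembly:::.edgeKeys(g2), keys)
})
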