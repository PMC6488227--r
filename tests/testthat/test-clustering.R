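# modularity and deterministic spectral partitioning

test_that("modularity matches hand arithmetic and the trivial partition", {
  tri2 <- rbind(cliquePairs(c("A", "B", "C")), cliquePairs(c("D", "E", "F")),
                c("C", "D"))
  net <- fullNet(tri2)
  one <- setNames(rep(0L, 6), genes(net))
  expect_equal(networkModularity(net, one), 0)
  split <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L),
                    c("A", "B", "C", "D", "E", "F"))
  expect_equal(networkModularity(net, split), 3 / 7 + 3 / 7 - 2 * (7 / 14)^2)
  expect_error(networkModularity(net, split[1:3]), "cover")
})

test_that("modularity agrees with an independent formula on random graphs", {
  for (seed in 1:5) {
    e <- randomConnectedGraph(9, 0.3, seed = 20 + seed)
    net <- fullNet(e)
    set.seed(seed)
    a <- setNames(sample(0:2, length(genes(net)), replace = TRUE),
                  genes(net))
    expect_equal(networkModularity(net, a),
                 oracleModularity(genes(net), net@edges, a),
                 tolerance = 1e-12)
  }
})

test_that("spectral partition finds planted two-community structure", {
  # two 5-cliques joined by one edge split exactly into the cliques
  e <- rbind(cliquePairs(paste0("A", 1:5)), cliquePairs(paste0("B", 1:5)),
             c("A1", "B1"))
  cl <- spectralPartition(fullNet(e))
  expect_equal(nModules(cl), 2L)
  a <- moduleAssignment(cl)
  expect_equal(length(unique(a[paste0("A", 1:5)])), 1L)
  expect_equal(length(unique(a[paste0("B", 1:5)])), 1L)

  # the two-triangle bridge graph yields the triangle partition, Q = 5/14
  tri2 <- rbind(cliquePairs(c("A", "B", "C")),
                cliquePairs(c("D", "E", "F")), c("C", "D"))
  cl2 <- spectralPartition(fullNet(tri2), minModuleSize = 3)
  expect_equal(nModules(cl2), 2L)
  expect_equal(modularityValue(cl2), 5 / 14, tolerance = 1e-12)

  # K6 is indivisible
  cl3 <- spectralPartition(fullNet(cliquePairs(paste0("K", 1:6))))
  expect_equal(nModules(cl3), 1L)
  expect_equal(modularityValue(cl3), 0)
})

test_that("reported modularity equals an independent recomputation", {
  for (seed in 1:4) {
    e <- randomConnectedGraph(10, 0.25, seed = 30 + seed)
    net <- fullNet(e)
    cl <- spectralPartition(net, minModuleSize = 1)
    expect_equal(modularityValue(cl),
                 oracleModularity(genes(net), net@edges,
                                  moduleAssignment(cl)),
                 tolerance = 1e-12)
  }
})

test_that("partitioning is deterministic under node/edge permutation", {
  e <- randomConnectedGraph(14, 0.25, seed = 9)
  net <- fullNet(e)
  cl1 <- spectralPartition(net)
  set.seed(1)
  net2 <- fullNet(e[sample(nrow(e)), 2:1])
  cl2 <- spectralPartition(net2)
  expect_identical(moduleAssignment(cl1)[sort(genes(net))],
                   moduleAssignment(cl2)[sort(genes(net))])
  expect_identical(spectralPartition(net)@assignment, cl1@assignment)
})

test_that("module labels decrease in size with lexicographic tie-break", {
  e <- rbind(cliquePairs(paste0("Z", 1:4)), cliquePairs(paste0("A", 1:3)),
             cliquePairs(paste0("M", 1:3)))
  cl <- spectralPartition(fullNet(e))
  a <- moduleAssignment(cl)
  expect_equal(unname(a["Z1"]), 0L)          # largest module first
  expect_equal(unname(a["A1"]), 1L)          # size tie: A before M
  expect_equal(unname(a["M1"]), 2L)
})

test_that("planted-partition blocks are recovered (ARI >= 0.9)", {
  cfg <- syntheticConfig(rng_seed = 1, n_blocks = 8, block_size = 15,
                         p_within = 0.6, p_between = 0.02,
                         n_seeds = 120, n_absent_seeds = 0)
  sim <- simulateInteractome(cfg)
  cl <- spectralPartition(sim$interactome)
  ari <- mclust::adjustedRandIndex(
    moduleAssignment(cl)[names(sim$blocks)], sim$blocks)
  expect_gte(ari, 0.9)
  expect_equal(nModules(cl), 8L)
})

test_that("cluster tables are consistent tabulations", {
  e <- rbind(cliquePairs(paste0("A", 1:5)), cliquePairs(paste0("B", 1:5)),
             c("A1", "B1"))
  net <- fullNet(e)
  cl <- spectralPartition(net)
  tab <- clusterTable(net, cl)
  expect_equal(tab$size, c(5L, 5L))
  expect_equal(sum(tab$size), nodeCount(net))
  expect_equal(sum(tab$n_seeds), length(seedGenes(net)))

  # a singleton component is its own module row
  ia <- new("Interactome", nodes = c("A", "B", "C"),
            edges = cbind("A", "B"),
            sourceCounts = c(kept = 1L, duplicate = 0L, self_loop = 0L,
                             malformed = 0L))
  net1 <- buildSeedNetwork(ia, mapSeeds(ia, c("A", "C")))
  cl1 <- spectralPartition(net1)
  tab1 <- clusterTable(net1, cl1)
  expect_equal(sort(tab1$size), c(1L, 2L))
})

test_that("edgeless networks get singleton modules and NA modularity", {
  ia <- new("Interactome", nodes = c("A", "B"), edges = cbind("A", "B"),
            sourceCounts = c(kept = 1L, duplicate = 0L, self_loop = 0L,
                             malformed = 0L))
  # seed C alone is impossible (must map); take an isolated-seed network
  ia2 <- new("Interactome", nodes = c("A", "B", "C"),
             edges = cbind("A", "B"),
             sourceCounts = c(kept = 1L, duplicate = 0L, self_loop = 0L,
                              malformed = 0L))
  net <- buildSeedNetwork(ia2, mapSeeds(ia2, "C"))
  cl <- spectralPartition(net)
  expect_equal(nModules(cl), 1L)
  expect_true(is.na(modularityValue(cl)))
  expect_error(networkModularity(net, moduleAssignment(cl)), "edgeless")
})
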