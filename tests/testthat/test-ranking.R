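# hypergeometric enrichment, spanning score, ranking, hallmark, FDR

# the 12-gene fixture: two 4-cliques bridged at G4-G5 plus a 4-cycle
# (G9..G12); seeding G1 and G5 yields the 8-node network G1..G8
fixtureTrio <- function() {
  ia <- exampleInteractome()
  net <- buildSeedNetwork(ia, mapSeeds(ia, c("G1", "G5")))
  cl <- new("ModulePartition",
            assignment = setNames(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
                                  paste0("G", 1:8)),
            nModules = 2L, modularity = networkModularity(
              net, setNames(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
                            paste0("G", 1:8))))
  list(ia = ia, net = net, cl = cl)
}

test_that("upper-tail hypergeometric matches exact enumeration", {
  expect_equal(hypergeomUpperTail(10, 4, 5, 0), 1)
  expect_equal(hypergeomUpperTail(10, 4, 5, 3), 66 / 252,
               tolerance = 1e-12)
  expect_error(hypergeomUpperTail(10, 11, 5, 3), "invalid")
  expect_error(hypergeomUpperTail(10, 4, 5, 5), "invalid")
  # spot grid vs the enumeration oracle
  for (N in c(5, 12, 20)) for (K in c(0, 2, N %/% 2, N))
    for (n in c(1, N %/% 3 + 1, N)) for (k in 0:min(K, n))
      expect_equal(hypergeomUpperTail(N, K, n, k),
                   enumHypergeomTail(N, K, n, k), tolerance = 1e-12)
  # pmf normalization at a few sizes
  for (N in c(8, 15)) {
    K <- 5; n <- 6
    pmf <- vapply(0:min(K, n), function(k)
      choose(K, k) * choose(N - K, n - k) / choose(N, n), 0)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("p is non-increasing in the overlap k", {
  p <- vapply(0:5, function(k) hypergeomUpperTail(30, 10, 5, k), 0)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("enrichment profiles use the documented N, K, n, k", {
  fx <- fixtureTrio()
  prof <- mirnaEnrichmentProfile(c("G1", "G2", "G5", "G6", "G9"),
                                 fx$ia, fx$net, fx$cl)
  expect_equal(prof$network[c("N", "K", "n", "k")],
               list(N = 12, K = 5, n = 8, k = 4))
  expect_equal(prof$network$p, 210 / 495, tolerance = 1e-12)
  expect_equal(prof$clusters$k, c(2L, 2L))
  expect_equal(prof$clusters$p[1], 285 / 495, tolerance = 1e-12)

  # no targets in the interactome: valid, p = 1 everywhere
  prof0 <- mirnaEnrichmentProfile(c("ZZZ1", "ZZZ2"), fx$ia, fx$net, fx$cl)
  expect_equal(prof0$network$K, 0)
  expect_equal(prof0$network$p, 1)
  expect_true(all(prof0$clusters$p == 1))
})

test_that("per-module overlaps add up to the network overlap", {
  cfg <- syntheticConfig(rng_seed = 3, n_seeds = 30, n_absent_seeds = 0)
  sim <- simulateInteractome(cfg)
  st <- simulateSeedsAndTargets(cfg, sim)
  net <- buildSeedNetwork(sim$interactome,
                          mapSeeds(sim$interactome, st$seeds))
  cl <- spectralPartition(net)
  for (i in c(1, 25, 77, 153)) {
    prof <- mirnaEnrichmentProfile(st$families@targets[[i]],
                                   sim$interactome, net, cl)
    expect_equal(sum(prof$clusters$k), prof$network$k)
  }
})

test_that("spanning scores combine breadth and network enrichment", {
  mk <- function(pnet, ps, ks = rep(1, length(ps)))
    list(network = list(N = 100, K = 10, n = 20, k = 5, p = pnet),
         clusters = data.frame(module = seq_along(ps) - 1,
                               size = rep(5, length(ps)), k = ks, p = ps))
  s0 <- spanningScore(mk(1, c(1, 1, 1), ks = c(0, 0, 0)))
  expect_equal(s0$B, 0)
  expect_equal(s0$spanning_score, 0)
  s1 <- spanningScore(mk(0.01, c(0.01, 0.2, 0.03)))
  expect_equal(s1$B, 2)
  expect_equal(s1$spanning_score, 2.99)
  expect_equal(s1$clusters_with_targets, 3)
  # presence-based breadth counts occupied modules instead
  s2 <- spanningScore(mk(0.01, c(0.01, 0.2, 0.03), ks = c(2, 1, 0)),
                      breadth = "presence")
  expect_equal(s2$spanning_score, 2 + 0.99)
  expect_equal(s2$B, 2)   # significant-module count still reported
})

test_that("ranking sorts by score with the documented tie-breaks", {
  df <- data.frame(family_id = c("f1", "f2", "f3"),
                   spanning_score = c(0, 2.99, 1.5),
                   p_net = c(1, 0.01, 0.1), network_k = c(0, 5, 3))
  r <- rankFamilies(df)
  expect_equal(r$family_id, c("f2", "f3", "f1"))
  expect_equal(r$rank, 1:3)

  tie <- data.frame(family_id = c("fa", "fb"),
                    spanning_score = c(2, 2), p_net = c(0.05, 0.05),
                    network_k = c(4, 10))
  expect_equal(rankFamilies(tie)$family_id, c("fb", "fa"))

  # permutation invariance on a full synthetic ranking
  cfg <- syntheticConfig(rng_seed = 8, n_seeds = 30, n_absent_seeds = 0)
  sim <- simulateInteractome(cfg)
  st <- simulateSeedsAndTargets(cfg, sim)
  net <- buildSeedNetwork(sim$interactome,
                          mapSeeds(sim$interactome, st$seeds))
  cl <- spectralPartition(net)
  rk <- spanningScores(st$families, sim$interactome, net, cl)
  set.seed(4)
  perm <- sample(length(st$families))
  fams2 <- new("MirnaFamilySet",
               familyId = st$families@familyId[perm],
               seedSequence = st$families@seedSequence[perm],
               members = st$families@members[perm],
               targets = st$families@targets[perm])
  rk2 <- spanningScores(fams2, sim$interactome, net, cl)
  expect_equal(rk2$family_id, rk$family_id)
  expect_equal(rk2$spanning_score, rk$spanning_score)
})

test_that("a broad regulator outranks a narrow one when the network is a
           minority of the interactome", {
  # 16 mapped seeds over 8 x 40 genes: the seed network covers about half
  # the universe, so module-level enrichment can discriminate breadth
  wins <- 0L
  for (seed in 1:10) {
    cfg <- syntheticConfig(rng_seed = seed, n_seeds = 16,
                           n_absent_seeds = 0)
    sim <- simulateInteractome(cfg)
    st <- simulateSeedsAndTargets(cfg, sim)
    net <- buildSeedNetwork(sim$interactome,
                            mapSeeds(sim$interactome, st$seeds))
    cl <- spectralPartition(net)
    rk <- spanningScores(st$families, sim$interactome, net, cl)
    rb <- rk$rank[rk$family_id == st$broad_id]
    rn <- rk$rank[rk$family_id == st$narrow_id]
    expect_lt(rb, rn)          # narrow never outranks broad
    if (rb == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("hallmark enrichment orders sets and applies BH-FDR", {
  uni <- paste0("U", 1:20)
  query <- paste0("U", 1:10)
  coll <- new("GeneSetCollection",
              setName = c("EXACT", "DISJOINT", "HALF"),
              description = rep("d", 3),
              genes = list(paste0("U", 1:10), paste0("X", 1:5),
                           paste0("U", 8:11)))
  tab <- hallmarkEnrichment(query, coll, uni)
  expect_equal(tab$set_name[1], "EXACT")       # maximal overlap first
  expect_equal(tab$p_value[1], 1 / choose(20, 10), tolerance = 1e-12)
  expect_false("DISJOINT" %in% tab$set_name)   # nothing in the universe
  expect_true(all(tab$fdr >= tab$p_value - 1e-15))
  expect_equal(tab$neg_log10_p, -log10(tab$p_value))

  # genes outside the universe are dropped and counted
  tab2 <- hallmarkEnrichment(c(query, "NOTINUNI"), coll, uni)
  expect_equal(attr(tab2, "dropped"), 1L)
  expect_error(hallmarkEnrichment(query, coll, character()), "universe")
})

test_that("BH adjustment reproduces the step-up closed form", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order preserved, monotone after sorting
  p <- c(0.2, 0.01, 0.9, 0.04)
  adj <- bhFdr(p)
  expect_equal(order(adj), order(p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bhFdr(c(0.5, 0)), "0, 1")
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})
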