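# readers, validation and seed-family grouping

test_that("edge-list loading deduplicates, drops self-loops, normalizes case", {
  f <- tempfile()
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  ia <- loadInteractome(f)
  expect_setequal(genes(ia), c("A", "B"))
  expect_equal(edgeCount(ia), 1L)
  sc <- sourceCounts(ia)
  expect_equal(unname(sc[c("kept", "duplicate", "self_loop")]),
               c(1L, 1L, 1L))

  writeLines(c("a\tb", "b\tc"), f)
  ia2 <- loadInteractome(f)
  expect_setequal(genes(ia2), c("A", "B", "C"))
  expect_equal(ia2@edges, cbind(c("A", "B"), c("B", "C")))
})

test_that("a mixed 20-line file parses to the hand-built graph", {
  # 18 good lines forming a known adjacency, 2 malformed
  good <- cbind(paste0("N", 1:18), paste0("N", c(2:18, 1)))
  lines <- c(paste(good[, 1], good[, 2], sep = "\t"))
  lines <- append(lines, c("ONLYONEFIELD", "BAD GENE\tX"), after = 7)
  f <- tempfile(); writeLines(lines, f)
  ia <- loadInteractome(f)
  sc <- sourceCounts(ia)
  expect_equal(unname(sc["kept"]), 18L)
  expect_equal(unname(sc["malformed"]), 2L)
  expect_equal(nodeCount(ia), 18L)
  # ring adjacency: every node has degree 2
  deg <- table(as.vector(ia@edges))
  expect_true(all(deg == 2))
})

test_that("SIF format, comments and fatal validation paths work", {
  f <- tempfile()
  writeLines(c("# a comment", "A\tpp\tB\tC", "B\tpp\tC", "D\tpp"), f)
  ia <- loadInteractome(f, format = "sif")
  expect_setequal(genes(ia), c("A", "B", "C"))
  expect_equal(edgeCount(ia), 3L)   # A-B, A-C, B-C
  expect_equal(unname(sourceCounts(ia)["malformed"]), 1L)

  writeLines(c("A\tA", "B\tB"), f)
  expect_error(loadInteractome(f), "no valid edges")
  expect_error(loadInteractome(tempfile()), "cannot read")
})

test_that("interactome round-trips through write + reload unchanged", {
  ia <- exampleInteractome()
  f <- tempfile()
  writeInteractome(ia, f)
  ia2 <- loadInteractome(f)
  expect_identical(genes(ia2), genes(ia))
  expect_identical(ia2@edges, ia@edges)
})

test_that("loading is invariant to input line order", {
  pairs <- cliquePairs(paste0("G", 1:6))
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(paste(pairs[, 1], pairs[, 2], sep = "\t"), f1)
  set.seed(42)
  sh <- pairs[sample(nrow(pairs)), 2:1]   # also swap endpoint order
  writeLines(paste(sh[, 1], sh[, 2], sep = "\t"), f2)
  a <- loadInteractome(f1); b <- loadInteractome(f2)
  expect_identical(a@nodes, b@nodes)
  expect_identical(a@edges, b@edges)
})

test_that("simple-dialect target tables aggregate and deduplicate", {
  f <- tempfile()
  writeLines(c("miR-X\tg1", "miR-X\tg1", "miR-X\tg2"), f)
  fam <- loadMirnaTargets(f, dialect = "simple")
  expect_equal(length(fam), 1L)
  expect_equal(familyTargets(fam, "miR-X"), c("G1", "G2"))
})

test_that("targetscan7 dialect filters by species and checks columns", {
  f <- tempfile()
  writeLines(c(
    "miR Family\tGene ID\tGene Symbol\tSpecies ID",
    "miR-1\tid1\tFOXO1\t9606",
    "miR-1\tid2\tFoxo3\t10090",
    "miR-1\tid3\tPTEN\t9606",
    "miR-7\tid4\tEGFR\t9606"), f)
  fam <- loadMirnaTargets(f, dialect = "targetscan7")
  expect_equal(familyIds(fam), c("miR-1", "miR-7"))
  expect_equal(familyTargets(fam, "miR-1"), c("FOXO1", "PTEN"))
  writeLines("Gene Symbol\tSpecies ID\nx\t9606", f)
  expect_error(loadMirnaTargets(f, dialect = "targetscan7"),
               "missing required column")
})

test_that("a 30-row, 3-family table matches hand counts and line order", {
  fams <- rep(c("miR-A", "miR-B", "miR-C"), times = c(12, 10, 8))
  genesv <- c(paste0("a", c(1:6, 1:6)),          # miR-A: 6 unique, each twice
              paste0("b", 1:10),                 # miR-B: 10 unique
              paste0("c", c(1, 1, 1, 1, 2:5)))   # miR-C: 5 unique
  lines <- paste(fams, genesv, sep = "\t")
  f1 <- tempfile(); writeLines(lines, f1)
  fam <- loadMirnaTargets(f1, dialect = "simple")
  expect_equal(lengths(fam@targets), c(6L, 10L, 5L))
  set.seed(7)
  f2 <- tempfile(); writeLines(sample(lines), f2)
  expect_identical(loadMirnaTargets(f2, dialect = "simple")@targets,
                   fam@targets)
})

test_that("seed grouping uses mature positions 2-8 and partitions input", {
  # the miR-200b/c/429 functional group shares the mature prefix UAACACUG
  fam <- groupFamiliesBySeed(
    c("hsa-miR-200b-3p", "hsa-miR-200c-3p", "hsa-miR-429"),
    c("UAACACUGCCUGGUAAUGAUGA",
      "UAACACUGUCGGGUAAUGAUGGA",
      "UAACACUGUCUGGUAAACCGUC"))
  expect_equal(length(fam), 1L)
  expect_equal(unname(seedSequences(fam)), "AACACUG")
  expect_equal(familyIds(fam),
               "hsa-miR-200b-3p/hsa-miR-200c-3p/hsa-miR-429")

  # one substitution at seed position 4 separates families
  two <- groupFamiliesBySeed(c("m1", "m2"),
                             c("UAACACUGCC", "UAAGACUGCC"))
  expect_equal(length(two), 2L)

  # 6 miRNAs, 2 shared seeds -> 4 families; every miRNA in exactly one
  nm <- paste0("mir", 1:6)
  sq <- c("UAACACUGAA", "UAACACUGCC",   # share seed AACACUG
          "UGGCAGUGAA", "UGGCAGUGUU",   # share seed GGCAGUG
          "UCCCUGAGAA", "UAGCUUAUCA")
  fam4 <- groupFamiliesBySeed(nm, sq)
  expect_equal(length(fam4), 4L)
  expect_setequal(unlist(fam4@members), nm)
  expect_equal(sum(lengths(fam4@members)), 6L)

  expect_error(groupFamiliesBySeed("x", "UAACACU"), "invalid mature")
  expect_error(groupFamiliesBySeed("x", "TAACACUGCC"), "invalid mature")
})

test_that("GMT parsing dedups genes, skips gene-less lines, rejects dups", {
  f <- tempfile()
  writeLines("S1\tdesc\ta\tb\ta", f)
  coll <- loadGmt(f)
  expect_equal(geneSetGenes(coll, "S1"), c("A", "B"))

  writeLines(character(), f)
  expect_error(loadGmt(f), "no gene sets")

  writeLines(c("S1\td\ta", "S1\td\tb"), f)
  expect_error(loadGmt(f), "duplicate")

  sets <- lapply(1:5, function(i) paste0("g", seq_len(i + 1)))
  writeLines(c(vapply(1:5, function(i)
    paste(c(sprintf("SET%d", i), "d", sets[[i]]), collapse = "\t"), ""),
    "EMPTYSET\tdesc"), f)
  coll5 <- loadGmt(f)
  expect_equal(length(coll5), 5L)
  expect_equal(lengths(coll5@genes), 2:6)
  expect_equal(attr(coll5, "skipped"), 1L)
})
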