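# synthetic_data: planted-partition interactomes, seed lists, planted
# regulator families and assay tables, with a machine-readable truth record

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the dimensions of the motivating study design: an
#' interactome of 8 modules of 40 genes (planted-partition edge
#' probabilities 0.25 within / 0.01 between blocks), 276 requested seed
#' genes (20 of them symbols absent from the interactome), 153 miRNA
#' families of 60 targets each, one planted broad regulator spanning all
#' blocks and one planted narrow regulator confined to as few blocks as
#' its target count allows.
#'
#' @param rng_seed integer seed; every generator output is a pure function
#'   of the configuration, including this seed.
#' @param n_blocks,block_size planted-partition dimensions.
#' @param p_within,p_between edge probabilities inside / between blocks.
#' @param n_seeds number of requested seed symbols (including absent ones).
#' @param n_absent_seeds how many requested seeds are symbols not present
#'   in the interactome.
#' @param seed_block_bias geometric concentration of mapped seeds across
#'   blocks: block \eqn{b} gets sampling weight
#'   \code{seed_block_bias^-(b-1)}; 1 = uniform.
#' @param n_families number of miRNA families (planted + decoys).
#' @param targets_per_family targets per family (equal across families so
#'   broad and narrow regulators are directly comparable).
#' @param broad_family_spread number of blocks the broad regulator's
#'   targets cover (default all blocks).
#' @param narrow_spread requested number of blocks for the narrow
#'   regulator; raised to \code{ceiling(targets_per_family / block_size)}
#'   when infeasible, and the spread actually used is recorded in the
#'   truth table.
#' @param decoy_target_rate fraction of each decoy family's targets drawn
#'   uniformly from the interactome (the remainder is drawn from seed
#'   genes, giving harder nulls when below 1).
#' @param chip_n_per_group,chip_noise_sd,chip_input_fraction ChIP table
#'   design: samples per group, Ct noise SD, input aliquot fraction.
#' @param chip_percent_a,chip_percent_b,chip_percent_igg planted percent
#'   input of the specific antibodies at the promoter in groups A and B,
#'   and of the IgG / control-region background.
#' @param qpcr_n_per_group,qpcr_fold,qpcr_noise_sd,qpcr_dct_base qPCR
#'   design: samples per group, planted fold change of group A over group
#'   B, Ct noise SD, baseline delta-Ct.
#' @return A validated configuration list (class \code{"syntheticConfig"}).
#' @export
syntheticConfig <- function(rng_seed = 1L,
                            n_blocks = 8L, block_size = 40L,
                            p_within = 0.25, p_between = 0.01,
                            n_seeds = 276L, n_absent_seeds = 20L,
                            seed_block_bias = 1,
                            n_families = 153L, targets_per_family = 60L,
                            broad_family_spread = n_blocks,
                            narrow_spread = 1L,
                            decoy_target_rate = 1,
                            chip_n_per_group = 5L, chip_noise_sd = 0.2,
                            chip_input_fraction = 0.1,
                            chip_percent_a = 10, chip_percent_b = 2,
                            chip_percent_igg = 0.2,
                            qpcr_n_per_group = 20L, qpcr_fold = 2,
                            qpcr_noise_sd = 0.2, qpcr_dct_base = 5) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_within, cfg$p_between, cfg$decoy_target_rate)
  if (any(probs < 0) || any(probs > 1))
    .fatal("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_blocks, cfg$block_size, cfg$n_seeds, cfg$n_families,
              cfg$targets_per_family, cfg$chip_n_per_group,
              cfg$qpcr_n_per_group)
  if (any(counts < 1)) .fatal("counts must be positive")
  nGenome <- cfg$n_blocks * cfg$block_size
  if (cfg$targets_per_family > nGenome)
    .fatal("targets_per_family (%d) exceeds genome size (%d)",
           cfg$targets_per_family, nGenome)
  if (cfg$broad_family_spread > cfg$n_blocks)
    .fatal("broad_family_spread exceeds n_blocks")
  if (cfg$n_seeds - cfg$n_absent_seeds < 1 ||
      cfg$n_seeds - cfg$n_absent_seeds > nGenome)
    .fatal("mappable seed count must be in [1, genome size]")
  if (cfg$seed_block_bias < 1) .fatal("seed_block_bias must be >= 1")
  if (cfg$n_families < 2) .fatal("need at least 2 families (broad + narrow)")
  structure(cfg, class = "syntheticConfig")
}

.synGenes <- function(cfg)
  sprintf("SYN%04d", seq_len(cfg$n_blocks * cfg$block_size))

#' Simulate a planted-partition interactome
#'
#' Draws a stochastic block model over \code{n_blocks * block_size}
#' synthetic gene symbols and returns it as an
#' \linkS4class{Interactome} plus the per-gene block truth.  Byte-identical
#' reproducible from \code{cfg$rng_seed}; edges are emitted in canonical
#' sorted order.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param dir optional output directory; when given,
#'   \code{interactome.tsv} (edge list) and \code{truth_blocks.tsv} are
#'   written there.
#' @return A list: \code{interactome}, \code{blocks} (named integer
#'   vector gene -> block), \code{paths}.
#' @export
simulateInteractome <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$rng_seed)
  genes <- .synGenes(cfg)
  n <- length(genes)
  blk <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pEdge <- ifelse(blk[ut[, 1]] == blk[ut[, 2]], cfg$p_within, cfg$p_between)
  sel <- runif(nrow(ut)) < pEdge
  if (!any(sel)) .fatal("parameter combination produced an empty graph")
  e <- .canonEdges(genes[ut[sel, 1]], genes[ut[sel, 2]])
  ia <- new("Interactome", nodes = genes, edges = e,
            sourceCounts = c(kept = nrow(e), duplicate = 0L,
                             self_loop = 0L, malformed = 0L))
  blocks <- setNames(blk, genes)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(interactome = file.path(dir, "interactome.tsv"),
               blocks = file.path(dir, "truth_blocks.tsv"))
    writeInteractome(ia, paths["interactome"])
    .writeTsv(data.frame(gene = genes, block = blk), paths["blocks"])
  }
  list(interactome = ia, blocks = blocks, paths = paths)
}

# even allocation of nTargets over chosen blocks (counts differ by <= 1),
# sampling network-pool genes of each block first
.plantTargets <- function(nTargets, chosenBlocks, poolNet, poolRest) {
  spread <- length(chosenBlocks)
  base <- nTargets %/% spread
  counts <- rep(base, spread) + c(rep(1L, nTargets %% spread),
                                  rep(0L, spread - nTargets %% spread))
  unlist(lapply(seq_len(spread), function(i) {
    b <- chosenBlocks[i]; want <- counts[i]
    pn <- poolNet[[b]]
    take <- sample(pn, min(want, length(pn)))
    short <- want - length(take)
    if (short > 0) {
      pr <- setdiff(poolRest[[b]], take)
      if (short > length(pr)) .fatal("block %d too small for allocation", b)
      take <- c(take, sample(pr, short))
    }
    take
  }), use.names = FALSE)
}

#' Simulate seed lists and miRNA target tables with planted regulators
#'
#' Samples a block-biased seed list (plus absent symbols), then emits one
#' miRNA family table in the simple dialect: one planted \emph{broad}
#' family whose targets are allocated evenly over
#' \code{broad_family_spread} blocks, one planted \emph{narrow} family of
#' equal size confined to as few blocks as feasible (at least
#' \code{narrow_spread}), and decoy families drawing targets uniformly
#' (at rate \code{decoy_target_rate}; the remainder from seed genes).
#' Planted families draw each block's allocation from that block's
#' seed-network genes first — a regulator of the disease network targets
#' the network — falling back to the block's remaining genes.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param sim result of \code{\link{simulateInteractome}} for the same
#'   configuration.
#' @param dir optional output directory (\code{seeds.txt},
#'   \code{targets.tsv}, \code{truth_families.tsv}).
#' @return A list: \code{seeds} (requested symbols), \code{mapped},
#'   \code{families} (a \linkS4class{MirnaFamilySet}), \code{truth}
#'   (data.frame with family roles and spreads used), \code{broad_id},
#'   \code{narrow_id}, \code{paths}.
#' @export
simulateSeedsAndTargets <- function(cfg, sim, dir = NULL) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$rng_seed + 1L)
  genes <- names(sim$blocks)
  blk <- sim$blocks
  nMapped <- cfg$n_seeds - cfg$n_absent_seeds
  w <- cfg$seed_block_bias^-(blk - 1)
  mapped <- sort(sample(genes, nMapped, prob = w))
  absent <- sprintf("ABSENT%03d", seq_len(cfg$n_absent_seeds))
  requested <- sample(c(mapped, absent))
  net <- buildSeedNetwork(sim$interactome, mapped)
  poolNet <- lapply(seq_len(cfg$n_blocks), function(b)
    intersect(net@nodes, genes[blk == b]))
  poolRest <- lapply(seq_len(cfg$n_blocks), function(b)
    setdiff(genes[blk == b], poolNet[[b]]))
  nT <- cfg$targets_per_family
  minSpread <- ceiling(nT / cfg$block_size)
  broadSpread <- max(cfg$broad_family_spread, minSpread)
  narrowSpread <- max(cfg$narrow_spread, minSpread)
  ids <- sprintf("miR-%03d", seq_len(cfg$n_families))
  planted <- sample(cfg$n_families, 2L)
  broadId <- ids[planted[1]]; narrowId <- ids[planted[2]]
  broadBlocks <- sort(sample(cfg$n_blocks, broadSpread))
  narrowBlocks <- sort(sample(cfg$n_blocks, narrowSpread))
  targets <- vector("list", cfg$n_families)
  for (i in seq_len(cfg$n_families)) {
    targets[[i]] <- if (i == planted[1]) {
      .plantTargets(nT, broadBlocks, poolNet, poolRest)
    } else if (i == planted[2]) {
      .plantTargets(nT, narrowBlocks, poolNet, poolRest)
    } else {
      nUni <- round(cfg$decoy_target_rate * nT)
      fromSeed <- if (nT - nUni > 0) sample(mapped, nT - nUni) else character()
      c(fromSeed, sample(setdiff(genes, fromSeed), nUni))
    }
    targets[[i]] <- sort(unique(targets[[i]]))
  }
  fams <- new("MirnaFamilySet", familyId = ids,
              seedSequence = rep(NA_character_, cfg$n_families),
              members = as.list(ids), targets = targets)
  role <- rep("decoy", cfg$n_families)
  role[planted[1]] <- "broad"; role[planted[2]] <- "narrow"
  spreadUsed <- rep(NA_integer_, cfg$n_families)
  spreadUsed[planted[1]] <- broadSpread
  spreadUsed[planted[2]] <- narrowSpread
  truth <- data.frame(family_id = ids, role = role,
                      spread_used = spreadUsed,
                      n_targets = lengths(targets))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(seeds = file.path(dir, "seeds.txt"),
               targets = file.path(dir, "targets.tsv"),
               families = file.path(dir, "truth_families.tsv"))
    writeLines(requested, paths["seeds"])
    writeLines(c("family_id\tgene_symbol",
                 unlist(lapply(seq_along(ids), function(i)
                   paste(ids[i], targets[[i]], sep = "\t")))),
               paths["targets"])
    .writeTsv(truth, paths["families"])
  }
  list(seeds = requested, mapped = mapped, families = fams, truth = truth,
       broad_id = broadId, narrow_id = narrowId, paths = paths)
}

#' Simulate a GMT gene-set collection from the planted blocks
#'
#' One set per planted block (a random 80\% of its genes) plus two
#' uniform random sets, so hallmark-style enrichment of network genes can
#' be exercised against sets that do and do not align with modules.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param sim result of \code{\link{simulateInteractome}}.
#' @param dir optional output directory (\code{genesets.gmt}).
#' @return A list: \code{collection} (a \linkS4class{GeneSetCollection}),
#'   \code{paths}.
#' @export
simulateGeneSets <- function(cfg, sim, dir = NULL) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$rng_seed + 3L)
  genes <- names(sim$blocks)
  sets <- lapply(seq_len(cfg$n_blocks), function(b) {
    g <- genes[sim$blocks == b]
    sort(sample(g, max(1L, round(0.8 * length(g)))))
  })
  names(sets) <- sprintf("BLOCK_PROCESS_%d", seq_len(cfg$n_blocks))
  rnd <- lapply(1:2, function(i)
    sort(sample(genes, max(2L, round(0.1 * length(genes))))))
  names(rnd) <- sprintf("RANDOM_SET_%d", 1:2)
  sets <- c(sets, rnd)
  coll <- new("GeneSetCollection", setName = names(sets),
              description = sprintf("synthetic gene set (%s)", names(sets)),
              genes = unname(sets))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(gmt = file.path(dir, "genesets.gmt"))
    writeLines(vapply(seq_along(sets), function(i)
      paste(c(names(sets)[i], coll@description[i], sets[[i]]),
            collapse = "\t"), ""), paths["gmt"])
  }
  list(collection = coll, paths = paths)
}

#' Simulate ChIP-qPCR and qRT-PCR Ct tables with planted effects
#'
#' ChIP: two groups (A/B) of \code{chip_n_per_group} samples, antibodies
#' ZEB1 / ZEB2 / IgG at a promoter and a control region.  The specific
#' antibodies at the promoter are planted at \code{chip_percent_a} percent
#' input in group A and \code{chip_percent_b} in group B; IgG rows and the
#' control region sit at the \code{chip_percent_igg} background with no
#' planted group effect.  Ct values are baseline plus the planted log2
#' effect plus Gaussian noise; with \code{chip_noise_sd = 0},
#' \code{\link{percentInput}} recovers the planted levels exactly.
#'
#' qPCR: groups A/B of \code{qpcr_n_per_group} samples with a planted
#' \code{qpcr_fold} expression ratio of A over B.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param dir optional output directory (\code{chip_ct.tsv},
#'   \code{qpcr_ct.tsv}).
#' @return A list: \code{chip}, \code{qpcr} (data.frames),
#'   \code{truth} (planted levels), \code{paths}.
#' @export
simulateAssays <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$rng_seed + 2L)
  grid <- expand.grid(sample = seq_len(cfg$chip_n_per_group),
                      group = c("A", "B"),
                      antibody = c("ZEB1", "ZEB2", "IGG"),
                      region = c("promoter", "control"),
                      stringsAsFactors = FALSE)
  planted <- ifelse(grid$region == "promoter" & grid$antibody != "IGG",
                    ifelse(grid$group == "A", cfg$chip_percent_a,
                           cfg$chip_percent_b),
                    cfg$chip_percent_igg)
  f <- cfg$chip_input_fraction
  ctInput <- 30 + rnorm(nrow(grid), sd = cfg$chip_noise_sd)
  adj <- ctInput - log2(1 / f)
  ctIp <- adj - log2(planted / 100) + rnorm(nrow(grid),
                                            sd = cfg$chip_noise_sd)
  chip <- data.frame(
    sample_id = sprintf("%s%02d", grid$group, grid$sample),
    group = grid$group, antibody = grid$antibody, region = grid$region,
    ct_ip = ctIp, ct_input = ctInput, input_fraction = f)
  nQ <- cfg$qpcr_n_per_group
  qgroup <- rep(c("A", "B"), each = nQ)
  dct <- ifelse(qgroup == "A", cfg$qpcr_dct_base - log2(cfg$qpcr_fold),
                cfg$qpcr_dct_base)
  ctRef <- 20 + rnorm(2 * nQ, sd = cfg$qpcr_noise_sd)
  ctTar <- ctRef + dct + rnorm(2 * nQ, sd = cfg$qpcr_noise_sd)
  qpcr <- data.frame(
    sample_id = sprintf("%s%02d", qgroup, c(seq_len(nQ), seq_len(nQ))),
    group = qgroup, ct_target = ctTar, ct_reference = ctRef)
  truth <- list(chip_percent = c(A = cfg$chip_percent_a,
                                 B = cfg$chip_percent_b,
                                 background = cfg$chip_percent_igg),
                qpcr_fold = cfg$qpcr_fold)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(chip = file.path(dir, "chip_ct.tsv"),
               qpcr = file.path(dir, "qpcr_ct.tsv"))
    .writeTsv(chip, paths["chip"])
    .writeTsv(qpcr, paths["qpcr"])
  }
  list(chip = chip, qpcr = qpcr, truth = truth, paths = paths)
}

# self-audit: reload every emitted file through data_io and check it
# against the in-memory truth
.auditSynthetic <- function(study) {
  p <- study$paths
  ia2 <- loadInteractome(p[["interactome"]])
  stopifnot(identical(ia2@edges, study$interactome@edges))
  stopifnot(identical(loadSeedList(p[["seeds"]]), study$seeds))
  fams2 <- loadMirnaTargets(p[["targets"]], dialect = "simple")
  stopifnot(identical(familyIds(fams2), familyIds(study$families)))
  stopifnot(identical(fams2@targets, study$families@targets))
  coll2 <- loadGmt(p[["gmt"]])
  stopifnot(identical(attr(coll2, "skipped"), 0L),
            identical(coll2@genes, study$geneSets@genes))
  invisible(TRUE)
}

#' Simulate a complete synthetic study
#'
#' Runs \code{\link{simulateInteractome}},
#' \code{\link{simulateSeedsAndTargets}}, \code{\link{simulateGeneSets}}
#' and \code{\link{simulateAssays}} for one configuration.  When
#' \code{dir} is given, all input files, the truth tables and a
#' \code{manifest.txt} holding the full configuration are written there,
#' and a self-audit pass reloads every emitted file through the package's
#' own readers and checks it against the in-memory truth.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param dir optional output directory.
#' @return A list with elements \code{config}, \code{interactome},
#'   \code{blocks}, \code{seeds}, \code{mapped}, \code{families},
#'   \code{familyTruth}, \code{broad_id}, \code{narrow_id},
#'   \code{geneSets}, \code{assays} and \code{paths}.
#' @export
simulateStudy <- function(cfg = syntheticConfig(), dir = NULL) {
  sim <- simulateInteractome(cfg, dir)
  st <- simulateSeedsAndTargets(cfg, sim, dir)
  gs <- simulateGeneSets(cfg, sim, dir)
  as <- simulateAssays(cfg, dir)
  study <- list(config = cfg, interactome = sim$interactome,
                blocks = sim$blocks, seeds = st$seeds, mapped = st$mapped,
                families = st$families, familyTruth = st$truth,
                broad_id = st$broad_id, narrow_id = st$narrow_id,
                geneSets = gs$collection, assays = as,
                paths = c(sim$paths, st$paths, gs$paths, as$paths))
  if (!is.null(dir)) {
    cfgLines <- vapply(names(unclass(cfg)), function(k)
      paste0(k, "=", format(cfg[[k]], scientific = FALSE)), "")
    writeLines(c("# mirSpan synthetic study manifest", cfgLines),
               file.path(dir, "manifest.txt"))
    study$paths <- c(study$paths,
                     manifest = file.path(dir, "manifest.txt"))
    .auditSynthetic(study)
  }
  study
}
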