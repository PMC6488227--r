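# data_io: readers for the three external table formats and seed-family
# grouping of mature miRNAs

.readLinesChecked <- function(path) {
  if (!file.exists(path)) .fatal("cannot read file: %s", path)
  readLines(path, warn = FALSE)
}

#' Load an interactome from an edge list or SIF file
#'
#' Parses a tab-separated gene association file into an undirected,
#' deduplicated \linkS4class{Interactome}.  Symbols are uppercased; edge
#' direction and any columns beyond the node columns are ignored; lines
#' starting with \code{#} and blank lines are skipped.  The returned
#' object's \code{sourceCounts()} records how many data lines were kept and
#' how many were dropped as duplicates, self-loops or malformed.
#'
#' @param path path to the input file.
#' @param format \code{"edge_list"} (two or more tab-separated columns,
#'   first two used) or \code{"sif"} (node, relation, node(s); one edge per
#'   target node).
#' @return An \linkS4class{Interactome}.
#'
#' @details A line is malformed when it has too few fields or a field that
#' is empty or contains internal whitespace.  A file from which no edge
#' survives is an error: an interactome with zero associations cannot serve
#' as an enrichment universe.
#'
#' @examples
#' f <- tempfile()
#' writeLines(c("TP53\tMDM2", "mdm2\ttp53", "TP53\tTP53", "EGFR\tGRB2"), f)
#' ia <- loadInteractome(f)
#' sourceCounts(ia)
#' @export
loadInteractome <- function(path, format = c("edge_list", "sif")) {
  format <- match.arg(format)
  lines <- .readLinesChecked(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  counts <- c(kept = 0L, duplicate = 0L, self_loop = 0L, malformed = 0L)
  from <- character(); to <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    pairs <- NULL
    if (format == "edge_list") {
      if (length(f) >= 2L) pairs <- cbind(f[1], f[2])
    } else {
      if (length(f) >= 3L) pairs <- cbind(f[1], f[-(1:2)])
    }
    if (is.null(pairs)) { counts["malformed"] <- counts["malformed"] + 1L; next }
    a <- .normGene(pairs[, 1]); b <- .normGene(pairs[, 2])
    if (!all(.validGene(a)) || !all(.validGene(b))) {
      counts["malformed"] <- counts["malformed"] + 1L; next
    }
    from <- c(from, a); to <- c(to, b)
  }
  self <- from == to
  counts["self_loop"] <- sum(self)
  from <- from[!self]; to <- to[!self]
  key <- paste(pmin(from, to), pmax(from, to))
  dup <- duplicated(key)
  counts["duplicate"] <- sum(dup)
  counts["kept"] <- sum(!dup)
  if (counts["kept"] == 0L)
    .fatal(paste0("no valid edges in %s (duplicate=%d, self_loop=%d, ",
                  "malformed=%d)"), path, counts["duplicate"],
           counts["self_loop"], counts["malformed"])
  e <- .canonEdges(from[!dup], to[!dup])
  new("Interactome", nodes = sort(unique(as.vector(e))), edges = e,
      sourceCounts = counts)
}

#' Write an interactome back to a tab-separated edge list
#'
#' Edges are written in canonical sorted order, so the output is
#' deterministic and reloads to an identical node and edge set.
#'
#' @param x an \linkS4class{Interactome} or \linkS4class{SeedNetwork}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeInteractome <- function(x, path) {
  stopifnot(is(x, "Interactome") || is(x, "SeedNetwork"))
  writeLines(paste(x@edges[, 1], x@edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Load a seed gene list
#'
#' One symbol per line; \code{#} comments and blank lines are skipped;
#' symbols are uppercased and deduplicated preserving first occurrence.
#'
#' @param path path to the list file.
#' @return Character vector of seed symbols.
#' @export
loadSeedList <- function(path) {
  lines <- trimws(.readLinesChecked(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  s <- .normGene(lines)
  bad <- !.validGene(s)
  if (any(bad)) .fatal("invalid seed symbol(s): %s",
                       paste(head(lines[bad], 5L), collapse = ", "))
  unique(s)
}

#' Load a miRNA-to-target table
#'
#' Aggregates a predicted-target table into one family per distinct family
#' identifier, with targets deduplicated and case-normalized.  Two dialects
#' are understood: \code{"targetscan7"}, a tab-separated file with a header
#' whose columns are matched case-insensitively by the name fragments
#' \code{"miR family"}, \code{"Gene Symbol"} and \code{"Species ID"} (rows
#' are filtered to \code{species} before aggregation); and
#' \code{"simple"}, a headerless two-column file \code{family_id} /
#' \code{gene_symbol} (a literal \code{family_id<TAB>gene_symbol} header
#' line is tolerated and skipped).
#'
#' @param path path to the table.
#' @param dialect \code{"targetscan7"} or \code{"simple"}.
#' @param species species identifier kept by the targetscan7 filter
#'   (default \code{"9606"}, human).
#' @return A \linkS4class{MirnaFamilySet}; seed sequences are \code{NA}
#'   (target tables carry no mature sequence) and each family's member list
#'   holds the family label itself.
#' @export
loadMirnaTargets <- function(path, dialect = c("targetscan7", "simple"),
                             species = "9606") {
  dialect <- match.arg(dialect)
  if (dialect == "targetscan7") {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      colClasses = "character")
    want <- c(`miR family` = "mir family", `Gene Symbol` = "gene symbol",
              `Species ID` = "species id")
    hit <- vapply(want, function(w) {
      i <- grep(w, tolower(names(tab)), fixed = TRUE)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    if (any(is.na(hit)))
      .fatal("missing required column(s): %s (have: %s)",
             paste(names(want)[is.na(hit)], collapse = ", "),
             paste(names(tab), collapse = ", "))
    fam <- tab[[hit[1]]]; sym <- tab[[hit[2]]]; sp <- tab[[hit[3]]]
    keep <- trimws(sp) == as.character(species)
    fam <- fam[keep]; sym <- sym[keep]
  } else {
    lines <- .readLinesChecked(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && identical(tolower(trimws(lines[1])),
                                   "family_id\tgene_symbol"))
      lines <- lines[-1]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 2L))
      .fatal("simple dialect requires 2 tab-separated columns on every line")
    fam <- vapply(f, `[`, "", 1L)
    sym <- vapply(f, `[`, "", 2L)
  }
  fam <- trimws(fam); sym <- .normGene(sym)
  ok <- nzchar(fam) & .validGene(sym)
  fam <- fam[ok]; sym <- sym[ok]
  if (!length(fam)) .fatal("no usable miRNA target rows in %s", path)
  ids <- sort(unique(fam))
  tg <- lapply(ids, function(id) sort(unique(sym[fam == id])))
  new("MirnaFamilySet", familyId = ids,
      seedSequence = rep(NA_character_, length(ids)),
      members = as.list(ids), targets = tg)
}

#' Group mature miRNAs into seed-sequence families
#'
#' The seed region is defined as mature positions 2-8 (a 7-mer, the
#' standard convention for target prediction); miRNAs with identical seeds
#' form one family, whose identifier is the sorted member names joined with
#' \code{"/"}.  Every input miRNA lands in exactly one family.
#'
#' @param names character vector of mature miRNA names.
#' @param sequences character vector of mature sequences (RNA over
#'   A/C/G/U, length >= 8; T is not accepted).
#' @return A \linkS4class{MirnaFamilySet} with empty target sets.
#'
#' @examples
#' fam <- groupFamiliesBySeed(
#'   c("hsa-miR-200b-3p", "hsa-miR-200c-3p", "hsa-miR-429"),
#'   c("UAACACUGCCUGGUAAUGAUGA",
#'     "UAACACUGUCGGGUAAUGAUGGA",
#'     "UAACACUGUCUGGUAAACCGUC"))
#' seedSequences(fam)  # one family, seed AACACUG
#' @export
groupFamiliesBySeed <- function(names, sequences) {
  if (length(names) != length(sequences))
    .fatal("names and sequences must have the same length")
  sequences <- toupper(trimws(sequences))
  bad <- nchar(sequences) < 8L | !grepl("^[ACGU]+$", sequences)
  if (any(bad))
    .fatal("invalid mature sequence for: %s",
           paste(names[bad], collapse = ", "))
  seed <- substr(sequences, 2L, 8L)
  ids <- vapply(split(names, seed),
                function(m) paste(sort(m), collapse = "/"), "")
  ord <- order(ids)
  new("MirnaFamilySet",
      familyId = unname(ids[ord]),
      seedSequence = names(ids)[ord],
      members = lapply(split(names, seed)[ord], sort),
      targets = rep(list(character()), length(ids)))
}

#' Load a GMT gene-set collection
#'
#' Standard GMT: each line is set name, description, then one or more gene
#' symbols, tab-separated.  Symbols are uppercased and deduplicated per
#' set.  Lines with no genes are skipped (counted in the
#' \code{"skipped"} attribute of the result); duplicate set names and an
#' empty collection are fatal.
#'
#' @param path path to the GMT file.
#' @return A \linkS4class{GeneSetCollection} with attribute
#'   \code{"skipped"} giving the number of gene-less lines dropped.
#' @export
loadGmt <- function(path) {
  lines <- .readLinesChecked(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  skipped <- sum(lengths(f) < 3L)
  f <- f[lengths(f) >= 3L]
  if (!length(f)) .fatal("no gene sets in %s", path)
  nm <- vapply(f, `[`, "", 1L)
  if (anyDuplicated(nm))
    .fatal("duplicate gene-set name(s): %s",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
  gs <- lapply(f, function(x) sort(unique(.normGene(x[-(1:2)]))))
  out <- new("GeneSetCollection", setName = nm,
             description = vapply(f, `[`, "", 2L), genes = gs)
  attr(out, "skipped") <- skipped
  out
}
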