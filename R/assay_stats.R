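# assay_stats: ChIP-qPCR percent input, comparative Ct, exact
# Mann-Whitney, Pearson correlation

#' ChIP-qPCR percent input
#'
#' The Percent Input Method: the input aliquot's Ct is first adjusted for
#' the fraction of chromatin it represents,
#' \eqn{Ct_{adj} = Ct_{input} - \log_2(1 / f)}, and occupancy is
#' \eqn{100 \times 2^{Ct_{adj} - Ct_{IP}}}.  With the default
#' \code{inputFraction = 0.1} (a 10\% input aliquot) the adjustment
#' subtracts \eqn{\log_2 10 \approx 3.32} cycles.  Amplification
#' efficiency is fixed at 2 per cycle.  The result is invariant to adding
#' a common constant to both Ct values.
#'
#' @param ctIp Ct of the immunoprecipitated sample (vectorized).
#' @param ctInput Ct of the input aliquot.
#' @param inputFraction fraction of chromatin set aside as input, in
#'   (0, 1].
#' @return Percent input (percentage scale: 100 means parity with input).
#'
#' @examples
#' percentInput(28, 30, 0.1)   # exactly 40
#' @export
percentInput <- function(ctIp, ctInput, inputFraction = 0.1) {
  if (any(inputFraction <= 0) || any(inputFraction > 1))
    .fatal("inputFraction must be in (0, 1]")
  if (any(!is.finite(ctIp)) || any(!is.finite(ctInput)) ||
      any(ctIp <= 0) || any(ctInput <= 0))
    .fatal("Ct values must be finite and positive")
  adj <- ctInput - log2(1 / inputFraction)
  100 * 2^(adj - ctIp)
}

#' Per-sample relative expression, 2^-dCt
#'
#' @param ctTarget Ct of the target assay (vectorized).
#' @param ctReference Ct of the endogenous reference assay (e.g. PPIA for
#'   mRNA, U6 snRNA for miRNA).
#' @return \eqn{2^{-(Ct_{target} - Ct_{reference})}}.
#' @export
relativeExpression <- function(ctTarget, ctReference) {
  if (any(!is.finite(ctTarget)) || any(!is.finite(ctReference)) ||
      any(ctTarget <= 0) || any(ctReference <= 0))
    .fatal("Ct values must be finite and positive")
  2^(-(ctTarget - ctReference))
}

#' Comparative Ct (ddCt) fold change between two groups
#'
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_A - \overline{\Delta Ct}_B}
#' and fold = \eqn{2^{-\Delta\Delta Ct}}, so a fold above 1 means higher
#' expression in group A.
#'
#' @param dctA,dctB numeric vectors of per-sample \eqn{\Delta Ct}
#'   (\eqn{Ct_{target} - Ct_{reference}}) for the two groups.
#' @return The fold change \eqn{2^{-\Delta\Delta Ct}}.
#' @examples
#' ddctFold(rep(4, 3), rep(5, 3))   # 2-fold up in group A
#' @export
ddctFold <- function(dctA, dctB) {
  if (!length(dctA) || !length(dctB)) .fatal("both groups must be non-empty")
  2^(-(mean(dctA) - mean(dctB)))
}

#' Exact Mann-Whitney U test
#'
#' \eqn{U} counts pairs with \eqn{x_i > y_j}, plus half the tied pairs.
#' When \eqn{\binom{n_x + n_y}{n_x} \le} \code{maxExact} the two-sided
#' p-value is exact: all relabelings of the pooled data are enumerated and
#' the smaller tail probability is doubled (capped at 1).  Larger designs
#' fall back to the normal approximation with tie correction and
#' continuity correction, flagged by \code{method}.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param maxExact enumeration budget on \eqn{\binom{n_x+n_y}{n_x}}
#'   (default 200000).
#' @return A list: \code{U}, \code{p} (two-sided), \code{method}
#'   (\code{"exact"} or \code{"normal"}), \code{nx}, \code{ny}.
#'
#' @examples
#' mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))   # U = 0, p = 0.1
#' @export
mannWhitneyExact <- function(x, y, maxExact = 200000) {
  if (!length(x) || !length(y)) .fatal("both groups must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    .fatal("values must be finite")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks handle ties
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (choose(nx + ny, nx) <= maxExact) {
    idx <- combn(nx + ny, nx)
    allU <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    tol <- 1e-9
    pLo <- mean(allU <= U + tol)
    pHi <- mean(allU >= U - tol)
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie <- table(pooled)
    nAll <- nx + ny
    sig2 <- nx * ny / 12 *
      (nAll + 1 - sum(tie^3 - tie) / (nAll * (nAll - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method, nx = nx, ny = ny)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around \code{stats::cor}: equal lengths of at
#' least 3 and non-degenerate variance in both vectors are required
#' (correlation is undefined for a constant vector).
#'
#' @param x,y numeric vectors.
#' @return The correlation coefficient, in \eqn{[-1, 1]}.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) .fatal("x and y must have the same length")
  if (length(x) < 3L) .fatal("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) .fatal("zero variance: r is undefined")
  cor(x, y, method = "pearson")
}

#' Read a ChIP-qPCR Ct table
#'
#' Tab-separated with header columns \code{sample_id}, \code{group},
#' \code{antibody}, \code{region}, \code{ct_ip}, \code{ct_input} and
#' optionally \code{input_fraction} (default filled with
#' \code{inputFraction}).
#'
#' @param path path to the table.
#' @param inputFraction default input fraction when the file has no
#'   \code{input_fraction} column.
#' @return A validated data.frame.
#' @export
readChipTable <- function(path, inputFraction = 0.1) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "antibody", "region", "ct_ip", "ct_input")
  if (!all(need %in% names(tab)))
    .fatal("ChIP table must have columns: %s", paste(need, collapse = ", "))
  if (!"input_fraction" %in% names(tab))
    tab$input_fraction <- inputFraction
  if (any(!is.finite(tab$ct_ip)) || any(!is.finite(tab$ct_input)))
    .fatal("non-numeric Ct values in %s", path)
  tab
}

#' Read a qRT-PCR Ct table
#'
#' Tab-separated with header columns \code{sample_id}, \code{group},
#' \code{ct_target}, \code{ct_reference}.
#'
#' @param path path to the table.
#' @return A validated data.frame.
#' @export
readQpcrTable <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(tab)))
    .fatal("qPCR table must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(tab$ct_target)) || any(!is.finite(tab$ct_reference)))
    .fatal("non-numeric Ct values in %s", path)
  tab
}

#' Summarise a ChIP-qPCR table: percent input and group comparisons
#'
#' Adds a \code{percent_input} column, then compares the two groups within
#' every antibody/region stratum with the exact Mann-Whitney test.
#'
#' @param tab a data.frame from \code{\link{readChipTable}}.
#' @return A list: \code{measurements} (the table with percent input) and
#'   \code{tests} (one row per antibody x region with group means, U and
#'   two-sided p).
#' @export
chipSummary <- function(tab) {
  tab$percent_input <- percentInput(tab$ct_ip, tab$ct_input,
                                    tab$input_fraction)
  groups <- sort(unique(tab$group))
  tests <- NULL
  if (length(groups) == 2L) {
    strata <- unique(tab[, c("antibody", "region")])
    tests <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      sub <- tab[tab$antibody == strata$antibody[i] &
                 tab$region == strata$region[i], ]
      a <- sub$percent_input[sub$group == groups[1]]
      b <- sub$percent_input[sub$group == groups[2]]
      if (!length(a) || !length(b)) return(NULL)
      mw <- mannWhitneyExact(a, b)
      data.frame(antibody = strata$antibody[i], region = strata$region[i],
                 group_a = groups[1], group_b = groups[2],
                 mean_a = mean(a), mean_b = mean(b),
                 U = mw$U, p_value = mw$p, method = mw$method)
    }))
  }
  list(measurements = tab, tests = tests)
}

#' Summarise a qRT-PCR table: relative expression and ddCt fold change
#'
#' @param tab a data.frame from \code{\link{readQpcrTable}}.
#' @return A list: \code{measurements} (with \code{dct} and
#'   \code{rel_expr} columns) and \code{tests} (fold change
#'   \eqn{2^{-\Delta\Delta Ct}} of group A over group B plus the exact
#'   Mann-Whitney p on per-sample \eqn{\Delta Ct}); \code{tests} is
#'   \code{NULL} unless exactly two groups are present.
#' @export
qpcrSummary <- function(tab) {
  tab$dct <- tab$ct_target - tab$ct_reference
  tab$rel_expr <- relativeExpression(tab$ct_target, tab$ct_reference)
  groups <- sort(unique(tab$group))
  tests <- NULL
  if (length(groups) == 2L) {
    a <- tab$dct[tab$group == groups[1]]
    b <- tab$dct[tab$group == groups[2]]
    mw <- mannWhitneyExact(a, b)
    tests <- data.frame(group_a = groups[1], group_b = groups[2],
                        fold_a_vs_b = ddctFold(a, b),
                        U = mw$U, p_value = mw$p, method = mw$method)
  }
  list(measurements = tab, tests = tests)
}
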