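# log of the hypergeometric point probability P(X = k) for a 2x2 table
# with margins: K = set size, n = DE size, N = background
logHyperPoint <- function(k, K, n, N) {
  lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
}

logSumExp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= overlap) where X is the overlap between a gene set of size
#' \code{setSize} and a draw of \code{deSize} genes from a background of
#' \code{background} genes; computed by summing point probabilities in
#' log space for numerical stability. This is the one-sided
#' over-representation p-value.
#'
#' @param overlap observed overlap (the table's \code{a} cell).
#' @param setSize genes in the set (\code{a + c}).
#' @param deSize genes in the DE list (\code{a + b}).
#' @param background total genes (\code{a + b + c + d}).
#' @return upper-tail p-value in [0, 1].
#' @examples
#' hypergeomUpper(1, 1, 1, 2) # 0.5
#' @export
hypergeomUpper <- function(overlap, setSize, deSize, background) {
  a <- as.numeric(overlap); K <- as.numeric(setSize)
  n <- as.numeric(deSize); N <- as.numeric(background)
  if (any(c(a, K, n, N) < 0) || K > N || n > N)
    stop("inconsistent margins: need 0 <= setSize, deSize <= background")
  if (a > min(K, n))
    stop("overlap ", a, " exceeds min(setSize, deSize) = ", min(K, n))
  if (a < max(0, K + n - N))
    stop("overlap ", a, " below the minimum ", max(0, K + n - N),
         " forced by the margins")
  kmax <- min(K, n)
  if (a <= max(0, K + n - N)) return(1)
  ks <- seq.int(a, kmax)
  p <- exp(logSumExp(logHyperPoint(ks, K, n, N)))
  min(1, p)
}

#' Fisher exact test on a 2x2 enrichment table
#'
#' For the table (a = DE and in set, b = DE not in set, c = in set not DE,
#' d = neither): the one-sided (greater) p-value is the hypergeometric
#' upper tail on the same margins -- the identity that makes the Fisher
#' test and the hypergeometric over-representation test the same test on a
#' 2x2 table. The two-sided p-value sums the probabilities of all tables
#' with the same margins whose point probability does not exceed that of
#' the observed table (with a small relative tolerance for floating-point
#' ties). The odds ratio is the sample (cross-product) estimate
#' \code{(a*d)/(b*c)}, \code{Inf} when \code{b*c == 0} with
#' \code{a*d > 0}.
#'
#' @param a,b,c,d nonnegative integer cells of the 2x2 table.
#' @return list with \code{odds_ratio}, \code{p_greater},
#'   \code{p_two_sided}.
#' @examples
#' fisherExact2x2(1, 0, 0, 1)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("table cells must be nonnegative integers")
  if (a + b == 0 || a + c == 0)
    stop("degenerate margin: the DE list (a+b) and the gene set (a+c) ",
         "must both be non-empty")
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  pGreater <- hypergeomUpper(a, K, n, N)
  ks <- seq.int(max(0, K + n - N), min(K, n))
  lp <- logHyperPoint(ks, K, n, N)
  lobs <- logHyperPoint(a, K, n, N)
  sel <- lp <= lobs + 1e-7 # relative tolerance on the log scale
  pTwo <- min(1, exp(logSumExp(lp[sel])))
  or <- if (b * c == 0 && a * d == 0) NaN
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  list(odds_ratio = or, p_greater = pGreater, p_two_sided = pTwo)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' adj_(i) = min over j >= i of m * p_(j) / j (values sorted ascending),
#' capped at 1 and returned in the original order. Idempotent and
#' invariant to input reordering.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  ps <- pvalues[o]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Over-representation of a gene set in a DE gene list
#'
#' Builds the 2x2 table by set algebra against the expressed background
#' (the gene set is intersected with the background first, so untested
#' genes cannot inflate the enrichment) and delegates to
#' \code{\link{fisherExact2x2}}.
#'
#' @param deGenes character vector of differentially expressed gene
#'   symbols; must be a subset of \code{background}.
#' @param geneSet character vector of gene symbols in the set (e.g. a
#'   disease gene database; intersected with \code{background}).
#' @param background character vector of all expressed gene symbols.
#' @return list with the table cells (\code{a}, \code{b}, \code{c},
#'   \code{d}), the sizes actually used (\code{set_size_used},
#'   \code{de_size}, \code{background_size}), \code{odds_ratio},
#'   \code{p_greater}, \code{p_two_sided}.
#' @examples
#' enrichGeneLists(c("g1"), c("g1"), c("g1", "g2"))
#' @export
enrichGeneLists <- function(deGenes, geneSet, background) {
  deGenes <- unique(deGenes)
  geneSet <- unique(geneSet)
  background <- unique(background)
  if (!all(deGenes %in% background))
    stop("deGenes must be a subset of the background (",
         sum(!deGenes %in% background), " absent)")
  setUsed <- intersect(geneSet, background)
  a <- length(intersect(deGenes, setUsed))
  b <- length(deGenes) - a
  cc <- length(setUsed) - a
  d <- length(background) - a - b - cc
  ft <- fisherExact2x2(a, b, cc, d)
  c(list(a = a, b = b, c = cc, d = d,
         set_size_used = length(setUsed), de_size = length(deGenes),
         background_size = length(background)), ft)
}

#' Enrichment of many gene sets with FDR adjustment
#'
#' Applies \code{\link{enrichGeneLists}} to each set and BH-adjusts the
#' one-sided p-values across sets.
#'
#' @param deGenes,background as in \code{\link{enrichGeneLists}}.
#' @param geneSets named list of gene-symbol vectors.
#' @return \code{DataFrame} with one row per set: \code{set}, \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{OR}, \code{p_greater},
#'   \code{p_two_sided}, \code{p_BH} (BH over \code{p_greater}).
#' @examples
#' bg <- paste0("g", 1:50)
#' enrichTable(bg[1:10], list(s1 = bg[1:8], s2 = bg[30:40]), bg)
#' @export
enrichTable <- function(deGenes, geneSets, background) {
  stopifnot(length(names(geneSets)) == length(geneSets))
  rows <- lapply(names(geneSets), function(nm) {
    r <- enrichGeneLists(deGenes, geneSets[[nm]], background)
    S4Vectors::DataFrame(set = nm, a = r$a, b = r$b, c = r$c, d = r$d,
                         OR = r$odds_ratio, p_greater = r$p_greater,
                         p_two_sided = r$p_two_sided)
  })
  out <- do.call(rbind, rows)
  out$p_BH <- bhAdjust(out$p_greater)
  out
}
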