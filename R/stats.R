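#' Fisher's exact test for a 2x2 table
#'
#' Exact p-value from the hypergeometric distribution conditional on the
#' table margins. The odds ratio is the sample cross-product ratio
#' `ad/bc` (`Inf` when `bc = 0` with `ad > 0`, flagged via the
#' `degenerate` field), not the conditional MLE.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @param alternative `"greater"`, `"less"` or `"two.sided"` (on the
#'   `[1,1]` cell).
#' @return list with `odds_ratio`, `p`, `alternative`, `degenerate`.
#' @export
fisher_exact <- function(table,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table)) || anyNA(table))
    stop("counts must be non-negative integers", call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b; n2 <- c + d; k <- a + c
  p <- switch(alternative,
    greater = phyper(a - 1, m, n2, k, lower.tail = FALSE),
    less = phyper(a, m, n2, k),
    two.sided = {
      support <- max(0, k - n2):min(k, m)
      dens <- dhyper(support, m, n2, k)
      sum(dens[dens <= dhyper(a, m, n2, k) * (1 + 1e-7)])
    })
  degenerate <- (b * c == 0) || (a * d == 0)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = min(p, 1), alternative = alternative,
       degenerate = degenerate)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe_size, set_size,
#' selection_size)`: the chance of at least the observed overlap when the
#' selection is drawn uniformly from the universe.
#'
#' @param overlap observed overlap count.
#' @param set_size gene-set size within the universe.
#' @param universe_size universe size.
#' @param selection_size selection size within the universe.
#' @return p-value.
#' @export
hypergeom_upper <- function(overlap, set_size, universe_size,
                            selection_size) {
  stopifnot(overlap >= 0, set_size >= 0, selection_size >= 0,
            universe_size >= set_size, universe_size >= selection_size,
            overlap <= min(set_size, selection_size))
  phyper(overlap - 1, set_size, universe_size - set_size, selection_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment over one test family; a thin named wrapper so
#' every module adjusts identically.
#'
#' @param p numeric vector of p-values.
#' @return adjusted q-values in the original order.
#' @export
fdr_adjust <- function(p) p.adjust(p, method = "BH")

#' Chi-square goodness-of-fit without continuity correction
#'
#' @param observed integer counts.
#' @param expected_prop expected proportions (normalized internally).
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_gof <- function(observed, expected_prop) {
  stopifnot(length(observed) == length(expected_prop),
            all(observed >= 0), all(expected_prop > 0))
  expected <- sum(observed) * expected_prop / sum(expected_prop)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}
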