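#' Pearson correlation corrected for temporal autocorrelation
#'
#' Pearson correlation between two annual time series with the
#' significance test adjusted for serial dependence by the effective-
#' degrees-of-freedom method of Pyper and Peterman: the effective sample
#' size N* satisfies
#' \deqn{1/N^* = 1/N + (2/N) \sum_j \rho_{xx}(j) \rho_{yy}(j),}
#' summing sample autocorrelation products over lags 1..floor(N/5) and
#' truncating the sum at the first negative product (the correction never
#' inflates the sample size). A two-sided t test on N* - 2 degrees of
#' freedom gives the corrected probability, which is never smaller than
#' the classical one.
#'
#' @param x,y numeric series of equal length >= 10, no missing values
#' @param maxLag highest lag entering the correction (default floor(N/5))
#' @return an object of class \code{"htest"} with \code{estimate} (the
#'   correlation), \code{parameter} (\code{n.eff}, effective sample size),
#'   \code{p.value} (corrected) and \code{p.uncorrected}
#' @examples
#' set.seed(1)
#' a <- as.numeric(arima.sim(list(ar = 0.8), 60))
#' b <- as.numeric(arima.sim(list(ar = 0.8), 60))
#' correctedCorrelation(a, b)
#' @export
correctedCorrelation <- function(x, y, maxLag = floor(length(x) / 5)) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 10L) stop("need at least 10 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance series")
  sigma <- stats::cor(x, y)
  acfx <- stats::acf(x, lag.max = maxLag, plot = FALSE)$acf[-1]
  acfy <- stats::acf(y, lag.max = maxLag, plot = FALSE)$acf[-1]
  prod <- acfx * acfy
  neg <- which(prod < 0)
  if (length(neg)) prod <- prod[seq_len(neg[1] - 1L)]
  s <- sum(prod)
  nEff <- 1 / (1 / n + (2 / n) * s)
  nEff <- min(nEff, n)
  nEff <- max(nEff, 3)  # the t test needs > 2 effective observations
  tval <- function(df) sigma * sqrt(df / (1 - sigma^2))
  pFor <- function(nn) {
    if (abs(sigma) >= 1) return(0)
    2 * stats::pt(-abs(tval(nn - 2)), df = nn - 2)
  }
  structure(list(
    statistic = c(t = tval(nEff - 2)),
    parameter = c(n.eff = nEff, n = n),
    p.value = pFor(nEff),
    p.uncorrected = pFor(n),
    estimate = c(cor = sigma),
    method = "Pearson correlation with autocorrelation-corrected effective df",
    data.name = paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  ), class = "htest")
}

#' Min-max standardisation
#'
#' Affine map of a series' observed range onto [lo, hi]. The reference
#' analyses use [0, 1] for clustering inputs and [-1, 1] for display.
#'
#' @param x numeric series with spread
#' @param lo,hi target interval endpoints
#' @return standardised series
#' @export
minmaxStandardise <- function(x, lo = 0, hi = 1) {
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) stop("constant series cannot be min-max standardised")
  lo + (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Centred simple moving average
#'
#' Smooths with a centred window of 2 * order + 1 points (order 1, the
#' "first-order" smoother, uses 3 points); near the ends the window
#' truncates to the available points. Order 0 is the identity.
#'
#' @param x numeric series
#' @param order half-width of the window (>= 0)
#' @return smoothed series, same length
#' @examples
#' movingAverage(c(0, 3, 0, 3, 0), 1)  # 1.5 1 2 1 1.5
#' @export
movingAverage <- function(x, order = 1) {
  stopifnot(order >= 0)
  if (order == 0) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - order):min(n, i + order)
    mean(x[w])
  }, numeric(1))
}

#' First principal component of standardised indicators
#'
#' Column-standardises a years-by-indicators table (zero mean, unit
#' variance), eigen-decomposes its correlation matrix and returns the
#' first-component scores — the construction behind composite indices such
#' as a multi-indicator plankton index of larval survival. The sign is
#' fixed so the first indicator loads non-negatively, for reproducible
#' output.
#'
#' @param table numeric matrix or data.frame, years in rows, >= 2
#'   indicator columns, no missing values
#' @return numeric PC1 scores with attributes \code{loadings} and
#'   \code{varExplained} (proportion of total variance)
#' @export
standardisedPcaIndex <- function(table) {
  m <- as.matrix(table)
  if (ncol(m) < 2L) stop("need at least 2 indicator columns")
  if (anyNA(m)) stop("missing values must be handled before the PCA")
  sds <- apply(m, 2L, stats::sd)
  if (all(sds == 0)) stop("rank-0 table: all indicators are constant")
  if (any(sds == 0)) stop("constant indicator column cannot be standardised")
  z <- scale(m)
  eg <- eigen(stats::cor(m), symmetric = TRUE)
  v <- eg$vectors[, 1L]
  if (v[1L] < 0) v <- -v
  scores <- as.numeric(z %*% v)
  attr(scores, "loadings") <- v
  attr(scores, "varExplained") <- eg$values[1L] / sum(eg$values)
  scores
}

#' Average-linkage clustering on Euclidean distances
#'
#' Pairwise Euclidean distances between item rows, merged by unweighted
#' average linkage (UPGMA) — the agglomeration rule sitting between
#' single and complete linkage. Backed by \code{stats::hclust}; merge
#' heights are checked to be non-decreasing.
#'
#' @param matrix numeric matrix, items in rows
#' @param k optional number of clusters to cut at
#' @return list with \code{hclust} (the merge tree) and, when \code{k} is
#'   given, \code{labels} (cluster membership per item)
#' @export
euclideanUpgma <- function(matrix, k = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L) stop("need at least 2 items")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  if (is.unsorted(hc$height)) warning("non-monotone merge heights")
  out <- list(hclust = hc)
  if (!is.null(k)) {
    if (k > nrow(m)) stop("k cannot exceed the number of items")
    out$labels <- as.integer(stats::cutree(hc, k = k))
  }
  out
}
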