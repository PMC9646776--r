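#' Equilibrium dSSB surface over (fishing intensity, carrying capacity)
#'
#' Long-run standardised SSB of the harvested logistic map at every node
#' of a regular (alpha, K) grid: X(alpha, K) = K (1 - alpha / r), floored
#' at 0 where removal outpaces growth. The reference grids run alpha over
#' [0, 0.5] and K over [0, 1] in steps of 0.001.
#'
#' @param r population growth rate
#' @param alphaAxis fishing-intensity nodes
#' @param kAxis carrying-capacity nodes
#' @return matrix [alpha, K] of equilibrium dSSB
#' @export
dssbSurface <- function(r = 0.5, alphaAxis = seq(0, 0.5, by = 0.001),
                        kAxis = seq(0, 1, by = 0.001)) {
  outer(alphaAxis, kAxis, function(a, k) equilibriumDssb(k, r, a))
}

# Central differences along one margin of a surface, with one-sided
# differences at nodes whose central stencil straddles the alpha = r kink
# of the floored equilibrium (a central difference there averages the two
# regimes and spikes spuriously).
marginSensitivity <- function(x, axis, along = c("row", "col")) {
  along <- match.arg(along)
  if (length(axis) < 3L) stop("need at least 3 nodes for central differences")
  if (along == "col") return(t(marginSensitivity(t(x), axis, "row")))
  n <- length(axis)
  i <- 2:(n - 1L)
  hi <- x[i + 1L, , drop = FALSE]
  lo <- x[i - 1L, , drop = FALSE]
  den <- axis[i + 1L] - axis[i - 1L]
  sens <- abs(hi - lo) / den
  # kink: one neighbour floored at 0, the other not -> one-sided difference
  mid <- x[i, , drop = FALSE]
  straddle <- (lo > 0 & hi == 0) | (lo == 0 & hi > 0)
  if (any(straddle)) {
    fwd <- abs(hi - mid) / (axis[i + 1L] - axis[i])
    bwd <- abs(mid - lo) / (axis[i] - axis[i - 1L])
    oneSided <- ifelse(mid > 0, bwd, fwd)
    sens[straddle] <- oneSided[straddle]
  }
  out <- matrix(NA_real_, n, ncol(x))
  out[i, ] <- sens
  # pad edges with the adjacent interior value so grids stay congruent
  out[1L, ] <- out[2L, ]
  out[n, ] <- out[n - 1L, ]
  out
}

#' Sensitivity of dSSB to fishing intensity
#'
#' Absolute central-difference derivative of the dSSB surface along the
#' fishing-intensity axis, per carrying-capacity column:
#' \deqn{\zeta_i = |X_{i+1} - X_{i-1}| / |\alpha_{i+1} - \alpha_{i-1}|.}
#' On the analytic equilibrium surface this approaches K / r below the
#' alpha = r floor. Nodes straddling the floor's kink use one-sided
#' differences; edge rows repeat the adjacent interior value.
#'
#' @param xSurface matrix [alpha, K] from \code{\link{dssbSurface}}
#' @param alphaAxis fishing-intensity nodes
#' @return matrix [alpha, K] of zeta
#' @export
zetaGrid <- function(xSurface, alphaAxis) {
  marginSensitivity(xSurface, alphaAxis, "row")
}

#' Sensitivity of dSSB to carrying capacity
#'
#' Mirror of \code{\link{zetaGrid}} along the K axis:
#' \deqn{\eta_j = |X_{j+1} - X_{j-1}| / |K_{j+1} - K_{j-1}|,}
#' approaching 1 - alpha / r below the floor.
#'
#' @param xSurface matrix [alpha, K]
#' @param kAxis carrying-capacity nodes
#' @return matrix [alpha, K] of eta
#' @export
etaGrid <- function(xSurface, kAxis) {
  marginSensitivity(xSurface, kAxis, "col")
}

#' Joint standardised sensitivity surface
#'
#' Elementwise sum I = zeta + eta, min-max standardised to [0, 1]:
#' I* = (I - min I) / (max I - min I). The standardisation is invariant to
#' affine transformations of I.
#'
#' @param zeta,eta congruent matrices from \code{\link{zetaGrid}} and
#'   \code{\link{etaGrid}}
#' @return matrix of I* in [0, 1]
#' @export
jointSensitivity <- function(zeta, eta) {
  if (!identical(dim(zeta), dim(eta))) stop("zeta and eta grids must be congruent")
  i <- zeta + eta
  rng <- range(i, na.rm = TRUE)
  if (rng[1] == rng[2]) stop("degenerate standardisation: I is constant")
  (i - rng[1]) / (rng[2] - rng[1])
}

#' Full sensitivity analysis
#'
#' Convenience wrapper building the equilibrium surface, both sensitivity
#' grids and the standardised joint surface on the reference grids
#' (alpha in [0, 0.5], K in [0, 1], step 0.001).
#'
#' @inheritParams dssbSurface
#' @return a \linkS4class{SensitivityGrids}
#' @export
sensitivityAnalysis <- function(r = 0.5, alphaAxis = seq(0, 0.5, by = 0.001),
                                kAxis = seq(0, 1, by = 0.001)) {
  x <- dssbSurface(r, alphaAxis, kAxis)
  z <- zetaGrid(x, alphaAxis)
  h <- etaGrid(x, kAxis)
  new("SensitivityGrids", alphaAxis = alphaAxis, kAxis = kAxis,
      xSurface = x, zeta = z, eta = h, iRaw = z + h,
      iStar = jointSensitivity(z, h), r = r)
}
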