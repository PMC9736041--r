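#' Convert between cumulative and differential DVH forms
#'
#' A cumulative curve stores the relative volume receiving at least each dose
#' edge; the differential form stores the relative volume falling in each
#' half-open bin \code{[edge_i, edge_{i+1})}. The two forms are exact
#' inverses whenever the cumulative curve ends at zero volume (all dose is
#' inside the grid). If a cumulative curve ends at a positive volume, the
#' residual mass above the last edge is placed in one appended bin of the
#' mean bin width so that total volume is conserved; such a curve does not
#' round-trip bit-for-bit (the appended edge persists).
#'
#' @param curve a [DVHCurve-class] of the appropriate kind.
#' @return A [DVHCurve-class] of the other kind on the same dose grid.
#' @examples
#' cv <- dvhCurve(c(0, 10, 20), c(1, 0.4, 0))
#' relVolume(cumulativeToDifferential(cv))  # 0.6 0.4
#' @export
cumulativeToDifferential <- function(curve) {
  if (!is(curve, "DVHCurve"))
    .errBadArgument("curve must be a DVHCurve")
  if (curve@kind != "cumulative")
    .errWrongKind("cumulativeToDifferential() requires a cumulative curve")
  d <- curve@doseEdges
  v <- curve@relVolume
  if (length(d) == 1L) {
    # single-point curve: all volume at (or above) the single edge
    d <- c(d, d + 0.1)
    v <- c(v, 0)
  }
  frac <- -diff(v)
  resid <- v[length(v)]
  if (resid > 1e-12) {
    w <- mean(diff(d))
    d <- c(d, d[length(d)] + w)
    frac <- c(frac, resid)
  }
  frac[abs(frac) < 1e-15] <- 0
  initialize(curve, kind = "differential", doseEdges = d, relVolume = frac)
}

#' @rdname cumulativeToDifferential
#' @export
differentialToCumulative <- function(curve) {
  if (!is(curve, "DVHCurve"))
    .errBadArgument("curve must be a DVHCurve")
  if (curve@kind != "differential")
    .errWrongKind("differentialToCumulative() requires a differential curve")
  cum <- c(rev(cumsum(rev(curve@relVolume))), 0)
  initialize(curve, kind = "cumulative", relVolume = cum)
}

#' Differential bin midpoints and fractions
#'
#' Internal canonicalisation: any curve reduced to (midpoint dose, volume
#' fraction) pairs, the representation in which mean dose and gEUD sums are
#' evaluated.
#' @noRd
.binFractions <- function(curve) {
  dc <- if (curve@kind == "cumulative") cumulativeToDifferential(curve) else curve
  d <- dc@doseEdges
  list(dose = (d[-length(d)] + d[-1L]) / 2, frac = dc@relVolume)
}
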