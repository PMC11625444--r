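#' Fraction of taxa with a gap at a site
#'
#' Counts `-` (internal or terminal alike) and `?` as gaps; IUPAC ambiguity
#' letters still represent a base call and count as occupied.
#'
#' @param alignment an alignment matrix.
#' @param site 1-based column index.
#' @return Proportion of gapped rows in `[0, 1]`.
#' @export
site_gap_fraction <- function(alignment, site) {
  if (site < 1L || site > ncol(alignment)) stop("site index out of range")
  mean(alignment[, site] %in% c("-", "?"))
}

#' Site-occupancy deletion mask
#'
#' The companion gappiness filter: a site is marked for deletion when its
#' gap fraction strictly exceeds `max_gap_fraction` ("more than 50% gaps" at
#' the default), so a column with exactly the threshold fraction is kept.
#' The filter is column-local and independent of the conflict trimmer; a
#' threshold of 0.18 reproduces an 82% site-occupancy filter.
#'
#' Occupancy is measured over all taxa present in the alignment given, so
#' the filter is less stringent when each locus is filtered as an isolated
#' file than when taxa absent from the locus are represented by gap rows.
#'
#' @param alignment an alignment matrix.
#' @param max_gap_fraction proportion in `[0, 1]`, default 0.5.
#' @return A [site_mask()] with reason `"occupancy"`.
#' @export
occupancy_mask <- function(alignment, max_gap_fraction = 0.5) {
  if (!is.numeric(max_gap_fraction) || is.na(max_gap_fraction) ||
      max_gap_fraction < 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must be in [0, 1]")
  frac <- colMeans(matrix(alignment %in% c("-", "?"), nrow(alignment)))
  site_mask(frac > max_gap_fraction, "occupancy")
}
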