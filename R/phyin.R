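#' Trimming parameters
#'
#' Bundles the four tunable parameters of the conflict trimmer with their
#' defaults: `d = 2` (maximum neighbour distance checked for pairwise
#' conflict), `e = TRUE` (treat internal gaps as a fifth state), `b = 10`
#' (block size over which the proportion of conflicted sites is measured),
#' and `p = 0.5` (threshold proportion; blocks whose proportion of
#' conflicted sites is as great or greater are marked).
#'
#' @param d integer >= 1, maximum neighbour distance.
#' @param e logical, internal gaps as a fifth state.
#' @param b integer >= 1, block size.
#' @param p proportion in `[0, 1]`, conflict threshold.
#' @return A list of class `phyin_params`.
#' @export
phyin_params <- function(d = 2L, e = TRUE, b = 10L, p = 0.5) {
  d <- as.integer(d); b <- as.integer(b)
  if (is.na(d) || d < 1L) stop("d must be an integer >= 1")
  if (is.na(b) || b < 1L) stop("b must be an integer >= 1")
  if (!is.logical(e) || is.na(e)) stop("e must be TRUE or FALSE")
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  structure(list(d = d, e = e, b = b, p = p), class = "phyin_params")
}

#' Flag sites in conflict with a near neighbour
#'
#' Every ordered pair of columns at most `d` apart is tested for pairwise
#' phylogenetic incompatibility ([are_incompatible()]); when a pair is
#' incompatible, both members are flagged as conflicted. Conflict is always
#' pairwise, even for `d > 1`. The number of conflicted sites can exceed the
#' number of conflicting pairs (each conflict flags two sites) or fall short
#' of it (k mutually conflicting sites contribute up to choose(k, 2) pairs).
#'
#' @param alignment an alignment matrix.
#' @param gaps gap classification from [classify_gaps()]; computed if `NULL`.
#' @param d maximum neighbour distance (integer >= 1).
#' @param e logical, treat internal gaps as a fifth state.
#' @return A logical vector of length `ncol(alignment)`.
#' @export
find_conflicted <- function(alignment, gaps = NULL, d = 2L, e = TRUE) {
  if (d < 1L) stop("d must be >= 1")
  if (is.null(gaps)) gaps <- classify_gaps(alignment)
  L <- ncol(alignment)
  cols <- lapply(seq_len(L), function(s) encode_column(alignment, gaps, s, e))
  flags <- logical(L)
  for (i in seq_len(L)) {
    for (j in seq(i + 1L, length.out = min(d, L - i))) {
      if (are_incompatible(cols[[i]], cols[[j]])) flags[i] <- flags[j] <- TRUE
    }
  }
  flags
}

#' Mark blocks with a high proportion of conflicted sites
#'
#' A window of `b` consecutive sites is slid over every start position (an
#' alignment shorter than `b` forms a single window of its own length).
#' Whenever the proportion of conflicted sites in a window is as great or
#' greater than `p`, the sites from the window's first conflicted to its
#' last conflicted site are marked for deletion; note a triggering window is
#' never deleted whole. Marks from overlapping windows are unioned.
#'
#' @param flags logical conflict flags from [find_conflicted()].
#' @param b block size (integer >= 1).
#' @param p threshold proportion in `[0, 1]`.
#' @return A [site_mask()] with reason `"phyin"`.
#' @export
select_blocks <- function(flags, b = 10L, p = 0.5) {
  if (b < 1L) stop("b must be >= 1")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  L <- length(flags)
  delete <- logical(L)
  win <- min(b, L)
  for (start in seq_len(L - win + 1L)) {
    idx <- start:(start + win - 1L)
    hit <- idx[flags[idx]]
    if (length(hit) == 0L) next
    if (length(hit) / win >= p) delete[hit[1L]:hit[length(hit)]] <- TRUE
  }
  site_mask(delete, "phyin")
}

#' Conflict-based deletion mask for an alignment
#'
#' Composes the full procedure: classify gaps, flag sites conflicting with a
#' neighbour within distance `d`, scan blocks of `b` sites against threshold
#' `p`, and mark the conflicted spans of triggering blocks for deletion.
#' Purely deterministic in its inputs.
#'
#' @param alignment an alignment matrix.
#' @param params a [phyin_params()] object.
#' @return A [site_mask()] with reason `"phyin"`.
#' @examples
#' aln <- phyin_example_alignment()
#' m <- phyin_mask(aln)
#' which(m$delete)
#' @export
phyin_mask <- function(alignment, params = phyin_params()) {
  stopifnot(inherits(params, "phyin_params"))
  gaps <- classify_gaps(alignment)
  flags <- find_conflicted(alignment, gaps, d = params$d, e = params$e)
  select_blocks(flags, b = params$b, p = params$p)
}

#' Summarize a trimming mask
#'
#' @param alignment the alignment the mask applies to.
#' @param mask a [site_mask()].
#' @return A list: `n_sites`, `n_deleted`, per-reason counts
#'   (`n_phyin`, `n_occupancy`), and `proportion_trimmed`.
#' @export
trim_report <- function(alignment, mask) {
  mask <- validate_site_mask(mask)
  if (length(mask$delete) != ncol(alignment))
    stop("mask length does not match alignment")
  reasons <- unlist(mask$reason)
  list(n_sites = ncol(alignment),
       n_deleted = sum(mask$delete),
       n_phyin = sum(reasons == "phyin"),
       n_occupancy = sum(reasons == "occupancy"),
       proportion_trimmed = sum(mask$delete) / ncol(alignment))
}

#' The small worked alignment shipped with the package
#'
#' An 8-taxon, 10-site nucleotide alignment whose first nine sites form a
#' conflicted block: with default parameters exactly three incompatible
#' neighbour pairs are found (sites 1-2, 2-3 and 7-9), five sites are
#' conflicted, and sites 1 through 9 are deleted, leaving site 10.
#'
#' @return An alignment matrix.
#' @export
phyin_example_alignment <- function() {
  read_fasta(system.file("extdata", "conflict_block_example.fasta",
                         package = "phyin", mustWork = TRUE))
}
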