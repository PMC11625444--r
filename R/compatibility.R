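# State codes used by the compatibility machinery: A,C,G,T,GAP are real
# states; NA is missing. Terminal gaps are always missing; internal gaps are
# the fifth state GAP only when requested.

.state_levels <- c("A", "C", "G", "T", "GAP")

#' Encode one alignment column for the compatibility test
#'
#' Maps the symbols of a column onto the state alphabet
#' `A, C, G, T, GAP` with `NA` for missing data. Terminal gaps are always
#' missing — they represent unsequenced flanks, not indel events. Internal
#' gaps become the fifth state `GAP` when `fifth_state = TRUE` (treating an
#' indel as seriously as a substitution), otherwise missing. `?` and IUPAC
#' ambiguity letters are always missing.
#'
#' @param alignment an alignment matrix.
#' @param gaps gap classification from [classify_gaps()].
#' @param site 1-based column index.
#' @param fifth_state logical: treat internal gaps as a fifth state?
#' @return A character vector of per-taxon states (`NA` = missing) with
#'   attributes `site` and `fifth_state`.
#' @export
encode_column <- function(alignment, gaps, site, fifth_state = TRUE) {
  if (site < 1L || site > ncol(alignment)) stop("site index out of range")
  sym <- alignment[, site]
  cls <- gaps[, site]
  st <- ifelse(cls == "observed", sym, NA_character_)
  if (fifth_state) st[cls == "internal_gap"] <- "GAP"
  structure(st, site = site, fifth_state = fifth_state)
}

#' Bipartite graph of observed state combinations between two columns
#'
#' For every taxon with a non-missing state in both columns, one edge joins
#' the taxon's state in the first column to its state in the second; parallel
#' edges are collapsed. Two columns are phylogenetically compatible exactly
#' when this graph is acyclic.
#'
#' @param ci,cj encoded columns from [encode_column()], same taxon order.
#' @return A list with `left` and `right` (distinct observed states per
#'   column) and `edges` (two-column character matrix of distinct pairs).
#' @export
build_state_pair_graph <- function(ci, cj) {
  if (length(ci) != length(cj))
    stop("columns have different taxon counts (", length(ci), " vs ", length(cj), ")")
  both <- !is.na(ci) & !is.na(cj)
  pairs <- unique(cbind(ci[both], cj[both]))
  dimnames(pairs) <- list(NULL, c("left", "right"))
  list(left = unique(pairs[, 1L]), right = unique(pairs[, 2L]), edges = pairs)
}

#' Pairwise phylogenetic incompatibility of two columns
#'
#' Two characters are incompatible when no tree exists on which both could
#' evolve without homoplasy. Equivalently, the bipartite state-pair graph of
#' the two columns contains a cycle. In the binary case this reduces to the
#' classical four-gamete test: the pair is incompatible exactly when all four
#' state combinations occur.
#'
#' The cycle test is run as a forest check with union-find: edges are added
#' one by one, and an edge joining two vertices already connected closes a
#' cycle. Only taxa observed in both columns contribute; columns sharing no
#' taxa, or constant on the shared taxa, are always compatible.
#'
#' @param ci,cj encoded columns from [encode_column()], same taxon order.
#' @return `TRUE` if the columns are incompatible.
#' @seealso [brute_force_compatible()] for the tree-enumeration oracle.
#' @export
are_incompatible <- function(ci, cj) {
  if (length(ci) != length(cj))
    stop("columns have different taxon counts (", length(ci), " vs ", length(cj), ")")
  both <- which(!is.na(ci) & !is.na(cj))
  if (length(both) < 2L) return(FALSE)
  a <- match(ci[both], .state_levels)
  b <- match(cj[both], .state_levels) + 5L
  keys <- unique(a * 16L + b)
  if (length(keys) < 4L) return(FALSE)  # shortest bipartite cycle has 4 edges
  ea <- keys %/% 16L
  eb <- keys %% 16L
  # union-find over vertex ids 1..10 (left states 1..5, right 6..10)
  parent <- 1:10
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  for (k in seq_along(ea)) {
    ra <- find(ea[k]); rb <- find(eb[k])
    if (ra == rb) return(TRUE)
    parent[ra] <- rb
  }
  FALSE
}

# conflict verdict for two raw columns of an alignment
.incompatible_sites <- function(alignment, gaps, i, j, fifth_state) {
  are_incompatible(encode_column(alignment, gaps, i, fifth_state),
                   encode_column(alignment, gaps, j, fifth_state))
}
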