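# Tree-enumeration oracle for pairwise compatibility. Deliberately
# independent of the state-pair-graph cycle test: it takes the definition of
# compatibility literally and searches all unrooted binary topologies for a
# tree on which both characters are homoplasy-free.

.tree_cache <- new.env(parent = emptyenv())

# postorder edge matrices for all unrooted binary topologies on n labelled
# tips (3, 15, 105, 945, 10395 trees for n = 4..8)
.all_topologies <- function(n) {
  key <- as.character(n)
  if (is.null(.tree_cache[[key]])) {
    trees <- phangorn::allTrees(n, rooted = FALSE)
    # labelled topologies are enumerated exhaustively, so tip number i can
    # stand for taxon i directly — no relabelling needed
    .tree_cache[[key]] <- lapply(trees, function(tr) {
      ape::reorder.phylo(tr, "postorder")$edge
    })
  }
  .tree_cache[[key]]
}

# Fitch (unordered) parsimony length of one character on one topology.
# states: integer vector per tip, 1..5, no NA; edges: postorder edge matrix.
.fitch_length <- function(states, edges, n_tip) {
  n_node <- max(edges)
  sets <- integer(n_node)
  sets[seq_len(n_tip)] <- bitwShiftL(1L, states - 1L)
  len <- 0L
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; child <- edges[k, 2L]
    if (sets[par] == 0L) {
      sets[par] <- sets[child]
    } else {
      inter <- bitwAnd(sets[par], sets[child])
      if (inter == 0L) {
        len <- len + 1L
        sets[par] <- bitwOr(sets[par], sets[child])
      } else {
        sets[par] <- inter
      }
    }
  }
  len
}

#' Brute-force compatibility by exhaustive tree enumeration
#'
#' Test oracle for [are_incompatible()]. Restricting attention to the taxa
#' with a non-missing state in both columns, it enumerates every unrooted
#' binary topology on those taxa and asks whether some tree gives each
#' character a Fitch parsimony length equal to its number of distinct states
#' minus one, i.e. makes both characters homoplasy-free. Pairs with three or
#' fewer doubly-observed taxa, or where either restricted column is
#' constant, are compatible without enumeration (any character on at most
#' three tips is convex on the single unrooted topology).
#'
#' Enumeration is capped at 8 doubly-observed taxa (10395 topologies).
#'
#' @param ci,cj encoded columns from [encode_column()], same taxon order.
#' @return `TRUE` if some tree accommodates both characters without
#'   homoplasy.
#' @export
brute_force_compatible <- function(ci, cj) {
  if (length(ci) != length(cj))
    stop("columns have different taxon counts (", length(ci), " vs ", length(cj), ")")
  both <- which(!is.na(ci) & !is.na(cj))
  si <- match(ci[both], .state_levels)
  sj <- match(cj[both], .state_levels)
  ki <- length(unique(si)); kj <- length(unique(sj))
  n <- length(both)
  if (n <= 3L || ki <= 1L || kj <= 1L) return(TRUE)
  if (n > 8L) stop("brute-force oracle is limited to 8 doubly-observed taxa, got ", n)
  for (edges in .all_topologies(n)) {
    if (.fitch_length(si, edges, n) == ki - 1L &&
        .fitch_length(sj, edges, n) == kj - 1L) return(TRUE)
  }
  FALSE
}
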