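# Seeded generator of test alignments: contiguous tree-consistent ("clean")
# regions flanked by i.i.d. randomized ("noise") regions, with terminal-end
# erosion and internal gap injection. Clean columns are built from character
# state changes placed on edges of one shared tree, so every clean column is
# homoplasy-free on that tree and clean columns are pairwise compatible by
# construction, even when internal gaps are read as a fifth state.

#' Configuration for synthetic fixture alignments
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_clean_sites number of tree-consistent sites.
#' @param n_noise_sites number of randomized sites.
#' @param noise_position where the noise sits relative to the clean core:
#'   `"left"`, `"right"`, `"both-flanks"` (half each side, emulating the
#'   fragment-prone flanks of sequence-capture loci) or `"interior"`.
#' @param terminal_gap_rate expected per-row proportion of sites eroded to
#'   gaps from the two sequence ends combined.
#' @param internal_gap_rate expected proportion of gap cells injected inside
#'   observed stretches (i.i.d. per cell in noise regions; placed as indel
#'   events on tree edges in clean regions so compatibility is preserved).
#' @param seed integer seed governing all randomness.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 16L, n_clean_sites = 200L,
                         n_noise_sites = 200L,
                         noise_position = c("both-flanks", "left", "right", "interior"),
                         terminal_gap_rate = 0.1,
                         internal_gap_rate = 0.02,
                         seed = 1L) {
  noise_position <- match.arg(noise_position)
  stopifnot(n_taxa >= 4L, n_clean_sites >= 0L, n_noise_sites >= 0L,
            terminal_gap_rate >= 0, terminal_gap_rate <= 1,
            internal_gap_rate >= 0, internal_gap_rate <= 1)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_clean_sites = as.integer(n_clean_sites),
                 n_noise_sites = as.integer(n_noise_sites),
                 noise_position = noise_position,
                 terminal_gap_rate = terminal_gap_rate,
                 internal_gap_rate = internal_gap_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Random unrooted binary tree topology
#'
#' Uniformly distributed labelled topology (tips `t1 ... tn`), deterministic
#' for a given seed.
#'
#' @param n_taxa number of tips, >= 4.
#' @param seed integer seed.
#' @return An unrooted `phylo` object.
#' @export
random_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 4L) stop("a bifurcating unrooted tree needs at least 4 taxa")
  set.seed(seed)
  ape::rtopology(n_taxa, rooted = FALSE,
                 tip.label = paste0("t", seq_len(n_taxa)))
}

# tip-index sets below each edge (child side), in the tree's own rooting;
# these sets are laminar, so painting states over them keeps columns convex
.edge_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; child <- tree$edge[k, 2L]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  lapply(tree$edge[, 2L], function(v) below[[v]])
}

#' Tree-consistent alignment block
#'
#' Each column starts from a uniform ancestral nucleotide; one randomly
#' chosen edge of the tree receives a substitution giving a derived state to
#' all taxa below it, and with probability `second_event_prob` a second edge
#' receives a third state. Because all painted tip sets are clades of one
#' tree, every column is homoplasy-free on it and any two columns are
#' mutually compatible.
#'
#' @param tree a `phylo` tree whose tips index the rows.
#' @param n_sites number of columns to generate.
#' @param seed integer seed.
#' @param second_event_prob probability of a second, third-state change.
#' @return A character matrix (tips x sites) over `A,C,G,T`.
#' @export
clean_region <- function(tree, n_sites, seed = 1L, second_event_prob = 0.3) {
  set.seed(seed)
  n <- length(tree$tip.label)
  sets <- .edge_tip_sets(tree)
  nuc <- c("A", "C", "G", "T")
  m <- matrix(NA_character_, n, n_sites, dimnames = list(tree$tip.label, NULL))
  for (s in seq_len(n_sites)) {
    anc <- sample(nuc, 1L)
    col <- rep(anc, n)
    derived <- sample(setdiff(nuc, anc), 1L)
    col[sets[[sample.int(length(sets), 1L)]]] <- derived
    if (stats::runif(1) < second_event_prob) {
      third <- sample(setdiff(nuc, c(anc, derived)), 1L)
      col[sets[[sample.int(length(sets), 1L)]]] <- third
    }
    m[, s] <- col
  }
  m
}

#' Randomized alignment block
#'
#' Independent uniform draws over `A,C,G,T` for every cell; models a region
#' of the alignment with no phylogenetic structure at all.
#'
#' @param n_taxa,n_sites block dimensions, >= 1.
#' @param seed integer seed.
#' @return A character matrix (`n_taxa` x `n_sites`).
#' @export
noise_region <- function(n_taxa, n_sites, seed = 1L) {
  stopifnot(n_taxa >= 1L, n_sites >= 1L)
  set.seed(seed)
  matrix(sample(c("A", "C", "G", "T"), n_taxa * n_sites, replace = TRUE),
         n_taxa, n_sites)
}

#' Generate a labelled fixture alignment
#'
#' Concatenates clean and noise blocks according to `noise_position`, then
#' erodes sequence ends into terminal gaps and injects internal gaps at the
#' configured rates. In clean regions internal gaps are placed as indel
#' events on edges of the generating tree (with per-column event probability
#' scaled so the expected gap-cell fraction matches `internal_gap_rate`),
#' preserving pairwise compatibility; in noise regions they are i.i.d.
#'
#' @param config a [synth_config()].
#' @return A list with `alignment` (character matrix), `labels` (per-site
#'   `"clean"`/`"noise"`), and `tree` (the generating `phylo`, or `NULL`
#'   when `n_clean_sites = 0`).
#' @export
make_fixture <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_taxa
  tree <- NULL
  clean <- NULL
  if (config$n_clean_sites > 0L) {
    tree <- random_tree(n, seed = config$seed)
    clean <- clean_region(tree, config$n_clean_sites, seed = config$seed + 1L)
  }
  taxa <- paste0("t", seq_len(n))
  noise <- if (config$n_noise_sites > 0L)
    noise_region(n, config$n_noise_sites, seed = config$seed + 2L) else NULL
  if (!is.null(noise)) rownames(noise) <- taxa
  if (is.null(clean) && is.null(noise)) stop("fixture has zero sites")

  piece <- function(block, lab) list(block = block, lab = lab)
  parts <- if (is.null(noise)) {
    list(piece(clean, "clean"))
  } else if (is.null(clean)) {
    list(piece(noise, "noise"))
  } else switch(config$noise_position,
    left = list(piece(noise, "noise"), piece(clean, "clean")),
    right = list(piece(clean, "clean"), piece(noise, "noise")),
    interior = {
      h <- ncol(clean) %/% 2L
      list(piece(clean[, seq_len(h), drop = FALSE], "clean"),
           piece(noise, "noise"),
           piece(clean[, seq_len(ncol(clean) - h) + h, drop = FALSE], "clean"))
    },
    `both-flanks` = {
      h <- ncol(noise) %/% 2L
      list(piece(noise[, seq_len(h), drop = FALSE], "noise"),
           piece(clean, "clean"),
           piece(noise[, seq_len(ncol(noise) - h) + h, drop = FALSE], "noise"))
    })
  aln <- do.call(cbind, lapply(parts, `[[`, "block"))
  labels <- unlist(lapply(parts, function(x) rep(x$lab, ncol(x$block))))
  rownames(aln) <- taxa
  L <- ncol(aln)

  set.seed(config$seed + 3L)
  # terminal erosion: each end of each row loses Binomial(L, rate/2) sites
  if (config$terminal_gap_rate > 0) {
    for (i in seq_len(n)) {
      nl <- stats::rbinom(1L, L, config$terminal_gap_rate / 2)
      nr <- stats::rbinom(1L, L, config$terminal_gap_rate / 2)
      nr <- min(nr, L - nl)
      if (nl > 0L) aln[i, seq_len(nl)] <- "-"
      if (nr > 0L) aln[i, seq_len(nr) + (L - nr)] <- "-"
    }
  }
  if (config$internal_gap_rate > 0) {
    noise_cells <- aln != "-" & matrix(rep(labels == "noise", each = n), n)
    drop_mask <- noise_cells & matrix(stats::runif(n * L) < config$internal_gap_rate, n)
    aln[drop_mask] <- "-"
    if (!is.null(clean)) {
      sets <- .edge_tip_sets(tree)
      mean_frac <- mean(lengths(sets)) / n
      q <- min(1, config$internal_gap_rate / mean_frac)
      for (s in which(labels == "clean")) {
        if (stats::runif(1) < q) {
          tips <- sets[[sample.int(length(sets), 1L)]]
          aln[tips, s] <- "-"
        }
      }
    }
  }
  list(alignment = as_alignment(aln), labels = labels, tree = tree)
}

#' Write a fixture to disk
#'
#' Writes the alignment as FASTA and the per-site region labels as a
#' two-column TSV sidecar (`site`, `region`).
#'
#' @param fixture result of [make_fixture()].
#' @param fasta_path,labels_path output paths.
#' @return Invisibly, `fasta_path`.
#' @export
write_fixture <- function(fixture, fasta_path, labels_path) {
  write_fasta(fixture$alignment, fasta_path)
  utils::write.table(
    data.frame(site = seq_along(fixture$labels), region = fixture$labels),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
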