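#' Nucleotide alignments as character matrices
#'
#' Throughout this package an alignment is a plain character matrix with one
#' row per taxon (rownames are the taxon labels) and one column per site.
#' Symbols are upper-case and drawn from the nucleotides `A`, `C`, `G`, `T`,
#' the gap glyph `-`, the missing-data glyph `?`, and the IUPAC ambiguity
#' letters (`N`, `R`, `Y`, `S`, `W`, `K`, `M`, `B`, `D`, `H`, `V`).
#' `as_alignment()` validates and normalizes such a matrix: symbols are
#' upper-cased, `U` is rewritten to `T` (so RNA input is accepted), taxon
#' labels must be unique and non-empty, and all rows must have the same
#' length.
#'
#' @param x a character matrix of single-character strings, with rownames.
#' @return A validated character matrix of class unchanged (plain matrix).
#' @examples
#' as_alignment(rbind(a = c("a", "c", "-", "g"), b = c("A", "C", "T", "G")))
#' @export
as_alignment <- function(x) {
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("alignment must have at least one taxon and one site")
  labs <- rownames(x)
  if (is.null(labs) || anyNA(labs) || any(!nzchar(labs)))
    stop("all taxa must have non-empty labels")
  if (anyDuplicated(labs))
    stop("duplicate taxon labels: ", paste(unique(labs[duplicated(labs)]), collapse = ", "))
  x <- toupper(x)
  x[x == "U"] <- "T"
  bad <- which(!(x %in% .alignment_alphabet))
  if (length(bad)) {
    w <- arrayInd(bad[1L], dim(x))
    stop(sprintf("invalid symbol '%s' for taxon '%s' at site %d",
                 x[bad[1L]], labs[w[1L]], w[2L]))
  }
  x
}

.alignment_alphabet <- c("A", "C", "G", "T", "-", "?",
                         "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# symbols carrying no state information for the compatibility machinery
.missing_symbols <- c("?", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read a FASTA alignment
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into an
#' alignment matrix. Sequences must all have the same length; symbols are
#' normalized as by [as_alignment()]. Taxon order follows file order.
#'
#' @param path path to a FASTA file.
#' @return An alignment matrix (taxa x sites).
#' @seealso [write_fasta()], [as_alignment()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  labs <- sub("\\s.*$", "", names(seqs))
  wid <- Biostrings::width(seqs)
  if (length(unique(wid)) > 1L) {
    off <- labs[wid != wid[1L]][1L]
    stop(sprintf("sequences differ in length (taxon '%s' has %d sites, '%s' has %d)",
                 labs[1L], wid[1L], off, wid[wid != wid[1L]][1L]))
  }
  if (wid[1L] == 0L) stop("sequences have zero length")
  m <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  rownames(m) <- labs
  as_alignment(m)
}

#' Write an alignment to FASTA
#'
#' Writes one unwrapped record per taxon. A zero-site alignment yields
#' header-only records. Round-tripping through [read_fasta()] preserves
#' symbols and taxon order exactly.
#'
#' @param alignment an alignment matrix.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(alignment, path) {
  seqs <- apply(alignment, 1L, paste, collapse = "")
  if (ncol(alignment) == 0L) seqs <- rep("", nrow(alignment))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- rownames(alignment)
  Biostrings::writeXStringSet(x, path, width = 20001L)
  invisible(path)
}

#' Classify every cell as observed, internal gap, terminal gap, or missing
#'
#' A `-` is a terminal gap when the run of gaps containing it reaches either
#' sequence end without an intervening observed nucleotide; other `-` cells
#' are internal gaps, which represent insertion/deletion events. `?` and the
#' IUPAC ambiguity letters are missing data; nucleotides are observed. The
#' classification of a row depends only on that row. A row of nothing but
#' gaps is entirely terminal gap.
#'
#' The distinction matters because terminal gaps in sequence-capture data
#' usually mean failure to sequence, not indels, so they are never promoted
#' to a fifth character state (see [encode_column()]).
#'
#' @param alignment an alignment matrix.
#' @return A character matrix of the same shape with entries in
#'   `"observed"`, `"internal_gap"`, `"terminal_gap"`, `"missing"`.
#' @export
classify_gaps <- function(alignment) {
  out <- matrix("observed", nrow(alignment), ncol(alignment),
                dimnames = dimnames(alignment))
  out[matrix(alignment %in% .missing_symbols, nrow(alignment))] <- "missing"
  L <- ncol(alignment)
  for (i in seq_len(nrow(alignment))) {
    gap <- alignment[i, ] == "-"
    if (!any(gap)) next
    obs <- which(alignment[i, ] != "-")
    if (length(obs) == 0L) {
      out[i, ] <- "terminal_gap"
      next
    }
    cls <- ifelse(gap, "internal_gap", out[i, ])
    first <- obs[1L]; last <- obs[length(obs)]
    if (first > 1L) cls[seq_len(first - 1L)] <- "terminal_gap"
    if (last < L) cls[(last + 1L):L] <- "terminal_gap"
    out[i, ] <- cls
  }
  out
}

#' Drop the columns flagged by a site mask
#'
#' Returns the alignment restricted to the unflagged columns, preserving
#' taxa and relative column order. An all-flagged mask yields a zero-site
#' alignment.
#'
#' @param alignment an alignment matrix.
#' @param mask a [site_mask()] of length `ncol(alignment)`.
#' @return The trimmed alignment matrix.
#' @export
apply_mask <- function(alignment, mask) {
  mask <- validate_site_mask(mask)
  if (length(mask$delete) != ncol(alignment))
    stop("mask length (", length(mask$delete), ") != number of sites (",
         ncol(alignment), ")")
  alignment[, !mask$delete, drop = FALSE]
}
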