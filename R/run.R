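#' Trim a FASTA alignment end to end
#'
#' Reads an alignment, computes the conflict-based deletion mask, optionally
#' unions it with the site-occupancy mask, and writes the requested
#' artifacts. Per-stage counts are reported via `message()` (standard
#' error), so standard output stays clean for data. The run is fully
#' deterministic: two runs on the same input produce byte-identical output.
#'
#' @param input path to the input FASTA file.
#' @param output path for the trimmed FASTA (ignored in `"mask-only"` mode;
#'   defaults to standard output in modes that write an alignment).
#' @param params a [phyin_params()] object.
#' @param occupancy maximum gap fraction for the occupancy filter
#'   (default 0.5), or `NULL`/`"off"` to disable it.
#' @param mode one of `"trimmed-fasta"`, `"mask-only"`, `"both"`.
#' @param mask_out optional path for the per-site mask report (TSV).
#' @param report optional path for the summary report (TSV key/value).
#' @param quiet suppress progress messages.
#' @return Invisibly, the [trim_report()] list.
#' @export
run_trim <- function(input, output = NULL, params = phyin_params(),
                     occupancy = 0.5, mode = c("trimmed-fasta", "mask-only", "both"),
                     mask_out = NULL, report = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  if (identical(occupancy, "off")) occupancy <- NULL
  aln <- read_fasta(input)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("read %d taxa x %d sites from %s", nrow(aln), ncol(aln), input)
  mask <- phyin_mask(aln, params)
  say("conflict trimming flagged %d sites (d=%d, e=%s, b=%d, p=%g)",
      sum(mask$delete), params$d, tolower(params$e), params$b, params$p)
  if (!is.null(occupancy)) {
    occ <- occupancy_mask(aln, occupancy)
    say("occupancy filter flagged %d sites (gap fraction > %g)",
        sum(occ$delete), occupancy)
    mask <- combine_masks(mask, occ)
  }
  rep <- trim_report(aln, mask)
  say("deleting %d of %d sites (%.1f%%)", rep$n_deleted, rep$n_sites,
      100 * rep$proportion_trimmed)
  if (mode %in% c("trimmed-fasta", "both")) {
    trimmed <- apply_mask(aln, mask)
    if (is.null(output)) {
      seqs <- if (ncol(trimmed) == 0L) rep("", nrow(trimmed))
              else apply(trimmed, 1L, paste, collapse = "")
      writeLines(paste0(">", rownames(trimmed), "\n", seqs))
    } else {
      write_fasta(trimmed, output)
      say("wrote trimmed alignment to %s", output)
    }
  }
  if (mode %in% c("mask-only", "both") && is.null(mask_out) && !is.null(output))
    mask_out <- paste0(output, ".mask.tsv")
  if (!is.null(mask_out)) {
    write_mask_report(mask, mask_out)
    say("wrote mask report to %s", mask_out)
  }
  if (!is.null(report)) {
    utils::write.table(
      data.frame(key = names(rep), value = unlist(rep)),
      report, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(rep)
}
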