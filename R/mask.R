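#' Per-site deletion masks
#'
#' A site mask records, for every column of an alignment, whether it is
#' marked for deletion and why. `reason` holds, per site, a character vector
#' that is a subset of `c("phyin", "occupancy")`; it is non-empty exactly
#' where `delete` is `TRUE`.
#'
#' @param delete logical vector, `TRUE` = delete the site.
#' @param reason either a single string applied to every flagged site, or a
#'   list of character vectors (one per site).
#' @return An object of class `site_mask`: a list with elements `delete`
#'   (logical) and `reason` (list of character vectors).
#' @examples
#' site_mask(c(TRUE, FALSE, TRUE), "phyin")
#' @export
site_mask <- function(delete, reason = "phyin") {
  delete <- as.logical(delete)
  if (anyNA(delete)) stop("mask flags must be TRUE or FALSE")
  if (is.character(reason) && length(reason) == 1L) {
    reason <- lapply(delete, function(f) if (f) reason else character(0))
  }
  out <- structure(list(delete = delete, reason = reason), class = "site_mask")
  validate_site_mask(out)
}

validate_site_mask <- function(mask) {
  if (!inherits(mask, "site_mask")) stop("not a site_mask")
  if (length(mask$reason) != length(mask$delete))
    stop("reason list and flag vector differ in length")
  n_reason <- lengths(mask$reason)
  if (any(n_reason > 0L & !mask$delete) || any(n_reason == 0L & mask$delete))
    stop("reasons must be non-empty exactly at flagged sites")
  bad <- setdiff(unique(unlist(mask$reason)), c("phyin", "occupancy"))
  if (length(bad)) stop("unknown mask reason: ", paste(bad, collapse = ", "))
  mask
}

#' @export
print.site_mask <- function(x, ...) {
  cat(sprintf("site_mask: %d of %d sites flagged for deletion\n",
              sum(x$delete), length(x$delete)))
  tab <- table(unlist(x$reason))
  for (r in names(tab)) cat(sprintf("  %-10s %d\n", r, tab[[r]]))
  invisible(x)
}

#' @export
length.site_mask <- function(x) length(x$delete)

#' Union of two site masks
#'
#' Site-wise union of the deletion flags, with reasons merged. The operation
#' is commutative, associative and idempotent, so masks from different
#' filters (conflict-based and occupancy-based) can be combined in any
#' order.
#'
#' @param a,b site masks of equal length.
#' @return A `site_mask`.
#' @export
combine_masks <- function(a, b) {
  a <- validate_site_mask(a); b <- validate_site_mask(b)
  if (length(a$delete) != length(b$delete))
    stop("masks differ in length (", length(a$delete), " vs ", length(b$delete), ")")
  reason <- mapply(function(x, y) sort(unique(c(x, y))),
                   a$reason, b$reason, SIMPLIFY = FALSE)
  structure(list(delete = a$delete | b$delete, reason = reason),
            class = "site_mask")
}

#' Write a mask as a tab-separated report
#'
#' One row per site, 1-based, with columns `site`, `action` (`keep` or
#' `delete`) and `reason` (`phyin`, `occupancy`, `both`, or `.` for kept
#' sites).
#'
#' @param mask a `site_mask`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_mask_report <- function(mask, path) {
  mask <- validate_site_mask(mask)
  reason <- vapply(mask$reason, function(r) {
    if (length(r) == 0L) "." else if (length(r) > 1L) "both" else r
  }, character(1))
  df <- data.frame(site = seq_along(mask$delete),
                   action = ifelse(mask$delete, "delete", "keep"),
                   reason = reason)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
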