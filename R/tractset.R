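#' Define an ordered set of white-matter tracts
#'
#' A tract set fixes the columns of every connectivity blueprint.  Two
#' blueprints are comparable only if their tract sets are identical
#' element-wise and in the same order: the divergence between two
#' fingerprints is meaningless unless entry k refers to the same anatomical
#' bundle in both.
#'
#' @param names Character vector of unique, non-empty tract identifiers.
#' @param hemisphere Optional character vector (`"left"`, `"right"` or
#'   `"cross"`) tagging each tract's hemisphere.  If `NULL`, tags are
#'   inferred from a trailing `_L`/`_R` in the name and default to
#'   `"cross"` otherwise.
#' @return An object of class `tract_set` with fields `names` and
#'   `hemisphere`.
#' @examples
#' ts <- tract_set(c("AF_L", "AF_R", "FMI"))
#' ts$hemisphere
#' @export
tract_set <- function(names, hemisphere = NULL) {
  names <- as.character(names)
  if (length(names) == 0L) stop("a tract set must contain at least one tract")
  if (anyNA(names) || any(!nzchar(names)))
    stop("tract names must be non-empty strings")
  if (anyDuplicated(names))
    stop("duplicate tract name: ", names[duplicated(names)][1L])
  if (is.null(hemisphere)) {
    hemisphere <- rep("cross", length(names))
    hemisphere[grepl("_l$", names, ignore.case = TRUE)] <- "left"
    hemisphere[grepl("_r$", names, ignore.case = TRUE)] <- "right"
  }
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != length(names))
    stop("hemisphere tags must match the number of tract names")
  bad <- setdiff(unique(hemisphere), c("left", "right", "cross"))
  if (length(bad))
    stop("invalid hemisphere tag(s): ", paste(bad, collapse = ", "))
  structure(list(names = names, hemisphere = hemisphere),
            class = "tract_set")
}

#' Canonical 39-tract set
#'
#' Convenience constructor for the standard blueprint dimension: 18 tracts
#' per hemisphere plus 3 cross-hemispheric pathways, 39 in total.  Names
#' are generic placeholders (`tract01_L`, ..., `cross3`); real analyses
#' supply their own tract names.
#'
#' @param n_pairs Number of per-hemisphere tract pairs (default 18).
#' @param n_cross Number of cross-hemispheric pathways (default 3).
#' @return A `tract_set` of length `2 * n_pairs + n_cross`.
#' @export
default_tract_set <- function(n_pairs = 18L, n_cross = 3L) {
  stems <- sprintf("tract%02d", seq_len(n_pairs))
  tract_set(
    c(paste0(stems, "_L"), paste0(stems, "_R"),
      paste0("cross", seq_len(n_cross))),
    c(rep("left", n_pairs), rep("right", n_pairs), rep("cross", n_cross))
  )
}

#' @export
length.tract_set <- function(x) length(x$names)

#' @export
print.tract_set <- function(x, ...) {
  cat("tract_set with", length(x$names), "tracts (",
      sum(x$hemisphere == "left"), "left,",
      sum(x$hemisphere == "right"), "right,",
      sum(x$hemisphere == "cross"), "cross )\n")
  cat(" ", paste(utils::head(x$names, 8L), collapse = ", "),
      if (length(x$names) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Test whether two tract sets are identical
#'
#' @param a,b `tract_set` objects.
#' @return `TRUE` if both have the same tract names in the same order.
#' @export
same_tract_set <- function(a, b) {
  identical(a$names, b$names)
}

# Stop with a message naming the first differing tract.
.check_tracts_match <- function(a, b, what = "blueprints") {
  if (length(a$names) != length(b$names))
    stop(what, " have tract sets of different size (",
         length(a$names), " vs ", length(b$names), ")")
  if (!identical(a$names, b$names)) {
    i <- which(a$names != b$names)[1L]
    stop(what, " have mismatched tract sets; first difference at position ",
         i, ": '", a$names[i], "' vs '", b$names[i], "'")
  }
  invisible(TRUE)
}
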