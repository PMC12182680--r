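#' Forest typology
#'
#' The set of forest type codes used across a study, the non-forest code, and
#' an optional mapping from fine sub-types (e.g. type x climate-zone
#' combinations) to primary types used for model fitting. The mapping is a
#' configuration input, not hard-coded: national studies typically aggregate
#' several dozen sub-types into 10-20 primary types to keep per-type sample
#' sizes workable.
#'
#' @param codes Integer vector of forest type codes (distinct, not containing
#'   `non_forest`).
#' @param labels Optional character labels, same length as `codes`.
#' @param non_forest Integer code for non-forest cells (default 0).
#' @param sub_to_primary Optional named integer vector mapping sub-type codes
#'   (names) to primary codes (values); every sub-type must map to exactly one
#'   primary code in `codes`.
#' @return An object of class `forest_typology`.
#' @examples
#' ty <- forest_typology(1:5, labels = c("ENF", "DNF", "EBF", "DBF", "MF"))
#' is_forest_code(c(0, 3), ty)
#' @export
forest_typology <- function(codes, labels = NULL, non_forest = 0L,
                            sub_to_primary = NULL) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes) || any(is.na(codes)))
    stop("typology error: codes must be distinct and non-missing")
  if (non_forest %in% codes)
    stop("typology error: non-forest code collides with a forest code")
  if (is.null(labels)) labels <- paste0("T", codes)
  if (length(labels) != length(codes))
    stop("typology error: labels must match codes in length")
  if (!is.null(sub_to_primary)) {
    if (is.null(names(sub_to_primary)))
      stop("typology error: sub_to_primary must be named by sub-type code")
    if (!all(sub_to_primary %in% codes))
      stop("typology error: sub_to_primary maps to unknown primary codes")
  }
  structure(list(codes = codes, labels = labels,
                 non_forest = as.integer(non_forest),
                 sub_to_primary = sub_to_primary),
            class = "forest_typology")
}

#' @export
print.forest_typology <- function(x, ...) {
  cat(sprintf("forest_typology: %d types (%s), non-forest = %d\n",
              length(x$codes), paste(x$labels, collapse = ", "),
              x$non_forest))
  invisible(x)
}

#' Test whether codes are forest codes
#' @param x Integer vector of codes.
#' @param typology A [forest_typology()].
#' @return Logical vector.
#' @export
is_forest_code <- function(x, typology) {
  x %in% typology$codes
}
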