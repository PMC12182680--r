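#' Fuse three forest cover products into one baseline map
#'
#' Combines three categorical cover products, ranked by reliability, into a
#' single map using sequential criteria: (1) if at least two products agree on
#' a FOREST type for a pixel, that type is adopted; (2) otherwise the rank-1
#' product's code is used if it is a forest code; (3) otherwise the rank-2
#' product's code if forest; (4) otherwise the rank-3 product's code.
#' A pixel on which two (or three) products agree that it is non-forest but
#' the remaining products disagree therefore still falls through the
#' rank cascade: agreement counts only for forest codes.
#'
#' @param p1,p2,p3 Integer matrices of cover codes, rank 1 (most reliable) to
#'   rank 3. Must share dimensions.
#' @param non_forest Integer non-forest code (default 0).
#' @param typology Optional [forest_typology()]; when supplied, every code in
#'   the inputs must be a known forest code or `non_forest`.
#' @return Integer matrix of fused codes.
#' @examples
#' fuse_cover(matrix(1L), matrix(1L), matrix(4L))  # majority -> 1
#' fuse_cover(matrix(0L), matrix(0L), matrix(3L))  # both NF -> rank 3
#' @export
fuse_cover <- function(p1, p2, p3, non_forest = 0L, typology = NULL) {
  if (!all(dim(p1) == dim(p2)) || !all(dim(p1) == dim(p3)))
    stop("shape error: cover products must share grid dimensions")
  if (anyNA(p1) || anyNA(p2) || anyNA(p3))
    stop("typology error: cover products must use explicit codes, not NA")
  if (!is.null(typology)) {
    known <- c(typology$codes, typology$non_forest)
    bad <- setdiff(unique(c(p1, p2, p3)), known)
    if (length(bad))
      stop("typology error: unknown cover code(s) ", paste(bad, collapse = ", "))
    non_forest <- typology$non_forest
  }
  v1 <- as.integer(p1); v2 <- as.integer(p2); v3 <- as.integer(p3)
  f1 <- v1 != non_forest; f2 <- v2 != non_forest; f3 <- v3 != non_forest
  out <- integer(length(v1))
  # criterion 1: two products agree on a forest type
  m12 <- v1 == v2 & f1
  m13 <- v1 == v3 & f1
  m23 <- v2 == v3 & f2
  done <- m12 | m13 | m23
  out[m23] <- v2[m23]
  out[m12 | m13] <- v1[m12 | m13]      # overlaps agree by construction
  # criteria 2-4: rank cascade
  rest <- !done
  use1 <- rest & f1
  use2 <- rest & !f1 & f2
  use3 <- rest & !f1 & !f2
  out[use1] <- v1[use1]
  out[use2] <- v2[use2]
  out[use3] <- v3[use3]
  matrix(out, nrow = nrow(p1), ncol = ncol(p1))
}

#' Fuse three stand-age products into one baseline age map
#'
#' Priority fill within the forest mask: the rank-1 product's age where
#' available, else the rank-2 product's, else the rank-3 product's age plus
#' its epoch offset (default +10 years, for a product mapped a decade before
#' the baseline year). Pixels where all three products are null are filled
#' with the median fused age of same-type pixels (or the overall median when
#' no type raster is given) and reported via a warning. Outside the mask the
#' result is `NA`.
#'
#' @param a1,a2,a3 Numeric matrices of stand ages (years); `NA` marks null.
#' @param mask Logical matrix: `TRUE` where the fused cover map says forest.
#' @param offsets Numeric length-3 vector of epoch offsets added to each
#'   product's ages on use (default `c(0, 0, 10)`).
#' @param types Optional integer matrix of fused cover codes used for the
#'   typology-level median fallback.
#' @return Numeric matrix of fused ages; `NA` outside `mask`.
#' @examples
#' a1 <- matrix(c(35, NA, NA, NA), 2)
#' a2 <- matrix(c(NA, 7, NA, NA), 2)
#' a3 <- matrix(c(NA, NA, 12, NA), 2)
#' suppressWarnings(fuse_age(a1, a2, a3, matrix(TRUE, 2, 2)))
#' @export
fuse_age <- function(a1, a2, a3, mask, offsets = c(0, 0, 10), types = NULL) {
  if (!all(dim(a1) == dim(a2)) || !all(dim(a1) == dim(a3)) ||
      !all(dim(a1) == dim(mask)))
    stop("shape error: age products and mask must share grid dimensions")
  if (length(offsets) != 3 || any(offsets < 0))
    stop("configuration error: offsets must be three non-negative years")
  if (any(a1 < 0, na.rm = TRUE) || any(a2 < 0, na.rm = TRUE) ||
      any(a3 < 0, na.rm = TRUE))
    stop("data error: non-null stand ages must be >= 0")
  out <- a1 + offsets[1]
  i <- is.na(out)
  out[i] <- a2[i] + offsets[2]
  i <- is.na(out)
  out[i] <- a3[i] + offsets[3]
  hole <- is.na(out) & mask
  if (any(hole)) {
    if (!is.null(types)) {
      for (ty in unique(types[hole])) {
        sel <- hole & types == ty
        med <- stats::median(out[mask & !is.na(out) & types == ty])
        if (is.na(med)) med <- stats::median(out[mask], na.rm = TRUE)
        out[sel] <- med
      }
    } else {
      out[hole] <- stats::median(out[mask], na.rm = TRUE)
    }
    warning(sprintf(
      "fuse_age: %d pixel(s) null in all three products; filled with median age",
      sum(hole)))
  }
  out[!mask] <- NA_real_
  out
}

#' Forest mask from fractional tree cover
#'
#' A cell counts as forest when its tree cover meets or exceeds the threshold
#' (inclusive, default 20 percent).
#'
#' @param tree_cover Numeric matrix of tree-cover fractions (unit "fraction",
#'   values in `[0, 1]`) or percentages (unit "percent", values in `[0, 100]`).
#' @param threshold Threshold as a fraction (default 0.20).
#' @param unit Declared unit of `tree_cover`.
#' @return Logical matrix.
#' @examples
#' forest_mask(matrix(c(0.199, 0.2), 1))
#' @export
forest_mask <- function(tree_cover, threshold = 0.20,
                        unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  tc <- tree_cover
  if (unit == "percent") tc <- tc / 100
  if (any(tc < 0 | tc > 1, na.rm = TRUE))
    stop("data error: tree cover outside declared range")
  tc >= threshold
}
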