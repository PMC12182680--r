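#' Greedy pruning of highly correlated environmental variables
#'
#' Reduces an environmental-variable matrix to a subset with pairwise Pearson
#' `|r|` at or below the threshold, the standard collinearity screen before
#' fitting species distribution models. Removal is greedy: the variable with
#' the largest number of above-threshold partners is dropped first; ties are
#' broken by larger mean `|r|` against the remaining variables, then by name
#' order.
#'
#' @param env Numeric matrix or data frame, variables in columns (named),
#'   locations in rows. At least 2 variables and 3 locations.
#' @param threshold Maximum allowed pairwise `|r|` (default 0.8).
#' @return Character vector of retained variable names (in original column
#'   order).
#' @examples
#' set.seed(1)
#' e <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
#' prune_correlated(cbind(e, x2 = e[, "x"]))
#' @export
prune_correlated <- function(env, threshold = 0.8) {
  env <- as.matrix(env)
  if (is.null(colnames(env)))
    colnames(env) <- paste0("V", seq_len(ncol(env)))
  if (ncol(env) < 2 || nrow(env) < 3)
    stop("data error: need >= 2 variables and >= 3 locations")
  if (any(!is.finite(env))) stop("data error: non-finite values in env matrix")
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0))
    stop("data error: constant column(s): ",
         paste(colnames(env)[sds == 0], collapse = ", "))
  keep <- colnames(env)
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(env[, keep, drop = FALSE]))
    diag(cm) <- 0
    counts <- rowSums(cm > threshold)
    if (max(counts) == 0) break
    cand <- names(counts)[counts == max(counts)]
    if (length(cand) > 1) {
      mr <- rowMeans(cm)[cand]
      cand <- cand[mr == max(mr)]
      cand <- sort(cand)[1]
    }
    keep <- setdiff(keep, cand[1])
  }
  intersect(colnames(env), keep)
}

#' Suitability decision at a threshold
#'
#' A pixel is suitable for a forest type when its suitability probability
#' strictly exceeds the type's MTSS threshold (maximum training sensitivity
#' plus specificity).
#'
#' @param p Suitability probability in `[0, 1]`.
#' @param mtss Threshold in `(0, 1)`.
#' @return Logical, same length as `p`.
#' @export
is_suitable <- function(p, mtss) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("data error: suitability probabilities must lie in [0, 1]")
  if (any(mtss <= 0 | mtss >= 1))
    stop("data error: MTSS thresholds must lie in (0, 1)")
  p > mtss
}

#' Most suitable qualifying forest type
#'
#' Among the types whose suitability strictly exceeds their MTSS threshold,
#' returns the one with the highest probability; `NA` if no type qualifies.
#' Exact ties are broken by typology code order (numeric where the codes are
#' numeric), so the result is deterministic.
#'
#' @param p_by_type Named numeric vector of suitability probabilities, one
#'   per type code.
#' @param mtss_by_type Named numeric vector of thresholds, same key set.
#' @return The winning type code (character, a name of `p_by_type`), or
#'   `NA_character_`.
#' @examples
#' best_type(c(`1` = 0.7, `2` = 0.9), c(`1` = 0.5, `2` = 0.95))
#' @export
best_type <- function(p_by_type, mtss_by_type) {
  if (!setequal(names(p_by_type), names(mtss_by_type)))
    stop("configuration error: type keys of p and mtss differ")
  mtss_by_type <- mtss_by_type[names(p_by_type)]
  ok <- is_suitable(p_by_type, mtss_by_type)
  if (!any(ok)) return(NA_character_)
  cand <- names(p_by_type)[ok & p_by_type == max(p_by_type[ok])]
  num <- suppressWarnings(as.numeric(cand))
  if (!anyNA(num)) cand[order(num)][1] else sort(cand)[1]
}
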