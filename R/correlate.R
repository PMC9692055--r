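#' Spearman rank correlation with average ranks
#'
#' The Pearson correlation of the rank-transformed variables, with ties
#' receiving average ranks.  Because it depends only on ranks, the result
#' is invariant under strictly monotone transforms of either argument —
#' the property that makes it the right summary when only the ordering of
#' learning efforts is meaningful.
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' spearman(1:3, c(10, 20, 30))  # 1
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed",
                                 call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined: a variable has zero rank variance",
         call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Per-LOT rank correlations between complexity and learning effort
#'
#' Joins each LOT's complexity profile with the per-category mean efforts
#' and computes Spearman's rho per LOT.  Records are sorted by descending
#' rho with ties broken by `lot_id`, the ordering used by the cumulative
#' operator-occurrence summaries.
#'
#' @param profiles List of [minimal_profile()] objects (one per LOT).
#' @param efforts Data frame with columns `category` (bit string) and
#'   `mean_effort`, e.g. from [effort_table()] or [surrogate_efforts()].
#' @param allow_subset If `FALSE` (default), every profile category must
#'   be present in `efforts`, otherwise a join error is raised; if `TRUE`
#'   the intersection is used with a warning (for partial runs).
#' @return Data frame of class `rho_table` with columns `lot_id`,
#'   `operators`, `n_operators`, `has_parity`, `n_categories`, `rho`.
#' @export
lot_rho_table <- function(profiles, efforts, allow_subset = FALSE) {
  if (length(profiles) == 0L) stop("no profiles given", call. = FALSE)
  ok <- vapply(profiles, inherits, logical(1), what = "complexity_profile")
  if (!all(ok)) stop("all elements must be complexity profiles", call. = FALSE)
  if (!is.data.frame(efforts) ||
      !all(c("category", "mean_effort") %in% names(efforts))) {
    stop("`efforts` must have columns 'category' and 'mean_effort'",
         call. = FALSE)
  }
  if (anyDuplicated(efforts$category)) {
    stop("duplicate categories in effort table", call. = FALSE)
  }

  rows <- lapply(profiles, function(p) {
    cats <- names(p$lengths)
    missing <- setdiff(cats, efforts$category)
    use <- cats
    if (length(missing) > 0L) {
      if (!allow_subset) {
        stop(sprintf("effort table lacks %d of the %d categories of LOT %s (use allow_subset = TRUE to intersect)",
                     length(missing), length(cats), p$lot_id), call. = FALSE)
      }
      use <- intersect(cats, efforts$category)
      warning(sprintf("LOT %s: correlating over %d of %d categories",
                      p$lot_id, length(use), length(cats)), call. = FALSE)
    }
    eff <- efforts$mean_effort[match(use, efforts$category)]
    data.frame(lot_id = p$lot_id,
               operators = paste(p$operators, collapse = "+"),
               n_operators = length(p$operators),
               has_parity = has_parity(p$operators),
               n_categories = length(use),
               rho = spearman(p$lengths[use], eff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rho, out$lot_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rho_table", "data.frame")
  out
}

#' Cumulative operator occurrences down the rho ordering
#'
#' For records sorted by descending rho, `curve[k, op]` is the number of
#' the top-k LOTs that contain `op`.  In the study the parity-operator
#' curves stay flat until the sharp drop in rho, visualising that parity
#' operators drive the weak-correlation regime.
#'
#' @param records A `rho_table` (must already be sorted by descending
#'   rho; [lot_rho_table()] output is).
#' @return Integer matrix with one row per rank k and one column per
#'   operator; each column is non-decreasing and ends at the operator's
#'   total occurrence count.
#' @export
cumulative_operator_counts <- function(records) {
  check_rho_table(records)
  if (is.unsorted(-records$rho)) {
    stop("records must be sorted by descending rho", call. = FALSE)
  }
  oplists <- strsplit(records$operators, "+", fixed = TRUE)
  ind <- vapply(OP_NAMES, function(op) {
    vapply(oplists, function(ops) op %in% ops, logical(1)) * 1L
  }, integer(nrow(records)))
  ind <- matrix(ind, nrow = nrow(records),
                dimnames = list(NULL, OP_NAMES))
  res <- apply(ind, 2L, cumsum)
  if (is.null(dim(res))) {          # single-record input
    res <- matrix(res, nrow = 1L, dimnames = list(NULL, OP_NAMES))
  }
  res
}

check_rho_table <- function(records) {
  need <- c("lot_id", "operators", "n_operators", "has_parity", "rho")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must be a rho table (see lot_rho_table)", call. = FALSE)
  }
  invisible(records)
}

#' Summarise rho by presence of parity operators
#'
#' @param records A `rho_table`.
#' @return Data frame with one row per group (`has_parity` FALSE/TRUE)
#'   and columns `n_lots`, `mean_rho`, `min_rho`, `max_rho`.  An empty
#'   group yields a row of `NA`s with `n_lots = 0`.
#' @export
parity_split <- function(records) {
  check_rho_table(records)
  out <- lapply(c(FALSE, TRUE), function(p) {
    r <- records$rho[records$has_parity == p]
    if (length(r) == 0L) {
      data.frame(has_parity = p, n_lots = 0L, mean_rho = NA_real_,
                 min_rho = NA_real_, max_rho = NA_real_)
    } else {
      data.frame(has_parity = p, n_lots = length(r), mean_rho = mean(r),
                 min_rho = min(r), max_rho = max(r))
    }
  })
  do.call(rbind, out)
}

#' Operator counts along the rho ordering
#'
#' @param records A `rho_table` sorted by descending rho.
#' @return List with `n_operators` (the per-rank operator-count
#'   sequence), `max_without_parity` and `max_with_parity` (NA when the
#'   group is empty).
#' @export
operators_per_lot_curve <- function(records) {
  check_rho_table(records)
  if (is.unsorted(-records$rho)) {
    stop("records must be sorted by descending rho", call. = FALSE)
  }
  wo <- records$n_operators[!records$has_parity]
  wi <- records$n_operators[records$has_parity]
  list(n_operators = records$n_operators,
       max_without_parity = if (length(wo)) max(wo) else NA_integer_,
       max_with_parity = if (length(wi)) max(wi) else NA_integer_)
}
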