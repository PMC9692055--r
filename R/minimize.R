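#' Construct formulas
#'
#' A formula is a rooted tree whose leaves are property literals and whose
#' internal nodes are operator applications with arity-matching children.
#' `lit(i)` makes the literal for property `i`; `fml(name, ...)` applies an
#' operator to child formulas.
#'
#' @param i Property index (1-based).
#' @param name Operator name (see [candidate_operators()]).
#' @param ... Child formulas (one for `not`, two for binary operators).
#' @return An object of class `lot_formula`.
#' @examples
#' f <- fml("nand", lit(1), fml("nand", lit(1), lit(1)))
#' formula_length(f)                 # 5
#' render_category(truth_table(f, 2), 2)  # "1111"
#' @export
lit <- function(i) {
  if (length(i) != 1L || is.na(i) || i < 1L || i != floor(i)) {
    stop("literal index must be a positive integer", call. = FALSE)
  }
  structure(list(var = as.integer(i)), class = "lot_formula")
}

#' @rdname lit
#' @export
fml <- function(name, ...) {
  name <- match.arg(name, OP_NAMES)
  args <- list(...)
  if (length(args) != OP_ARITY[[name]]) {
    stop(sprintf("'%s' takes %d argument(s), got %d",
                 name, OP_ARITY[[name]], length(args)), call. = FALSE)
  }
  ok <- vapply(args, inherits, logical(1), what = "lot_formula")
  if (!all(ok)) stop("all children must be formulas", call. = FALSE)
  structure(list(op = name, args = args), class = "lot_formula")
}

#' @export
format.lot_formula <- function(x, ...) {
  if (!is.null(x$var)) return(paste0("p", x$var))
  paste0(x$op, "(",
         paste(vapply(x$args, format, character(1)), collapse = ","), ")")
}

#' @export
print.lot_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Truth table of a formula
#'
#' Evaluates a formula over all `2^n` assignments at once via bitwise
#' operations on truth-table masks.
#'
#' @param f A `lot_formula`.
#' @param n Number of properties (all literal indices in `f` must be
#'   `<= n`).
#' @return Integer category mask.
#' @export
truth_table <- function(f, n) {
  n <- check_n(n)
  eval_node <- function(node) {
    if (!is.null(node$var)) {
      if (node$var > n) {
        stop(sprintf("literal p%d out of range for n = %d", node$var, n),
             call. = FALSE)
      }
      return(literal_table(node$var, n))
    }
    if (is.null(node$op) || is.null(node$args)) {
      stop("malformed formula node", call. = FALSE)
    }
    kids <- lapply(node$args, eval_node)
    if (OP_ARITY[[node$op]] == 1L) {
      apply_op_mask(node$op, kids[[1]], n = n)
    } else {
      apply_op_mask(node$op, kids[[1]], kids[[2]], n = n)
    }
  }
  if (!inherits(f, "lot_formula")) stop("`f` must be a lot_formula",
                                        call. = FALSE)
  eval_node(unclass(f))
}

#' Length of a formula
#'
#' The complexity metric is the total parse-tree node count: operator
#' applications plus literal occurrences.  `nand(p,q)` has length 3.
#'
#' @param f A `lot_formula`.
#' @return Positive integer.
#' @export
formula_length <- function(f) {
  count <- function(node) {
    if (!is.null(node$var)) return(1L)
    1L + sum(vapply(node$args, count, integer(1)))
  }
  if (!inherits(f, "lot_formula")) stop("`f` must be a lot_formula",
                                        call. = FALSE)
  count(unclass(f))
}

#' Minimal formula lengths for every category in an LOT
#'
#' Computes, for a functionally complete LOT, the length of the shortest
#' formula (parse-tree node count) realising each of the `2^(2^n)`
#' categories.  A size-ordered dynamic program over truth tables starts
#' from the literal tables at size 1 and, for each size in ascending
#' order, applies the unary operator to tables of the previous size and
#' the binary operators to all ordered pairs of tables whose sizes sum to
#' one less; the first size at which a table appears is its minimal
#' length, so no relaxation is needed.
#'
#' @param lot Character vector of operator names; must pass
#'   [is_complete()].
#' @param n Number of properties (1-4; the study domain uses 4).
#' @param cap Safety cap on formula size; reaching it without covering all
#'   categories is an error (it indicates a bug or an incomplete LOT, not
#'   a deep search).
#' @param metric Length metric: `"nodes"` (default) counts operator
#'   applications plus literal occurrences, so `nand(p,q)` has length 3
#'   and a bare literal has length 1; `"ops"` counts operator
#'   applications only, so a literal has length 0.  For LOTs without the
#'   unary `not` the two are linked by `nodes = 2 * ops + 1` and induce
#'   the same ranking; with `not` they can differ.  The operator-count
#'   metric is the one that reproduces the reported maximum of 26 for
#'   the nand-only LOT over all four-property categories (the node-count
#'   maximum of the same witness trees is 53).
#' @return An object of class `complexity_profile`: a list with `lot_id`,
#'   `n`, `lengths` (integer vector of length `2^(2^n)`, indexed by
#'   category mask + 1, named by category string) and `max_length`.
#'   Provenance for witness reconstruction is kept in an attribute.
#' @examples
#' pr <- minimal_profile("nand", 2)
#' pr$lengths[["0011"]]  # 3, i.e. nand(p1,p1)
#' @export
minimal_profile <- function(lot, n, cap = 64L, metric = c("nodes", "ops")) {
  lot <- check_ops(lot)
  n <- check_n(n)
  metric <- match.arg(metric)
  if (!is_complete(lot)) {
    stop(sprintf("LOT {%s} is not functionally complete; minimal lengths are undefined for some categories",
                 paste(lot, collapse = ", ")), call. = FALSE)
  }
  codes <- match(lot, OP_NAMES)
  # canonical operator order drives the deterministic witness tie-break
  codes <- sort(codes)
  res <- cpp_minimal_profile(as.integer(codes), n, as.integer(cap),
                             if (metric == "nodes") 1L else 0L)
  if (res$n_assigned < 2L^(2L^n)) {
    stop(sprintf("search cap %d reached with %d/%d categories assigned",
                 cap, res$n_assigned, 2L^(2L^n)), call. = FALSE)
  }
  lengths <- res$lengths
  names(lengths) <- render_category(seq_along(lengths) - 1L, n)
  out <- structure(list(lot_id = lot_id(lot), operators = sort(lot), n = n,
                        metric = metric, lengths = lengths,
                        max_length = max(lengths)),
                   class = "complexity_profile")
  attr(out, "prov") <- list(op = res$prov_op, left = res$prov_left,
                            right = res$prov_right)
  out
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat(sprintf("Complexity profile for LOT {%s} at n = %d\n",
              paste(x$operators, collapse = ", "), x$n))
  cat(sprintf("  %d categories, minimal lengths %d..%d\n",
              length(x$lengths), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Witness minimal formula for one category
#'
#' Reconstructs a shortest formula for a category from the dynamic
#' program's provenance.  Among equal-length formulas the witness is the
#' first one generated under a fixed iteration order (operators in
#' canonical order, subformula sizes ascending, left before right, truth
#' tables ascending), so the result is reproducible.
#'
#' @param lot Character vector of operator names (complete LOT).
#' @param category Category as a bit string or integer mask.
#' @param n Number of properties.
#' @param profile Optional precomputed [minimal_profile()] for `lot`,
#'   to avoid recomputation.
#' @return A `lot_formula` whose [truth_table()] equals the category and
#'   whose [formula_length()] equals the profile entry.
#' @examples
#' f <- minimal_formula("nand", "0111", 2)
#' format(f)  # "nand(p1,p2)"
#' @export
minimal_formula <- function(lot, category, n, profile = NULL) {
  n <- check_n(n)
  mask <- if (is.character(category)) parse_category(category, n)
          else as.integer(category)
  if (is.null(profile)) profile <- minimal_profile(lot, n)
  if (!inherits(profile, "complexity_profile") ||
      profile$lot_id != lot_id(lot) || profile$n != n) {
    stop("`profile` does not match `lot` and `n`", call. = FALSE)
  }
  prov <- attr(profile, "prov")
  build <- function(m) {
    idx <- m + 1L
    op <- prov$op[idx]
    if (op < 0L) return(lit(-op))
    name <- OP_NAMES[op]
    if (OP_ARITY[[name]] == 1L) {
      fml(name, build(prov$left[idx]))
    } else {
      fml(name, build(prov$left[idx]), build(prov$right[idx]))
    }
  }
  build(mask)
}

#' Count distinct complexity profiles
#'
#' Two LOTs with identical minimal-length vectors over all categories make
#' identical predictions under the minimal-formula assumption; this counts
#' the distinct vectors under exact equality.
#'
#' @param profiles List of [minimal_profile()] results sharing one `n`.
#' @return Integer: number of distinct length vectors.
#' @export
profile_dedup <- function(profiles) {
  if (length(profiles) == 0L) return(0L)
  ok <- vapply(profiles, inherits, logical(1), what = "complexity_profile")
  if (!all(ok)) stop("all elements must be complexity profiles", call. = FALSE)
  ns <- vapply(profiles, function(p) p$n, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("profiles computed at different n cannot be compared", call. = FALSE)
  }
  keys <- vapply(profiles, function(p) paste(p$lengths, collapse = ","),
                 character(1))
  length(unique(keys))
}
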