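# The nine candidate connectives, in canonical order.  Constants,
# affirmations, the (negated) projections and the left-pointing
# conditionals are excluded from the universe: they never shorten a
# minimal formula relative to this set.
OP_NAMES <- c("and", "or", "cond", "ncond", "bicond", "nbicond",
              "nand", "nor", "not")
OP_ARITY <- c(and = 2L, or = 2L, cond = 2L, ncond = 2L, bicond = 2L,
              nbicond = 2L, nand = 2L, nor = 2L, not = 1L)
OP_SYMBOL <- c(and = "∧", or = "∨", cond = "→",
               ncond = "↛", bicond = "↔", nbicond = "↮",
               nand = "⊼", nor = "⊽", not = "¬")
PARITY_OPS <- c("bicond", "nbicond")

#' The candidate operator set
#'
#' The nine unary/binary connectives from which languages of thought
#' (LOTs) are assembled: conjunction, disjunction, the material
#' conditional and its negation, the biconditional and its negation (the
#' parity operators, i.e. XNOR and XOR), negated conjunction (nand,
#' Sheffer stroke), negated disjunction (nor, Peirce arrow), and negation.
#'
#' @return A data frame with columns `name`, `arity` and `symbol`, one row
#'   per operator, in canonical order.
#' @export
candidate_operators <- function() {
  data.frame(name = OP_NAMES,
             arity = unname(OP_ARITY[OP_NAMES]),
             symbol = unname(OP_SYMBOL[OP_NAMES]),
             stringsAsFactors = FALSE)
}

#' Apply an operator to truth values
#'
#' Evaluates one of the nine connectives on scalar (or vectorised) truth
#' values.  Unary `not` ignores `y`.
#'
#' @param name Operator name, one of `candidate_operators()$name`.
#' @param x,y Logical inputs (`y` omitted for `not`).
#' @return Logical result.
#' @examples
#' op_truth("nand", TRUE, TRUE)   # FALSE
#' op_truth("nbicond", TRUE, FALSE) # TRUE (XOR)
#' @export
op_truth <- function(name, x, y = NULL) {
  name <- match.arg(name, OP_NAMES)
  if (OP_ARITY[[name]] == 1L) {
    return(!x)
  }
  if (is.null(y)) stop(sprintf("'%s' is binary; `y` is required", name),
                       call. = FALSE)
  switch(name,
         and     = x & y,
         or      = x | y,
         cond    = !x | y,
         ncond   = x & !y,
         bicond  = x == y,
         nbicond = xor(x, y),
         nand    = !(x & y),
         nor     = !(x | y))
}

# Bitwise operator application on 2^n-bit truth-table masks.
apply_op_mask <- function(name, a, b = NULL, n) {
  full <- 2L^(2L^n) - 1L
  switch(name,
         and     = bitwAnd(a, b),
         or      = bitwOr(a, b),
         cond    = bitwOr(bitwAnd(bitwNot(a), full), b),
         ncond   = bitwAnd(a, bitwAnd(bitwNot(b), full)),
         bicond  = bitwAnd(bitwNot(bitwXor(a, b)), full),
         nbicond = bitwXor(a, b),
         nand    = bitwAnd(bitwNot(bitwAnd(a, b)), full),
         nor     = bitwAnd(bitwNot(bitwOr(a, b)), full),
         not     = bitwAnd(bitwNot(a), full),
         stop(sprintf("unknown operator '%s'", name), call. = FALSE))
}

#' Canonical identifier of an operator set
#'
#' @param ops Character vector of operator names (possibly empty).
#' @return A single string: the sorted names joined by `"+"`; `"empty"`
#'   for the empty set.
#' @export
lot_id <- function(ops) {
  ops <- check_ops(ops, allow_empty = TRUE)
  if (length(ops) == 0L) return("empty")
  paste(sort(ops), collapse = "+")
}

check_ops <- function(ops, allow_empty = FALSE) {
  if (length(ops) == 0L) {
    if (allow_empty) return(character(0))
    stop("operator set must be non-empty", call. = FALSE)
  }
  if (!is.character(ops)) stop("operators must be given by name", call. = FALSE)
  bad <- setdiff(ops, OP_NAMES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown operator(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(ops)) stop("duplicate operators in set", call. = FALSE)
  ops
}

#' Enumerate all candidate LOTs
#'
#' Every subset of the nine candidate operators is a candidate language of
#' thought; there are `2^9 = 512`, including the empty set (which is
#' trivially incomplete and removed by [complete_lots()]).
#'
#' @return A named list of 512 character vectors of operator names; names
#'   are the canonical [lot_id()]s, in lexicographic id order.
#' @export
all_lots <- function() {
  subsets <- vector("list", 512L)
  for (code in 0:511) {
    subsets[[code + 1L]] <- OP_NAMES[bitwAnd(code, 2L^(0:8)) != 0L]
  }
  ids <- vapply(subsets, lot_id, character(1))
  subsets <- subsets[order(ids)]
  names(subsets) <- sort(ids)
  subsets
}

# Post clone membership per operator.  A set of operators is functionally
# complete (with projections/literals available, constants not) iff for
# each of the five maximal clones it contains at least one operator
# outside the clone.
op_clone_table <- function() {
  arity <- OP_ARITY
  inputs2 <- expand.grid(x = c(FALSE, TRUE), y = c(FALSE, TRUE))
  memb <- matrix(NA, nrow = 9L, ncol = 5L,
                 dimnames = list(OP_NAMES,
                                 c("zero", "one", "monotone", "selfdual",
                                   "affine")))
  for (op in OP_NAMES) {
    if (arity[[op]] == 1L) {
      f <- function(x, y = NULL) op_truth(op, x)
      tab <- f(c(FALSE, TRUE))
      memb[op, "zero"] <- !tab[1]
      memb[op, "one"] <- tab[2]
      memb[op, "monotone"] <- tab[1] <= tab[2]
      memb[op, "selfdual"] <- all(f(!c(FALSE, TRUE)) == !tab)
      # unary affine: f = c XOR a*x for a,c in {0,1}; always true for
      # identity/negation/constants
      memb[op, "affine"] <- TRUE
    } else {
      f <- function(x, y) op_truth(op, x, y)
      tab <- f(inputs2$x, inputs2$y)
      memb[op, "zero"] <- !tab[1]                       # f(0,0) = 0
      memb[op, "one"] <- tab[4]                         # f(1,1) = 1
      mono <- TRUE
      for (i in 1:4) for (j in 1:4) {
        if (inputs2$x[i] <= inputs2$x[j] && inputs2$y[i] <= inputs2$y[j] &&
            tab[i] > tab[j]) mono <- FALSE
      }
      memb[op, "monotone"] <- mono
      memb[op, "selfdual"] <- all(f(!inputs2$x, !inputs2$y) == !tab)
      # binary affine: f(x,y) = c XOR a*x XOR b*y; fit on three points,
      # check the fourth
      cc <- tab[1]; a <- xor(tab[2], cc); b <- xor(tab[3], cc)
      pred <- xor(xor(cc, a & inputs2$x), b & inputs2$y)
      memb[op, "affine"] <- all(pred == tab)
    }
  }
  memb
}

#' Functional completeness of an operator set
#'
#' An LOT is functionally complete (a Boolean basis) when every category
#' over the properties is the truth table of some formula built from
#' property literals and the LOT's operators.  Decided by Post's
#' criterion: the set is complete iff it is not contained in any of the
#' five maximal clones (0-preserving, 1-preserving, monotone, self-dual,
#' affine).  Constants are not assumed available; literals are
#' projections, which belong to every clone and so never affect the test.
#'
#' @param ops Character vector of operator names (may be empty: the empty
#'   set is incomplete).
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_complete("nand")            # TRUE (Sheffer stroke)
#' is_complete(c("and", "or"))    # FALSE (monotone clone)
#' @export
is_complete <- function(ops) {
  ops <- check_ops(ops, allow_empty = TRUE)
  if (length(ops) == 0L) return(FALSE)
  memb <- clone_membership_cache()
  all(colSums(!memb[ops, , drop = FALSE]) > 0L)
}

clone_cache_env <- new.env(parent = emptyenv())
clone_membership_cache <- function() {
  if (is.null(clone_cache_env$memb)) clone_cache_env$memb <- op_clone_table()
  clone_cache_env$memb
}

#' All functionally complete LOTs
#'
#' Filters the 512 candidate operator subsets with [is_complete()].
#'
#' @return Named list of operator-name vectors (one per complete LOT),
#'   ordered by canonical id.  There are 468.
#' @export
complete_lots <- function() {
  lots <- all_lots()
  lots[vapply(lots, is_complete, logical(1))]
}

#' Does an LOT contain a parity operator?
#'
#' The parity operators are the biconditional (XNOR) and the negated
#' biconditional (XOR); categories compactly expressible with them tend to
#' be nonlinearly separable.
#'
#' @param ops Character vector of operator names.
#' @return `TRUE` iff `ops` contains `bicond` or `nbicond`.
#' @export
has_parity <- function(ops) {
  ops <- check_ops(ops, allow_empty = TRUE)
  any(PARITY_OPS %in% ops)
}
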