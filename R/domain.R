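#' Enumerate the property assignments for an n-property domain
#'
#' An object is an assignment of truth values to the `n` binary properties
#' `p1..pn`.  The assignment order is fixed package-wide and matches the
#' left-to-right reading of category strings: index 1 is the all-true
#' assignment, the last index is the all-false assignment, and `p1` is the
#' most significant property.  For `n = 2` the order is
#' (T,T), (T,F), (F,T), (F,F).
#'
#' @param n Number of binary properties (`n >= 1`).
#' @return A `2^n` by `n` logical matrix; row `i` is the i-th assignment,
#'   columns are named `p1..pn`.
#' @examples
#' assignments(2)
#' @export
assignments <- function(n) {
  n <- check_n(n)
  k <- 2L^n
  # row i encodes the binary digits of (2^n - i), p1 most significant
  vals <- k - seq_len(k)
  m <- matrix(FALSE, nrow = k, ncol = n,
              dimnames = list(NULL, paste0("p", seq_len(n))))
  for (j in seq_len(n)) {
    m[, j] <- bitwAnd(vals, 2L^(n - j)) != 0L
  }
  m
}

#' Number of categories definable with n properties
#'
#' With `n` binary properties there are `2^n` distinguishable objects and
#' one category per subset of objects, hence `2^(2^n)` categories.
#'
#' @param n Number of properties (`n >= 0`).
#' @return The category count `2^(2^n)` as a double (exact for `n <= 4`).
#' @examples
#' category_count(2) # 16
#' category_count(4) # 65536
#' @export
category_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  2^(2^n)
}

#' Parse a category bit-string into an integer truth-table mask
#'
#' A category over `n` properties is written as a `2^n`-character string of
#' 0s and 1s, character `i` giving membership of the object at assignment
#' index `i` (see [assignments()]).  Internally a category is the integer
#' whose binary numeral is that string, so the string form and the mask are
#' interconvertible without loss.
#'
#' @param s A `2^n`-character string over `{0,1}`.
#' @param n Number of properties.
#' @return An integer mask in `[0, 2^(2^n) - 1]`.
#' @seealso [render_category()] for the inverse.
#' @examples
#' parse_category("1100", 2) # the category "p"
#' @export
parse_category <- function(s, n) {
  n <- check_n(n)
  k <- 2L^n
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop("`s` must be a single string", call. = FALSE)
  }
  if (nchar(s) != k) {
    stop(sprintf("category string must have %d characters, got %d",
                 k, nchar(s)), call. = FALSE)
  }
  if (grepl("[^01]", s)) {
    stop("category string may only contain '0' and '1'", call. = FALSE)
  }
  strtoi(s, base = 2L)
}

#' Render a category mask as its bit-string form
#'
#' @param mask Integer mask (or vector of masks) in `[0, 2^(2^n) - 1]`.
#' @param n Number of properties.
#' @return Character vector of `2^n`-character bit strings.
#' @examples
#' render_category(12, 2) # "1100"
#' @export
render_category <- function(mask, n) {
  n <- check_n(n)
  k <- 2L^n
  if (any(is.na(mask)) || any(mask < 0) || any(mask > 2^k - 1)) {
    stop("mask out of range for this n", call. = FALSE)
  }
  # column j of the bit matrix is character j (most significant bit first)
  bits <- outer(as.numeric(mask), 2^((k - 1):0),
                function(m, p) (m %/% p) %% 2)
  apply(bits, 1L, paste, collapse = "")
}

#' Truth table of a single property literal
#'
#' @param i Property index in `1..n`.
#' @param n Number of properties.
#' @return Integer mask of the category containing exactly the objects for
#'   which property `i` is true.
#' @examples
#' render_category(literal_table(1, 2), 2) # "1100"
#' @export
literal_table <- function(i, n) {
  n <- check_n(n)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n || i != floor(i)) {
    stop(sprintf("property index must be in 1..%d", n), call. = FALSE)
  }
  k <- 2L^n
  vals <- k - seq_len(k)          # assignment encodings, index order
  bits <- as.integer(bitwAnd(vals, 2L^(n - as.integer(i))) != 0L)
  # character j of the string is bit (2^n - j) of the mask
  as.integer(sum(bits * 2^(k - seq_len(k))))
}

check_n <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1L || n != floor(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (n > 4L) {
    stop("domains with more than 4 properties are not supported", call. = FALSE)
  }
  as.integer(n)
}

#' All category masks for an n-property domain
#'
#' @param n Number of properties.
#' @return Integer vector `0:(2^(2^n) - 1)`.
#' @export
all_categories <- function(n) {
  n <- check_n(n)
  seq.int(0L, 2L^(2L^n) - 1L)
}
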