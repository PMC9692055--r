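# Independent oracles used to cross-check the package's fast paths.
# They deliberately use different algorithms (set closure to fixpoint,
# Bellman-Ford-style relaxation, raw tree enumeration) from the
# implementation they validate (Post's clone criterion, size-ordered DP).

# Truth-table application helper shared by the oracles (n = 2 only):
# precomputed 16 x 16 result matrix per binary operator, length-16 map
# for negation.
oracle_op_matrices <- function() {
  ops <- setdiff(lotlearn::candidate_operators()$name, "not")
  tabs <- 0:15
  mats <- lapply(ops, function(op) {
    outer(tabs, tabs, function(a, b) lotlearn:::apply_op_mask(op, a, b, n = 2))
  })
  names(mats) <- ops
  list(binary = mats,
       not = lotlearn:::apply_op_mask("not", tabs, n = 2))
}

# Brute-force completeness: close {p, q} under the operator set over the
# 16 two-property functions; complete iff the closure is everything.
closure_complete <- function(ops, mats = oracle_op_matrices()) {
  reach <- c(lotlearn::literal_table(1, 2), lotlearn::literal_table(2, 2))
  repeat {
    new <- reach
    for (op in ops) {
      if (op == "not") {
        new <- union(new, mats$not[reach + 1L])
      } else {
        new <- union(new, as.vector(mats$binary[[op]][reach + 1L, reach + 1L]))
      }
    }
    if (length(new) == length(reach)) break
    reach <- new
  }
  length(reach) == 16L
}

# Minimal lengths by relaxation to fixpoint: start from the literals and
# repeatedly relax every (operator, argument tables) combination until no
# length improves.  No size ordering is involved, unlike the DP.
relax_min_lengths <- function(ops, metric = c("nodes", "ops"),
                              mats = oracle_op_matrices()) {
  metric <- match.arg(metric)
  litc <- if (metric == "nodes") 1 else 0
  len <- rep(Inf, 16)
  len[lotlearn::literal_table(1, 2) + 1L] <- litc
  len[lotlearn::literal_table(2, 2) + 1L] <- litc
  repeat {
    old <- len
    for (op in ops) {
      if (op == "not") {
        cand <- len + 1
        tgt <- mats$not + 1L
        for (i in 1:16) len[tgt[i]] <- min(len[tgt[i]], cand[i])
      } else {
        cand <- 1 + outer(len, len, "+")
        tgt <- mats$binary[[op]] + 1L
        upd <- tapply(as.vector(cand), as.vector(tgt), min)
        idx <- as.integer(names(upd))
        len[idx] <- pmin(len[idx], unname(upd))
      }
    }
    if (identical(old, len)) break
  }
  stats::setNames(len, lotlearn::render_category(0:15, 2))
}

# Exhaustive enumeration of all formula trees up to a node budget, for
# small operator sets.  Trees are generated explicitly (with duplicates),
# so this is a true enumeration, not a table-keyed search.  Returns the
# minimal node count per truth table among formulas within the budget.
enum_min_lengths <- function(ops, max_nodes = 13,
                             mats = oracle_op_matrices()) {
  by_size <- vector("list", max_nodes)
  by_size[[1]] <- c(lotlearn::literal_table(1, 2), lotlearn::literal_table(2, 2))
  for (s in 2:max_nodes) {
    acc <- integer(0)
    for (op in ops) {
      if (op == "not") {
        acc <- c(acc, mats$not[by_size[[s - 1]] + 1L])
      } else if (s >= 3) {
        for (s1 in 1:(s - 2)) {
          a <- by_size[[s1]]; b <- by_size[[s - 1 - s1]]
          if (length(a) && length(b)) {
            acc <- c(acc, as.vector(mats$binary[[op]][a + 1L, b + 1L]))
          }
        }
      }
    }
    by_size[[s]] <- acc
  }
  len <- rep(NA_integer_, 16)
  for (s in seq_len(max_nodes)) {
    seen <- unique(by_size[[s]])
    new <- seen[is.na(len[seen + 1L])]
    len[new + 1L] <- s
  }
  stats::setNames(len, lotlearn::render_category(0:15, 2))
}

# tiny configs used across the ANN tests
tiny_net <- function(n) lotlearn::network_config(input_dim = n)
tiny_trn <- function(...) {
  lotlearn::training_config(epochs = 20L, batch_size = 4L, replicates = 2L, ...)
}
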