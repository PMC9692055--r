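#' Surrogate-effort generator configuration
#'
#' The generator embodies the modelling assumption that links the two
#' accounts: learning effort is a noisy, strictly increasing function of
#' minimal formula length.  Efforts are drawn as
#' `transform(length) + N(0, noise_sd)`, truncated below at a small
#' positive floor so they live in the same positive range as cross-entropy
#' based efforts.
#'
#' @param transform One of `"identity"`, `"log"`, `"power"` (square root);
#'   all strictly increasing, so at `noise_sd = 0` the rank correlation
#'   with the generating profile is exactly 1.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (>= 0), in units of the transformed length.
#' @param seed Integer seed.
#' @param floor Positive truncation floor for the efforts.
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(transform = c("identity", "log", "power"),
                             noise_sd = 0, seed = 1L, floor = 1e-6) {
  transform <- match.arg(transform)
  if (length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a single non-negative number", call. = FALSE)
  }
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  structure(list(transform = transform, noise_sd = noise_sd,
                 seed = as.integer(seed), floor = floor),
            class = "surrogate_config")
}

#' Generate surrogate learning efforts from a complexity profile
#'
#' Produces an effort table with the same shape as [effort_table()]
#' output, so the correlation stage runs identically on surrogate and
#' real data.  Reproducible for a fixed config seed.
#'
#' @param profile A [minimal_profile()] object (the generating LOT).
#' @param cfg A [surrogate_config()].
#' @return Data frame with columns `category` and `mean_effort`.
#' @examples
#' pr <- minimal_profile("nand", 2)
#' eff <- surrogate_efforts(pr, surrogate_config(noise_sd = 0))
#' spearman(pr$lengths, eff$mean_effort)  # 1
#' @export
surrogate_efforts <- function(profile, cfg = surrogate_config()) {
  if (!inherits(profile, "complexity_profile")) {
    stop("`profile` must be a complexity_profile", call. = FALSE)
  }
  if (!inherits(cfg, "surrogate_config")) {
    stop("`cfg` must be a surrogate_config", call. = FALSE)
  }
  f <- switch(cfg$transform,
              identity = function(x) x,
              log = log,
              power = sqrt)
  base <- f(as.numeric(profile$lengths))
  eff <- withr_seed(cfg$seed, {
    base + stats::rnorm(length(base), sd = cfg$noise_sd)
  })
  data.frame(category = names(profile$lengths),
             mean_effort = pmax(eff, cfg$floor),
             stringsAsFactors = FALSE)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Two-property reference world
#'
#' A self-contained fixture for the two-property domain: the three
#' reference LOTs (the nand-only minimal LOT, an English-like LOT with
#' not/and/or/nor, and a parity LOT with not/or/xor) together with the
#' expected minimal formula length of each of the 16 categories in each
#' LOT.  The lengths are parse-tree node counts of known minimal
#' formulas; `minimal_profile()` must reproduce them exactly, which is
#' the package's primary regression check.
#'
#' @return A list with `n = 2`, `lots` (named list of operator vectors)
#'   and `expected_lengths` (named list of integer vectors indexed by
#'   category string).
#' @export
small_world <- function() {
  cats <- c("1100", "1010", "0011", "0111", "0101", "1111", "1011", "1101",
            "1110", "1000", "1001", "0000", "0100", "0010", "0110", "0001")
  # node counts of reference minimal formulas, one per category, e.g.
  # nand-only: "0001" -> nand(nand(p,nand(p,p)), nand(nand(p,p),nand(q,q)))
  len_nand <- c(1L, 1L, 3L, 3L, 3L, 5L, 5L, 5L, 7L, 7L, 11L, 11L, 11L, 11L,
                11L, 13L)
  # not/and/or/nor: "1001" -> or(and(p,q), nor(p,q))
  len_english <- c(1L, 1L, 2L, 4L, 2L, 4L, 4L, 4L, 3L, 3L, 7L, 4L, 4L, 4L,
                   7L, 3L)
  # not/or/xor: "0110" -> nbicond(p,q)
  len_parity <- c(1L, 1L, 2L, 5L, 2L, 4L, 4L, 4L, 3L, 6L, 4L, 3L, 5L, 5L,
                  3L, 4L)
  mk <- function(v) stats::setNames(v, cats)
  list(n = 2L,
       lots = list("nand" = "nand",
                   "and+nor+not+or" = c("not", "and", "or", "nor"),
                   "nbicond+not+or" = c("not", "or", "nbicond")),
       expected_lengths = list("nand" = mk(len_nand),
                               "and+nor+not+or" = mk(len_english),
                               "nbicond+not+or" = mk(len_parity)))
}

#' Rank-recovery experiment on surrogate data
#'
#' End-to-end check of the analysis pipeline: surrogate efforts are
#' generated from one LOT's complexity profile and all candidate LOTs are
#' ranked by their rank correlation with those efforts.  At zero noise
#' the generating LOT (or any LOT with an identical profile) attains
#' rho = 1 and ranks first; as noise grows the recovery degrades.
#'
#' @param generating_lot Operator-name vector of the LOT whose profile
#'   drives the surrogate efforts.
#' @param candidate_lots List of operator-name vectors to rank (all
#'   functionally complete).
#' @param cfg A [surrogate_config()].
#' @param n Number of properties (default 2 for fast checks).
#' @return A list with `records` (the [lot_rho_table()]), `efforts`, and
#'   `generator_rank` (rank of the generating LOT's id in the table).
#' @export
recovery_experiment <- function(generating_lot, candidate_lots,
                                cfg = surrogate_config(), n = 2L) {
  gen_profile <- minimal_profile(generating_lot, n)
  profiles <- lapply(candidate_lots, minimal_profile, n = n)
  eff <- surrogate_efforts(gen_profile, cfg)
  records <- lot_rho_table(profiles, eff)
  list(records = records,
       efforts = eff,
       generator_rank = match(lot_id(generating_lot), records$lot_id))
}
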