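#' Network architecture configuration
#'
#' The study architecture is a feedforward network with one input unit
#' per property, two rectifier (ReLU) hidden layers of 16 units, and a
#' single sigmoid output unit read as the network's confidence that the
#' input object belongs to the category.  Hidden layers use He-uniform
#' initialisation, the output layer Xavier-uniform; both are driven by
#' the training seed.
#'
#' @param input_dim Number of input units (the property count; default 4).
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @return A list of class `network_config`.
#' @export
network_config <- function(input_dim = 4L, hidden_sizes = c(16L, 16L)) {
  if (input_dim < 1L) stop("input_dim must be >= 1", call. = FALSE)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L)) {
    stop("hidden_sizes must be positive", call. = FALSE)
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 hidden_activation = "relu",
                 output_activation = "sigmoid"),
            class = "network_config")
}

#' Training configuration
#'
#' Training minimises binary cross entropy with Adam.  The defaults are
#' the study conditions: batch size 8, 400 epochs, 25 replicate runs per
#' category, and the standard Adam hyperparameters (lr 0.001, beta1 0.9,
#' beta2 0.999, eps 1e-8).  The batch size must divide the dataset size
#' `2^n` (two batches per epoch at n = 4).  Replicate `r` of category `c`
#' uses the seed `base_seed XOR hash(c, r)`, so runs are reproducible and
#' independent of execution order.
#'
#' @param epochs Number of passes over the `2^n` examples.
#' @param batch_size Minibatch size; must divide `2^n`.
#' @param replicates Number of independent training runs per category.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param base_seed Base seed for the seed policy.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 400L, batch_size = 8L, replicates = 25L,
                            lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8, base_seed = 1L) {
  if (epochs < 1L || batch_size < 1L || replicates < 1L) {
    stop("epochs, batch_size and replicates must be >= 1", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 replicates = as.integer(replicates),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 base_seed = as.integer(base_seed)),
            class = "training_config")
}

#' Build the training set for a category
#'
#' Each of the `2^n` objects becomes one example: the input is the
#' assignment encoded as a 0/1 vector (in the package-wide assignment
#' order), the label its membership bit in the category.
#'
#' @param category Category as a bit string or integer mask.
#' @param n Number of properties.
#' @return A list with `x` (`2^n` by `n` numeric matrix) and `y`
#'   (numeric 0/1 labels).
#' @examples
#' make_dataset("1100", 2)
#' @export
make_dataset <- function(category, n) {
  n <- check_n(n)
  mask <- if (is.character(category)) parse_category(category, n)
          else as.integer(category)
  x <- assignments(n) * 1
  s <- render_category(mask, n)
  y <- as.numeric(strsplit(s, "")[[1]])
  list(x = x, y = y)
}

# Seed for (category, replicate): base XOR a small integer hash, kept in
# [1, 2^31).  Pure function of its arguments, so categories can be run in
# any order (or concurrently) with identical results.
replicate_seed <- function(base_seed, mask, replicate) {
  h <- (as.double(mask) * 100003 + as.double(replicate) * 7919) %% 2147483647
  s <- bitwXor(as.integer(base_seed %% 2147483647), as.integer(h))
  if (s <= 0L) s <- s + 2147483646L + 1L  # avoid the degenerate 0 seed
  s
}

#' Train one network on one category
#'
#' Runs `epochs * (2^n / batch_size)` gradient steps of Adam on binary
#' cross entropy and returns the learning effort: the unweighted mean of
#' all per-batch losses, i.e. the area under the learning curve.  The
#' same seed yields a bitwise-identical effort on re-run.
#'
#' @param category Category as bit string or integer mask.
#' @param n Number of properties.
#' @param seed Integer seed for weight initialisation and shuffling.
#' @param net A [network_config()] with `input_dim == n`.
#' @param trn A [training_config()].
#' @return A list with `effort` (positive scalar) and `losses` (per-batch
#'   loss trajectory, length `epochs * 2^n / batch_size`).
#' @export
train_once <- function(category, n, seed,
                       net = network_config(input_dim = n),
                       trn = training_config()) {
  n <- check_n(n)
  if (!inherits(net, "network_config")) stop("`net` must be a network_config",
                                             call. = FALSE)
  if (!inherits(trn, "training_config")) stop("`trn` must be a training_config",
                                              call. = FALSE)
  if (net$input_dim != n) {
    stop(sprintf("network input_dim (%d) must equal n (%d)",
                 net$input_dim, n), call. = FALSE)
  }
  if ((2L^n) %% trn$batch_size != 0L) {
    stop(sprintf("batch size %d does not divide the dataset size %d",
                 trn$batch_size, 2L^n), call. = FALSE)
  }
  d <- make_dataset(category, n)
  cpp_train_mlp(d$x, d$y, net$hidden_sizes, trn$epochs, trn$batch_size,
                trn$lr, trn$beta1, trn$beta2, trn$eps, as.integer(seed))
}

#' Replicate learning efforts for one category
#'
#' Trains `trn$replicates` independent networks on the category, each with
#' the seed `base_seed XOR hash(category, replicate)`, and summarises by
#' the arithmetic mean.
#'
#' @inheritParams train_once
#' @return A list with `samples` (data frame: `category`, `replicate`,
#'   `effort`) and `mean_effort`.
#' @export
measure_effort <- function(category, n,
                           net = network_config(input_dim = n),
                           trn = training_config()) {
  n <- check_n(n)
  mask <- if (is.character(category)) parse_category(category, n)
          else as.integer(category)
  efforts <- vapply(seq_len(trn$replicates), function(r) {
    train_once(mask, n, replicate_seed(trn$base_seed, mask, r), net, trn)$effort
  }, numeric(1))
  list(samples = data.frame(category = render_category(mask, n),
                            replicate = seq_len(trn$replicates),
                            effort = efforts,
                            stringsAsFactors = FALSE),
       mean_effort = mean(efforts))
}

#' Batch learning-effort table over categories
#'
#' Runs [measure_effort()] for each category and collects per-category
#' summaries.  With a `checkpoint` path, per-replicate rows are appended
#' to a CSV as each category finishes and already-recorded categories are
#' skipped on re-run, so an interrupted run resumes to an identical final
#' table (seeds are a pure function of category and replicate).
#'
#' @param categories Vector of category bit strings or integer masks.
#' @param n Number of properties.
#' @param net,trn Configurations as in [train_once()].
#' @param checkpoint Optional path of a CSV (columns `category`,
#'   `replicate`, `effort`) used as an incremental store.
#' @param verbose Print a progress line per category.
#' @return A data frame with columns `category`, `mean_effort`, `sd_effort`
#'   and `n_replicates`, in the input category order.
#' @export
effort_table <- function(categories, n,
                         net = network_config(input_dim = n),
                         trn = training_config(),
                         checkpoint = NULL, verbose = FALSE) {
  n <- check_n(n)
  masks <- vapply(categories, function(c) {
    if (is.character(c)) parse_category(c, n) else as.integer(c)
  }, integer(1))
  strs <- render_category(masks, n)

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE,
                            colClasses = c(category = "character"))
  }
  rows <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    cs <- strs[i]
    if (!is.null(done) && cs %in% done$category) {
      sub <- done[done$category == cs, , drop = FALSE]
      if (nrow(sub) == trn$replicates) {
        rows[[i]] <- sub
        next
      }
    }
    res <- tryCatch(measure_effort(masks[i], n, net, trn),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("category %s failed: %s", cs, conditionMessage(res)),
              call. = FALSE)
      next
    }
    rows[[i]] <- res$samples
    if (!is.null(checkpoint)) {
      out <- res$samples
      # full precision so a resumed run reproduces efforts bitwise
      out$effort <- sprintf("%.17g", out$effort)
      utils::write.table(out, checkpoint, sep = ",", quote = TRUE,
                         row.names = FALSE, col.names = !file.exists(checkpoint),
                         append = file.exists(checkpoint))
    }
    if (verbose) message(sprintf("category %s: mean effort %.5f",
                                 cs, res$mean_effort))
  }
  samples <- do.call(rbind, rows)
  agg <- lapply(strs, function(cs) {
    e <- samples$effort[samples$category == cs]
    data.frame(category = cs, mean_effort = mean(e),
               sd_effort = stats::sd(e), n_replicates = length(e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, agg)
}
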