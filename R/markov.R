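# Position-specific (inhomogeneous) Markov chain models of siRNA sequences.
#
# A model of order h consists of
#   * an initial distribution over the h-mers occupying positions 1..h, and
#   * for each position j in (h+1)..L, a conditional distribution
#     Pr(base at j | h preceding bases).
# All distributions are estimated by relative frequency from a training set
# of effective siRNAs; an optional pseudocount smooths them.

all_kmers <- function(h) {
  grids <- rep(list(RNA_BASES), h)
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Fit a position-specific Markov chain model
#'
#' Estimates an order-`h` inhomogeneous Markov chain from a set of
#' equal-length sequences. The initial distribution is the relative
#' frequency of the leading `h`-mer; the transition distribution at each
#' position `j` in `(h+1):L` is the relative frequency of the base at `j`
#' given the `h` preceding bases, estimated separately per position.
#'
#' With `pseudocount = 0` (the default) unobserved events have probability
#' exactly zero. Zeros are deliberate: the relative mean probability
#' discounts models that assign a sequence probability zero, so smoothing
#' is off unless explicitly requested. With `pseudocount > 0` every count
#' (including contexts never observed at a position, and unseen initial
#' h-mers) is incremented, so every sequence over the RNA alphabet gets a
#' strictly positive probability.
#'
#' @param training a `sirna_set`, or a character vector of equal-length
#'   sequences over `{A,C,G,U}` (normalized on entry).
#' @param order Markov order `h`, one of 1, 2 or 3.
#' @param pseudocount non-negative smoothing count added to every event.
#' @param position_specific logical; if `FALSE` transition counts are pooled
#'   across positions into a single homogeneous conditional distribution
#'   (applied at every position). The default `TRUE` keeps each position's
#'   distribution separate, which is what lets the model express
#'   position-dependent sequence preferences.
#' @return an object of class `markov_model`.
#' @examples
#' m <- fit_markov(c("UAAUC", "UACCG", "CGAUC", "CGCCG"), order = 1)
#' sequence_probability(m, "UAAUC")
#' @export
fit_markov <- function(training, order, pseudocount = 0,
                       position_specific = TRUE) {
  seqs <- if (inherits(training, "sirna_set")) training$seq
          else normalize_sequence(training)
  if (length(seqs) == 0) stop("empty training set", call. = FALSE)
  if (length(order) != 1 || !order %in% 1:3) {
    stop("`order` must be 1, 2 or 3", call. = FALSE)
  }
  if (pseudocount < 0) stop("`pseudocount` must be non-negative", call. = FALSE)
  mat <- seq_matrix(seqs)  # errors on heterogeneous lengths
  L <- ncol(mat)
  if (L <= order) {
    stop("sequence length (", L, ") must exceed the model order (", order, ")",
         call. = FALSE)
  }
  n <- nrow(mat)
  h <- order
  kmers <- all_kmers(h)

  lead <- apply(mat[, seq_len(h), drop = FALSE], 1, paste0, collapse = "")
  init_counts <- stats::setNames(numeric(length(kmers)), kmers)
  tab <- table(lead)
  init_counts[names(tab)] <- as.numeric(tab)
  initial <- (init_counts + pseudocount) / (n + pseudocount * length(kmers))

  ctx_at <- function(j) {
    apply(mat[, (j - h):(j - 1), drop = FALSE], 1, paste0, collapse = "")
  }
  count_matrix <- function(ctx, base) {
    cm <- matrix(0, nrow = length(kmers), ncol = 4,
                 dimnames = list(kmers, RNA_BASES))
    tb <- table(ctx, base)
    cm[rownames(tb), colnames(tb)] <- cm[rownames(tb), colnames(tb)] + tb
    cm
  }
  positions <- (h + 1):L
  if (position_specific) {
    counts <- lapply(positions, function(j) count_matrix(ctx_at(j), mat[, j]))
    names(counts) <- positions
  } else {
    pooled <- Reduce(`+`, lapply(positions, function(j) {
      count_matrix(ctx_at(j), mat[, j])
    }))
    counts <- stats::setNames(rep(list(pooled), length(positions)), positions)
  }
  transitions <- lapply(counts, function(cm) {
    tot <- rowSums(cm) + 4 * pseudocount
    pr <- (cm + pseudocount) / ifelse(tot > 0, tot, 1)
    pr[tot == 0, ] <- 0  # context never observed, no smoothing requested
    pr
  })

  structure(
    list(order = as.integer(h), length = as.integer(L),
         pseudocount = pseudocount,
         position_specific = position_specific,
         initial = initial, transitions = transitions,
         n_training = n),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf(
    "markov_model: order %d, length %d, %s transitions, pseudocount %g (trained on %d sequence(s))\n",
    x$order, x$length,
    if (x$position_specific) "position-specific" else "homogeneous",
    x$pseudocount, x$n_training
  ))
  invisible(x)
}

#' Probability of a sequence under a Markov chain model
#'
#' Computes the chain probability: the probability of the leading h-mer
#' times the product over positions `(h+1):L` of the position's conditional
#' probability of the observed base given its `h` predecessors. Any factor
#' of zero (an h-mer or a transition never seen in training, with
#' pseudocount 0) makes the whole probability zero.
#'
#' @param model a `markov_model`.
#' @param seq a single sequence (or character vector of sequences) of the
#'   length the model was trained for.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
sequence_probability <- function(model, seq) {
  stopifnot(inherits(model, "markov_model"))
  seqs <- if (inherits(seq, "sirna_set")) seq$seq else normalize_sequence(seq)
  if (length(seqs) == 0) return(numeric(0))
  mat <- seq_matrix(seqs)
  if (ncol(mat) != model$length) {
    stop("sequence length ", ncol(mat), " does not match model length ",
         model$length, call. = FALSE)
  }
  h <- model$order
  p <- model$initial[apply(mat[, seq_len(h), drop = FALSE], 1,
                           paste0, collapse = "")]
  p <- unname(p)
  for (j in (h + 1):model$length) {
    ctx <- apply(mat[, (j - h):(j - 1), drop = FALSE], 1, paste0, collapse = "")
    tr <- model$transitions[[as.character(j)]]
    p <- p * tr[cbind(ctx, mat[, j])]
  }
  unname(p)
}

#' Relative mean probability of the positive chain probabilities
#'
#' The relative mean probability of a sequence is the arithmetic mean of
#' those of its three chain probabilities (orders 1, 2, 3) that are
#' strictly positive: `(q1 + q2 + q3) / (#positive among q1,q2,q3)`. When
#' all three are zero the result is zero. Averaging only over the positive
#' members keeps one unobserved higher-order context from dragging an
#' otherwise well-supported sequence to zero.
#'
#' @param q1,q2,q3 chain probabilities in `[0, 1]`; vectors are recycled to
#'   a common length.
#' @return numeric vector of relative mean probabilities.
#' @examples
#' relative_mean_probability(0.3, 0, 0.1)  # mean of the two positive values
#' @export
relative_mean_probability <- function(q1, q2, q3) {
  qs <- cbind(q1, q2, q3)
  if (any(is.na(qs)) || any(qs < 0 | qs > 1)) {
    stop("chain probabilities must lie in [0, 1]", call. = FALSE)
  }
  denom <- rowSums(qs > 0)
  ifelse(denom == 0, 0, rowSums(qs) / denom)
}

#' Train the order-1, 2 and 3 models used for scoring
#'
#' Convenience wrapper fitting the three chain models on one training set.
#'
#' @inheritParams fit_markov
#' @return a list of three `markov_model` objects named `"1"`, `"2"`, `"3"`.
#' @export
fit_markov_models <- function(training, pseudocount = 0,
                              position_specific = TRUE) {
  stats::setNames(
    lapply(1:3, fit_markov, training = training, pseudocount = pseudocount,
           position_specific = position_specific),
    as.character(1:3)
  )
}

#' Score sequences under the three chain models
#'
#' Computes, for each sequence, the chain probabilities `q1`, `q2`, `q3`
#' under the order-1/2/3 models and their relative mean probability `q4`.
#'
#' @param models a list of `markov_model` objects of orders 1, 2 and 3 with
#'   a common length (as returned by [fit_markov_models()]), or a single
#'   `markov_model` that is then used for all three orders' role (the
#'   convention of the five-nucleotide simulation study, where the relative
#'   mean probability of a sequence equals its order-1 chain probability).
#' @param records a `sirna_set` or character vector of sequences.
#' @return a `data.frame` with columns `id`, `q1`, `q2`, `q3`, `q4`, one row
#'   per input sequence, in input order.
#' @export
profile_sequences <- function(models, records) {
  if (inherits(models, "markov_model")) models <- list(models, models, models)
  if (length(models) != 3) {
    stop("`models` must supply three models (orders 1, 2, 3)", call. = FALSE)
  }
  orders <- vapply(models, function(m) m$order, numeric(1))
  models <- models[order(orders)]
  ids <- if (inherits(records, "sirna_set")) records$id else NULL
  seqs <- if (inherits(records, "sirna_set")) records$seq
          else normalize_sequence(records)
  if (length(seqs) == 0) {
    return(data.frame(id = character(0), q1 = numeric(0), q2 = numeric(0),
                      q3 = numeric(0), q4 = numeric(0)))
  }
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  q <- lapply(models, sequence_probability, seq = seqs)
  data.frame(
    id = ids,
    q1 = q[[1]], q2 = q[[2]], q3 = q[[3]],
    q4 = relative_mean_probability(q[[1]], q[[2]], q[[3]]),
    stringsAsFactors = FALSE
  )
}

#' Entropy-style score of a relative mean probability
#'
#' The absolute value of the natural logarithm of the relative mean
#' probability, interpretable as a per-sequence entropy: sequences typical
#' of the effective training set score low, atypical ones score high.
#' Undefined at zero (the caller may treat a zero probability as infinite
#' entropy).
#'
#' @param q4 relative mean probabilities in `(0, 1]`.
#' @return numeric vector of non-negative scores; monotone decreasing in `q4`.
#' @export
entropy_score <- function(q4) {
  if (any(is.na(q4)) || any(q4 <= 0 | q4 > 1)) {
    stop("`q4` must lie in (0, 1]; zero probabilities have no finite score",
         call. = FALSE)
  }
  abs(log(q4))
}
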