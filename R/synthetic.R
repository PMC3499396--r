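# Seeded generators for the simulation models used to benchmark the
# method, plus the 17-sequence worked example with its reference scores
# and cluster memberships.

#' The inhomogeneous order-1 chain behind simulation group X
#'
#' Builds (rather than fits) the exact order-1 model of the group-X
#' simulation: position 1 is U with probability 0.75 and C with 0.25;
#' at position 2, `Pr(A|U) = 0.75`, `Pr(U|U) = 0.25` and `Pr(G|C) = 1`
#' (all other conditionals zero); at positions 3 to `length` every
#' conditional is uniform 0.25.
#'
#' @param length sequence length, at least 3 (the simulation uses 5).
#' @return a `markov_model` of order 1.
#' @export
group_x_model <- function(length = 5) {
  stopifnot(length >= 3)
  initial <- stats::setNames(c(0, 0.25, 0, 0.75), RNA_BASES)
  blank <- matrix(0, nrow = 4, ncol = 4,
                  dimnames = list(RNA_BASES, RNA_BASES))
  pos2 <- blank
  pos2["U", "A"] <- 0.75
  pos2["U", "U"] <- 0.25
  pos2["C", "G"] <- 1
  uniform <- matrix(0.25, nrow = 4, ncol = 4,
                    dimnames = list(RNA_BASES, RNA_BASES))
  transitions <- c(list(pos2), rep(list(uniform), length - 2))
  names(transitions) <- 2:length
  structure(
    list(order = 1L, length = as.integer(length), pseudocount = 0,
         position_specific = TRUE, initial = initial,
         transitions = transitions, n_training = NA_integer_),
    class = "markov_model"
  )
}

# internal: sample one position from a per-context conditional matrix given
# the previous bases, grouping by context so each group is one sample() call
sample_conditional <- function(prev, cond) {
  out <- character(length(prev))
  for (b in unique(prev)) {
    idx <- which(prev == b)
    out[idx] <- sample(RNA_BASES, length(idx), replace = TRUE,
                       prob = cond[b, ])
  }
  out
}

#' Generate sequences from the group-X simulation chain
#'
#' Samples `n` sequences from the inhomogeneous order-1 chain of
#' [group_x_model()]. Every generated sequence has strictly positive
#' probability under that chain.
#'
#' @param n number of sequences (0 allowed).
#' @param length sequence length (default 5).
#' @param seed optional integer seed.
#' @return a `sirna_set` with ids `x1, x2, ...`.
#' @export
generate_group_x <- function(n, length = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(sirna_set(character(0), id = character(0)))
  model <- group_x_model(length)
  first <- sample(RNA_BASES, n, replace = TRUE, prob = model$initial)
  mat <- matrix("", nrow = n, ncol = length)
  mat[, 1] <- first
  for (j in 2:length) {
    mat[, j] <- sample_conditional(mat[, j - 1], model$transitions[[as.character(j)]])
  }
  sirna_set(apply(mat, 1, paste0, collapse = ""), id = paste0("x", seq_len(n)))
}

#' Generate sequences from the constrained-uniform group-Y model
#'
#' Samples length-5 sequences uniformly over the 4^5 space minus the two
#' forbidden endpoint combinations: U at position 1 with A at position 5,
#' and C at position 1 with G at position 5. Sampling is by rejection from
#' the uniform 5-mer distribution; 896 of the 1024 5-mers are admissible,
#' so about one draw in eight is rejected.
#'
#' @param n number of sequences (0 allowed).
#' @param seed optional integer seed.
#' @return a `sirna_set` with ids `y1, y2, ...`.
#' @export
generate_group_y <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(sirna_set(character(0), id = character(0)))
  out <- character(0)
  while (length(out) < n) {
    draw <- matrix(sample(RNA_BASES, 5 * 2 * (n - length(out) + 4),
                          replace = TRUE), ncol = 5)
    forbidden <- (draw[, 1] == "U" & draw[, 5] == "A") |
                 (draw[, 1] == "C" & draw[, 5] == "G")
    keep <- draw[!forbidden, , drop = FALSE]
    out <- c(out, apply(keep, 1, paste0, collapse = ""))
  }
  sirna_set(out[seq_len(n)], id = paste0("y", seq_len(n)))
}

#' Generate uniform random siRNA sequences
#'
#' Independent, identically distributed sequences over `{A,C,G,U}`,
#' uniform at every position.
#'
#' @param n number of sequences (0 allowed).
#' @param length sequence length (default 19, the paired length of a
#'   typical siRNA guide).
#' @param seed optional integer seed.
#' @return a `sirna_set` with ids `r1, r2, ...`.
#' @export
generate_random_sirnas <- function(n, length = 19, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(sirna_set(character(0), id = character(0)))
  mat <- matrix(sample(RNA_BASES, n * length, replace = TRUE), nrow = n)
  sirna_set(apply(mat, 1, paste0, collapse = ""), id = paste0("r", seq_len(n)))
}

#' Generate a labeled benchmark pool with positional signal
#'
#' Builds a two-class pool for exercising the classifier and the
#' resampling protocol. Effective sequences are drawn from an
#' inhomogeneous order-1 chain that is uniform everywhere except at
#' `signal_positions`, where the next base follows its predecessor through
#' a fixed cyclic preference (A to C, C to G, G to U, U to A) with
#' probability `bias`; a signal at position 1 biases the initial base
#' toward U with probability `bias`. Ineffective sequences are uniform
#' i.i.d. With `bias = 0.25` the two classes are identically distributed.
#'
#' @param n_eff,n_ineff class sizes.
#' @param length sequence length (default 19).
#' @param signal_positions 1-based positions carrying the class signal;
#'   defaults to positions 1, 2, the midpoint and the last position.
#' @param bias preference probability at signal positions, in `[0.25, 1]`;
#'   default 0.9 gives a strong, easily recoverable signal.
#' @param seed optional integer seed.
#' @return a `sirna_set` with labels `"effective"`/`"ineffective"`.
#' @export
generate_labeled_pool <- function(n_eff, n_ineff, length = 19,
                                  signal_positions = NULL,
                                  bias = 0.9, seed = NULL) {
  if (is.null(signal_positions)) {
    signal_positions <- unique(c(1, 2, ceiling(length / 2), length))
  }
  stopifnot(all(signal_positions >= 1), all(signal_positions <= length),
            bias >= 0.25, bias <= 1)
  if (!is.null(seed)) set.seed(seed)
  other <- (1 - bias) / 3
  cyc <- stats::setNames(c("C", "G", "U", "A"), RNA_BASES)  # preferred follower
  draw_effective <- function(n) {
    mat <- matrix("", nrow = n, ncol = length)
    if (1 %in% signal_positions) {
      mat[, 1] <- sample(RNA_BASES, n, replace = TRUE,
                         prob = ifelse(RNA_BASES == "U", bias, other))
    } else {
      mat[, 1] <- sample(RNA_BASES, n, replace = TRUE)
    }
    if (length >= 2) for (j in 2:length) {
      if (j %in% signal_positions) {
        cond <- matrix(other, nrow = 4, ncol = 4,
                       dimnames = list(RNA_BASES, RNA_BASES))
        cond[cbind(RNA_BASES, unname(cyc))] <- bias
        mat[, j] <- sample_conditional(mat[, j - 1], cond)
      } else {
        mat[, j] <- sample(RNA_BASES, n, replace = TRUE)
      }
    }
    apply(mat, 1, paste0, collapse = "")
  }
  seqs <- character(0)
  labels <- character(0)
  if (n_eff > 0) {
    seqs <- draw_effective(n_eff)
    labels <- rep("effective", n_eff)
  }
  if (n_ineff > 0) {
    mat <- matrix(sample(RNA_BASES, n_ineff * length, replace = TRUE),
                  nrow = n_ineff)
    seqs <- c(seqs, apply(mat, 1, paste0, collapse = ""))
    labels <- c(labels, rep("ineffective", n_ineff))
  }
  sirna_set(seqs, id = paste0("p", seq_along(seqs)), label = labels)
}

#' The reference 17-sequence worked example
#'
#' Returns the 17 five-nucleotide simulation sequences (ten from group X,
#' seven from group Y) together with their expected scores under the
#' group-X chain and the cluster memberships the two algorithms produce:
#' the mini-cluster procedure separates them into four clusters that
#' respect the score groups, while 2-means co-clusters seven group-X
#' sequences with all of group Y.
#'
#' Scores are stored at full precision (`0.0087890625`,
#' `0.0029296875`, `0.00390625`, `0`); printed reference tables round them
#' to four decimals.
#'
#' @return a `data.frame` with columns `id`, `group`, `seq`, `q_expected`,
#'   `rmp_cluster`, `kmean_cluster`.
#' @export
table1_fixture <- function() {
  data.frame(
    id = c(paste0("a", 1:10), paste0("b", 1:7)),
    group = rep(c("X", "Y"), c(10, 7)),
    seq = c("UAAUC", "UACCG", "UAGAA", "UUCCG", "UUGAA", "UUUGU",
            "CGAUC", "CGCCG", "CGGAA", "CGUGU",
            "AACGA", "AUGGA", "UCAGC", "UGUUC", "UCCUG", "CCAAA", "CCUAC"),
    q_expected = c(rep(0.75 * 0.75 * 0.25^3, 3),
                   rep(0.75 * 0.25 * 0.25^3, 3),
                   rep(0.25 * 1 * 0.25^3, 4),
                   rep(0, 7)),
    rmp_cluster = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, rep(4L, 7)),
    kmean_cluster = c(1L, 1L, 1L, rep(2L, 14)),
    stringsAsFactors = FALSE
  )
}
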