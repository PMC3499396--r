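# End-to-end classification and evaluation. The pipeline profiles the
# labeled training sequences and the unlabeled queries with the same three
# chain models, clusters everything on one feature, labels the clusters
# from the training efficacies, merges the unlabeled clusters, and reads
# each query's call off its final cluster.

#' Classify query siRNAs by mini-clustering with training sequences
#'
#' @param queries a `sirna_set` (or character vector) of sequences to call.
#' @param train a `sirna_set` whose `label` column marks known effective and
#'   ineffective sequences; `unknown` rows are ignored as labels but still
#'   clustered.
#' @param models optional list of order-1/2/3 `markov_model`s (see
#'   [fit_markov_models()]); fitted on the effective training sequences when
#'   `NULL`.
#' @param feature which profile column drives the clustering: `"q4"` (the
#'   relative mean probability, default) or one of `"q1"`, `"q2"`, `"q3"`.
#' @param pseudocount passed to [fit_markov_models()] when models are fitted
#'   here.
#' @return a character vector of `"effective"`/`"ineffective"` calls, one
#'   per query, named by query id. The full clustering (training + queries)
#'   is attached as attribute `"clustering"` and the combined profile table
#'   as attribute `"profiles"`.
#' @export
classify <- function(queries, train, models = NULL,
                     feature = c("q4", "q1", "q2", "q3"), pseudocount = 0) {
  feature <- match.arg(feature)
  if (!inherits(train, "sirna_set")) {
    stop("`train` must be a sirna_set with labels", call. = FALSE)
  }
  if (!inherits(queries, "sirna_set")) queries <- sirna_set(queries)
  if (is.null(models)) {
    eff <- train[train$label == "effective", , drop = FALSE]
    if (nrow(eff) == 0) {
      stop("no effective training sequences to fit models on", call. = FALSE)
    }
    models <- fit_markov_models(eff, pseudocount = pseudocount)
  }
  if (nrow(queries) == 0) {
    out <- character(0)
    return(out)
  }
  all_seq <- c(train$seq, queries$seq)
  prof <- profile_sequences(models, all_seq)
  prof$id <- c(train$id, queries$id)
  known <- c(train$label, rep("unknown", nrow(queries)))
  clustering <- build_mini_clusters(prof[[feature]])
  clustering <- label_clusters(clustering, known)
  clustering <- merge_uncertain(clustering)
  calls <- clustering$label[seq(nrow(train) + 1, length.out = nrow(queries))]
  names(calls) <- queries$id
  attr(calls, "clustering") <- clustering
  attr(calls, "profiles") <- prof
  calls
}

#' Confusion-matrix evaluation of efficacy calls
#'
#' Computes the usual confusion counts treating `"effective"` as the
#' positive class, plus two specificities: the conventional
#' `TN / (TN + FP)` (`specificity_true`) and the precision-style
#' `TP / (TP + FP)` (`precision`), i.e. the fraction of predicted-effective
#' sequences that really are effective. Benchmark tables for this method
#' report the precision-style quantity in their "Specificity" column, so
#' both are returned.
#'
#' @param predictions character vector of `"effective"`/`"ineffective"`
#'   calls, named by sequence id (or matched to `truth` by position).
#' @param truth character vector of true labels covering every predicted
#'   id.
#' @return an object of class `evaluation_result`: a list with counts
#'   (`tp`, `fp`, `tn`, `fn`, `n_effective`, `n_ineffective`,
#'   `total_predicted_effective`) and rates (`sensitivity`,
#'   `specificity_true`, `precision`).
#' @examples
#' evaluate(c(a = "effective", b = "effective", c = "ineffective"),
#'          c(a = "effective", b = "ineffective", c = "ineffective"))
#' @export
evaluate <- function(predictions, truth) {
  if (!is.null(names(predictions)) && !is.null(names(truth))) {
    missing <- setdiff(names(predictions), names(truth))
    if (length(missing) > 0) {
      stop("prediction id(s) missing from truth: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    truth <- truth[names(predictions)]
  } else if (length(predictions) != length(truth)) {
    stop("unnamed predictions and truth must have equal length", call. = FALSE)
  }
  stopifnot(all(predictions %in% c("effective", "ineffective")),
            all(truth %in% c("effective", "ineffective")))
  tp <- sum(predictions == "effective" & truth == "effective")
  fp <- sum(predictions == "effective" & truth == "ineffective")
  tn <- sum(predictions == "ineffective" & truth == "ineffective")
  fn <- sum(predictions == "ineffective" & truth == "effective")
  res <- list(
    n_effective = tp + fn,
    n_ineffective = tn + fp,
    total_predicted_effective = tp + fp,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity_true = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
  class(res) <- "evaluation_result"
  res
}

#' Round half away from zero
#'
#' Plain decimal rounding with halves going up, the convention used when
#' formatting reported percentages (R's own `round()` rounds halves to
#' even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    paste0("evaluation_result: %d effective, %d ineffective\n",
           "  predicted effective (Total): %d\n",
           "  TP %d  FP %d  TN %d  FN %d\n",
           "  sensitivity %.4f   precision %s%%   specificity (TN-based) %s%%\n"),
    x$n_effective, x$n_ineffective, x$total_predicted_effective,
    x$tp, x$fp, x$tn, x$fn, x$sensitivity,
    format(round_half_up(100 * x$precision, 2)),
    format(round_half_up(100 * x$specificity_true, 2))
  ))
  invisible(x)
}

#' Benchmark-style summary row for an evaluation
#'
#' Formats one or more evaluation results as the customary benchmark table
#' for this method: algorithm, clustering feature, number of
#' predicted-effective sequences ("Total"), sensitivity, and the
#' precision-style specificity, the last two as percentages rounded half-up
#' to two decimals.
#'
#' @param results a single `evaluation_result` or a list of them.
#' @param algorithm,feature character vectors recycled across `results`.
#' @return a `data.frame` with columns `Algorithm`, `Feature`, `Total`,
#'   `Sensitivity(%)`, `Specificity(%)`.
#' @export
evaluation_table <- function(results, algorithm = "Mini-cluster",
                             feature = "Q4") {
  if (inherits(results, "evaluation_result")) results <- list(results)
  n <- length(results)
  algorithm <- rep_len(algorithm, n)
  feature <- rep_len(feature, n)
  out <- data.frame(
    Algorithm = algorithm,
    Feature = feature,
    Total = vapply(results, function(r) r$total_predicted_effective, numeric(1)),
    Sensitivity = vapply(results, function(r)
      round_half_up(100 * r$sensitivity, 2), numeric(1)),
    Specificity = vapply(results, function(r)
      round_half_up(100 * r$precision, 2), numeric(1)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out)[4:5] <- c("Sensitivity(%)", "Specificity(%)")
  out
}

#' Held-out resampling protocol for the mini-cluster classifier
#'
#' Repeatedly samples a fraction of the effective sequences (without
#' replacement) to act as the model-training and known-effective set,
#' keeps the remaining effective sequences as unlabeled queries, and
#' classifies them alongside the ineffective sequences. Two error counts
#' are recorded per repeat: held-out effective sequences called
#' ineffective, and known ineffective sequences that end up inside
#' effective-labeled clusters. The summary reports the means across
#' repeats.
#'
#' By default the ineffective sequences contribute known labels during
#' each repeat (otherwise no cluster could ever be labeled ineffective);
#' set `label_ineffective = FALSE` to withhold them and cluster them as
#' unlabeled queries instead.
#'
#' @param effective,ineffective `sirna_set`s (or character vectors) of the
#'   two truth classes.
#' @param fraction fraction of effective sequences used for training per
#'   repeat, in `(0, 1)`; the customary protocol uses 0.8.
#' @param repeats number of resampling repeats (the original protocol runs
#'   1000).
#' @param seed integer seed making the whole run reproducible.
#' @param feature clustering feature, as in [classify()].
#' @param label_ineffective logical, see above.
#' @param pseudocount passed to model fitting.
#' @return an object of class `resample_summary`: list with
#'   `mean_effective_missed`, `mean_ineffective_misidentified`,
#'   `mean_effective_missed_rate`, and a per-repeat `data.frame` `repeats`.
#' @export
resample_protocol <- function(effective, ineffective, fraction = 0.8,
                              repeats = 1000, seed = NULL,
                              feature = c("q4", "q1", "q2", "q3"),
                              label_ineffective = TRUE, pseudocount = 0) {
  feature <- match.arg(feature)
  if (!inherits(effective, "sirna_set")) effective <- sirna_set(effective)
  if (!inherits(ineffective, "sirna_set")) {
    ineffective <- sirna_set(ineffective, id = paste0("i", seq_along(ineffective)))
  }
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n_eff <- nrow(effective)
  n_train <- floor(fraction * n_eff)
  if (n_train < 1 || n_train >= n_eff) {
    stop("`fraction` leaves an empty training or test split (",
         n_train, " of ", n_eff, " effective sequences trained on)",
         call. = FALSE)
  }
  if (repeats < 1) stop("`repeats` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  per <- vapply(seq_len(repeats), function(r) {
    idx <- sample.int(n_eff, n_train)
    train_eff <- effective[idx, , drop = FALSE]
    test_eff <- effective[-idx, , drop = FALSE]
    train_eff$label <- "effective"
    test_eff$label <- "unknown"
    models <- fit_markov_models(train_eff, pseudocount = pseudocount)
    ineff <- ineffective
    ineff$label <- if (label_ineffective) "ineffective" else "unknown"
    train <- rbind(train_eff, ineff)
    class(train) <- c("sirna_set", "data.frame")
    calls <- classify(test_eff, train, models = models, feature = feature)
    clustering <- attr(calls, "clustering")
    ineff_calls <- clustering$label[seq(nrow(train_eff) + 1,
                                        length.out = nrow(ineff))]
    c(effective_missed = sum(calls == "ineffective"),
      ineffective_misidentified = sum(ineff_calls == "effective"))
  }, numeric(2))
  per <- as.data.frame(t(per))
  per$repeat_id <- seq_len(repeats)
  res <- list(
    mean_effective_missed = mean(per$effective_missed),
    mean_ineffective_misidentified = mean(per$ineffective_misidentified),
    mean_effective_missed_rate = mean(per$effective_missed) / (n_eff - n_train),
    n_effective = n_eff, n_ineffective = nrow(ineffective),
    n_train = n_train, fraction = fraction, repeats = per,
    feature = feature
  )
  class(res) <- "resample_summary"
  res
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf(
    paste0("resample_summary (%d repeats, %d/%d effective trained on, feature %s):\n",
           "  mean held-out effective called ineffective: %.2f (rate %.4f)\n",
           "  mean ineffective in effective clusters:     %.2f\n"),
    nrow(x$repeats), x$n_train, x$n_effective, x$feature,
    x$mean_effective_missed, x$mean_effective_missed_rate,
    x$mean_ineffective_misidentified
  ))
  invisible(x)
}

#' Exact one-dimensional k-means
#'
#' Finds the globally optimal sum-of-squared-error partition of
#' one-dimensional values into `k` clusters. Optimal one-dimensional
#' clusters are contiguous in sorted order, so the optimum is found by
#' dynamic programming over contiguous blocks; splits are only placed
#' between distinct values, so ties always share a cluster. Deterministic —
#' no random initialization.
#'
#' @param values numeric vector.
#' @param k number of clusters; must not exceed the number of distinct
#'   values.
#' @return list with `cluster` (integer assignment per input, clusters
#'   numbered 1..k by decreasing cluster mean) and `sse` (the optimal
#'   total within-cluster sum of squares).
#' @examples
#' kmeans_1d(c(0, 0, 1, 1, 1, 10), k = 2)$cluster
#' @export
kmeans_1d <- function(values, k = 2) {
  values <- as.numeric(values)
  n <- length(values)
  uv <- sort(unique(values))
  m <- length(uv)
  if (k > m) {
    stop("k (", k, ") exceeds the number of distinct values (", m, ")",
         call. = FALSE)
  }
  cnt <- as.numeric(table(factor(values, levels = uv)))
  s1 <- cumsum(uv * cnt)
  s2 <- cumsum(uv^2 * cnt)
  cn <- cumsum(cnt)
  block_sse <- function(i, j) {  # SSE of distinct-value blocks i..j
    s <- s1[j] - if (i > 1) s1[i - 1] else 0
    q <- s2[j] - if (i > 1) s2[i - 1] else 0
    w <- cn[j] - if (i > 1) cn[i - 1] else 0
    q - s^2 / w
  }
  # dp[c, j]: best SSE of first j blocks in c clusters
  dp <- matrix(Inf, nrow = k, ncol = m)
  back <- matrix(0L, nrow = k, ncol = m)
  dp[1, ] <- vapply(seq_len(m), function(j) block_sse(1, j), numeric(1))
  if (k > 1) {
    for (c in 2:k) {
      for (j in c:m) {
        cand <- vapply((c - 1):(j - 1), function(t) {
          dp[c - 1, t] + block_sse(t + 1, j)
        }, numeric(1))
        best <- which.min(cand)
        dp[c, j] <- cand[best]
        back[c, j] <- (c - 1) + best - 1L  # last block of previous cluster
      }
    }
  }
  # reconstruct block ranges
  bounds <- integer(k + 1)
  bounds[k + 1] <- m
  if (k > 1) {
    j <- m
    for (c in k:2) {
      j <- back[c, j]
      bounds[c] <- j
    }
  }
  block_of <- match(values, uv)
  cluster_sorted <- findInterval(block_of, bounds[-(k + 1)] + 1)
  # cluster_sorted numbers clusters ascending in value; renumber descending
  cluster <- as.integer((k + 1L) - cluster_sorted)
  list(cluster = cluster, sse = dp[k, m], k = k)
}
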