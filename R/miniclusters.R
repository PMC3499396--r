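# Mini-cluster agglomeration on a one-dimensional feature (by default the
# relative mean probability). The procedure repeatedly examines the closest
# pair of elements not yet in any cluster:
#   * the very first pair founds cluster 1;
#   * for later pairs, if either member lies at least as close (squared
#     difference, non-strict) to some already-assigned element as the two
#     pair members lie to each other, each member joins the cluster of its
#     nearest assigned element; otherwise the pair founds a new cluster;
#   * a final leftover element joins the cluster of its nearest assigned
#     element.
# Ties are broken deterministically: pairs order by (distance, smaller
# index, larger index); "nearest assigned element" prefers the smallest
# index among equidistant candidates. The non-strict comparison guarantees
# that elements with identical feature values always share a cluster.

#' Squared-difference distance between two feature values
#'
#' The distance used throughout the mini-cluster procedure:
#' `(qa - qb)^2`. Symmetric, zero exactly when the values coincide.
#'
#' @param qa,qb numeric feature values (vectors recycle).
#' @return non-negative numeric vector.
#' @export
pairwise_distance <- function(qa, qb) {
  (qa - qb)^2
}

# internal: closest unassigned pair under the (distance, i, j) order.
# `values` full vector, `un` sorted vector of unassigned indices (>= 2).
closest_unassigned_pair <- function(values, un) {
  v <- values[un]
  o <- order(v, un)
  sv <- v[o]
  dmin <- min((sv[-1] - sv[-length(sv)])^2)  # min over adjacent sorted pairs
  s <- sqrt(dmin)
  # smallest index i that has a partner at squared distance exactly dmin
  has_partner <- vapply(seq_along(un), function(k) {
    any((v - v[k])^2 == dmin & un != un[k])
  }, logical(1))
  i <- min(un[has_partner])
  vi <- values[i]
  cand <- un[(v - vi)^2 == dmin & un != i]
  c(i, min(cand))
}

#' Build mini-clusters from one-dimensional feature values
#'
#' Agglomerates the values into small clusters by repeated nearest-pair
#' examination (see Details). Every input index ends up in exactly one
#' cluster, and inputs with identical values are guaranteed to share a
#' cluster. Clusters are numbered in order of creation.
#'
#' @details The procedure orders all unordered index pairs by increasing
#' squared difference, breaking ties by the smaller and then the larger
#' index. It repeatedly takes the first pair whose members are both
#' unassigned. The first such pair founds the first cluster. For a later
#' pair `(i, j)` at distance `d`, each member's minimum distance to the
#' already-assigned elements is computed; if either minimum is less than or
#' equal to `d`, each of `i` and `j` joins the cluster of its nearest
#' assigned element (possibly two different clusters), otherwise `(i, j)`
#' founds a new cluster. When a single element remains unassigned it joins
#' the cluster of its nearest assigned element.
#'
#' @param values numeric vector of feature values (non-empty, finite).
#' @return an object of class `mini_clustering`: a list with elements
#'   `cluster` (integer assignment per input index, numbered in creation
#'   order), `n`, and `values`.
#' @examples
#' build_mini_clusters(c(0.0088, 0.0088, 0.0029, 0.0029, 0, 0))$cluster
#' @export
build_mini_clusters <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  cluster <- rep(NA_integer_, n)
  if (n == 1) {
    cluster[1] <- 1L
  } else {
    n_clusters <- 0L
    assigned <- integer(0)  # kept sorted ascending
    repeat {
      un <- which(is.na(cluster))
      if (length(un) < 2) break
      pair <- closest_unassigned_pair(values, un)
      i <- pair[1]; j <- pair[2]
      d <- pairwise_distance(values[i], values[j])
      if (n_clusters == 0L) {
        n_clusters <- 1L
        cluster[c(i, j)] <- 1L
      } else {
        da <- pairwise_distance(values[assigned], values[i])
        db <- pairwise_distance(values[assigned], values[j])
        if (min(da) <= d || min(db) <= d) {
          cluster[i] <- cluster[assigned[which.min(da)]]
          cluster[j] <- cluster[assigned[which.min(db)]]
        } else {
          n_clusters <- n_clusters + 1L
          cluster[c(i, j)] <- n_clusters
        }
      }
      assigned <- sort(c(assigned, i, j))
    }
    left <- which(is.na(cluster))
    if (length(left) == 1) {
      da <- pairwise_distance(values[assigned], values[left])
      cluster[left] <- cluster[assigned[which.min(da)]]
    }
  }
  structure(list(cluster = cluster, n = n, values = values),
            class = "mini_clustering")
}

#' @export
print.mini_clustering <- function(x, ...) {
  k <- length(unique(x$cluster))
  cat(sprintf("mini_clustering: %d element(s) in %d cluster(s)\n", x$n, k))
  if (!is.null(x$label)) {
    tb <- table(x$label[!duplicated(x$cluster)])
    cat("cluster labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Label mini-clusters from known efficacies
#'
#' A cluster is `effective` if at least one of its members is known
#' effective, `ineffective` if it has known members and all of them are
#' ineffective, and `uncertain` if none of its members has a known label.
#'
#' @param clustering a `mini_clustering`.
#' @param known named vector or plain vector mapping input indices to
#'   `"effective"`/`"ineffective"`; either a character vector with names
#'   giving indices, or a character vector of per-index labels (with
#'   `"unknown"`/`NA` for unlabeled indices).
#' @return the clustering with added elements `label` (per element) and
#'   `cluster_label` (per cluster id).
#' @export
label_clusters <- function(clustering, known) {
  stopifnot(inherits(clustering, "mini_clustering"))
  n <- clustering$n
  lab <- rep(NA_character_, n)
  if (!is.null(names(known))) {
    idx <- as.integer(names(known))
    lab[idx] <- as.character(known)
  } else if (length(known) == n) {
    lab <- as.character(known)
  } else {
    stop("`known` must be named by index or cover every element", call. = FALSE)
  }
  lab[lab %in% "unknown"] <- NA_character_
  ok <- is.na(lab) | lab %in% c("effective", "ineffective")
  if (!all(ok)) stop("known labels must be 'effective' or 'ineffective'",
                     call. = FALSE)
  ids <- sort(unique(clustering$cluster))
  cluster_label <- vapply(ids, function(cl) {
    members <- lab[clustering$cluster == cl]
    if (any(members == "effective", na.rm = TRUE)) "effective"
    else if (any(members == "ineffective", na.rm = TRUE)) "ineffective"
    else "uncertain"
  }, character(1))
  names(cluster_label) <- ids
  clustering$known <- lab
  clustering$cluster_label <- cluster_label
  clustering$label <- unname(cluster_label[as.character(clustering$cluster)])
  clustering
}

#' Merge uncertain mini-clusters into their nearest determined cluster
#'
#' Each cluster with no known-labeled member adopts the label of (and is
#' merged into) the determined cluster at minimum single-linkage
#' squared-difference distance, i.e. the minimum over all cross-cluster
#' member pairs. Determined clusters are never relabeled. When two
#' determined clusters are exactly equidistant from an uncertain one, the
#' tie resolves toward an effective cluster, preserving the
#' sensitivity-first behaviour of the procedure.
#'
#' @param clustering a labeled `mini_clustering` (see [label_clusters()]).
#' @return the clustering with every element in a determined cluster; the
#'   `label` element carries the final per-element efficacy call.
#' @export
merge_uncertain <- function(clustering) {
  stopifnot(inherits(clustering, "mini_clustering"))
  if (is.null(clustering$cluster_label)) {
    stop("clustering is unlabeled; call label_clusters() first", call. = FALSE)
  }
  cl_lab <- clustering$cluster_label
  uncertain <- names(cl_lab)[cl_lab == "uncertain"]
  if (length(uncertain) == 0) return(clustering)
  determined <- names(cl_lab)[cl_lab != "uncertain"]
  if (length(determined) == 0) {
    stop("no determined cluster to merge into: no training labels reached ",
         "any cluster", call. = FALSE)
  }
  values <- clustering$values
  cluster <- clustering$cluster
  # prefer effective targets on exact distance ties
  det_order <- determined[order(cl_lab[determined] != "effective",
                                as.integer(determined))]
  det_values <- lapply(det_order, function(a) values[cluster == as.integer(a)])
  targets <- vapply(uncertain, function(b) {
    vb <- values[cluster == as.integer(b)]
    d <- vapply(det_values, function(va) min(outer(va, vb, pairwise_distance)),
                numeric(1))
    det_order[which.min(d)]
  }, character(1))
  for (b in uncertain) {
    cluster[clustering$cluster == as.integer(b)] <- as.integer(targets[[b]])
  }
  kept <- sort(unique(cluster))
  clustering$cluster <- cluster
  clustering$cluster_label <- cl_lab[as.character(kept)]
  clustering$label <- unname(clustering$cluster_label[as.character(cluster)])
  clustering
}

#' Cluster assignments as a data frame
#'
#' @param x a `mini_clustering`.
#' @param ids optional identifiers (defaults to `s1, s2, ...`).
#' @param ... unused.
#' @return a `data.frame` with columns `id`, `value`, `cluster_id` and,
#'   when the clustering is labeled, `cluster_label`.
#' @export
as.data.frame.mini_clustering <- function(x, ids = NULL, ...) {
  if (is.null(ids)) ids <- paste0("s", seq_len(x$n))
  out <- data.frame(id = ids, value = x$values, cluster_id = x$cluster,
                    stringsAsFactors = FALSE)
  if (!is.null(x$label)) out$cluster_label <- x$label
  out
}
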