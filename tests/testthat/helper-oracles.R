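# Independent reference implementations used as oracles. These are written
# directly from the definitions (scalar loops, explicit pair lists) and
# share no code with the package internals they check.

# chain probability by an explicit per-position loop over one sequence
naive_chain_probability <- function(model, s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  h <- model$order
  p <- model$initial[paste(ch[seq_len(h)], collapse = "")]
  p <- if (is.na(p)) 0 else unname(p)
  for (j in (h + 1):length(ch)) {
    ctx <- paste(ch[(j - h):(j - 1)], collapse = "")
    tr <- model$transitions[[as.character(j)]]
    p <- p * tr[ctx, ch[j]]
  }
  p
}

# literal realization of the nearest-pair agglomeration: materialize every
# unordered pair, sort by (distance, i, j), and rescan the full list after
# every assignment
naive_mini_clusters <- function(values) {
  n <- length(values)
  cl <- rep(NA_integer_, n)
  if (n == 1) return(1L)
  pr <- expand.grid(j = seq_len(n), i = seq_len(n))
  pr <- pr[pr$i < pr$j, c("i", "j")]
  d <- (values[pr$i] - values[pr$j])^2
  o <- order(d, pr$i, pr$j)
  pr <- pr[o, ]
  d <- d[o]
  nk <- 0L
  repeat {
    open <- which(is.na(cl[pr$i]) & is.na(cl[pr$j]))
    if (length(open) == 0) break
    h <- open[1]
    i <- pr$i[h]; j <- pr$j[h]; dd <- d[h]
    if (nk == 0L) {
      nk <- 1L
      cl[c(i, j)] <- 1L
    } else {
      asg <- which(!is.na(cl))
      di <- (values[asg] - values[i])^2
      dj <- (values[asg] - values[j])^2
      if (min(di) <= dd || min(dj) <= dd) {
        cl[i] <- cl[asg[which.min(di)]]
        cl[j] <- cl[asg[which.min(dj)]]
      } else {
        nk <- nk + 1L
        cl[c(i, j)] <- nk
      }
    }
  }
  left <- which(is.na(cl))
  if (length(left) == 1) {
    asg <- which(!is.na(cl))
    cl[left] <- cl[asg[which.min((values[asg] - values[left])^2)]]
  }
  cl
}

# canonical form of a partition: list of member-index sets, sorted
canonical_partition <- function(cluster) {
  parts <- unname(split(seq_along(cluster), cluster))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, numeric(1), 1))]
}

# total within-cluster sum of squares of a 1-D partition
partition_sse <- function(values, cluster) {
  sum(vapply(unique(cluster), function(cl) {
    v <- values[cluster == cl]
    sum((v - mean(v))^2)
  }, numeric(1)))
}
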