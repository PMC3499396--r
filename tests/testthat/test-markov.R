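test_that("relative frequencies match hand-tallied counts on a tiny set", {
  m <- fit_markov(c("UAAUC", "UACCG", "CGAUC", "CGCCG"), order = 1)
  expect_equal(unname(m$initial[c("U", "C")]), c(0.5, 0.5))
  expect_equal(sum(m$initial), 1)
  # position 2: U is always followed by A, C always by G
  expect_equal(m$transitions[["2"]]["U", "A"], 1)
  expect_equal(m$transitions[["2"]]["C", "G"], 1)
  # position 3: contexts A (UAAUC, UACCG) and G (CGAUC, CGCCG) each split A/C
  expect_equal(m$transitions[["3"]]["A", c("A", "C")],
               c(A = 0.5, C = 0.5))
  expect_equal(m$transitions[["3"]]["G", c("A", "C")],
               c(A = 0.5, C = 0.5))
  # unobserved context at an interior position has all-zero conditionals
  expect_equal(sum(m$transitions[["2"]]["A", ]), 0)
})

test_that("degenerate training (copies of one sequence) gives unit transitions", {
  m <- fit_markov(rep("UAAUC", 5), order = 1)
  expect_equal(unname(m$initial["U"]), 1)
  p <- sequence_probability(m, "UAAUC")
  expect_equal(p, 1)
})

test_that("fit_markov rejects bad inputs with distinct errors", {
  expect_error(fit_markov(character(0), 1), "empty training")
  expect_error(fit_markov(c("UAAUC", "UAAU"), 1), "heterogeneous")
  expect_error(fit_markov(c("UAAUC", "UACCG"), 4), "order")
  expect_error(fit_markov(c("UAAUC"), 1, pseudocount = -1), "non-negative")
  expect_error(fit_markov(c("UAXUC"), 1), "illegal character")
})

test_that("every estimated distribution sums to one", {
  set.seed(11)
  seqs <- generate_random_sirnas(200, length = 9)$seq
  for (h in 1:3) {
    m <- fit_markov(seqs, order = h)
    expect_equal(sum(m$initial), 1, tolerance = 1e-12)
    for (j in names(m$transitions)) {
      rs <- rowSums(m$transitions[[j]])
      expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
    }
  }
})

test_that("sequence_probability agrees with a naive per-position loop", {
  set.seed(7)
  train <- generate_random_sirnas(60, length = 8)$seq
  probes <- generate_random_sirnas(40, length = 8)$seq
  for (h in 1:3) {
    m <- fit_markov(train, order = h)
    got <- sequence_probability(m, probes)
    want <- vapply(probes, naive_chain_probability, numeric(1), model = m)
    expect_equal(got, unname(want))
  }
})

test_that("probabilities under the group-X chain match the reference scores", {
  m <- group_x_model(5)
  expect_equal(sequence_probability(m, "UAAUC"), 0.0087890625)
  expect_equal(sequence_probability(m, "AACGA"), 0)  # A impossible at position 1
  # fitting on the complete enumeration of 5-mers gives the exactly uniform
  # chain, under which every 5-mer has probability 0.25^5
  all5 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "U")), 5),
                                      stringsAsFactors = FALSE))
  uni <- fit_markov(all5, order = 1)
  expect_equal(sequence_probability(uni, "AGCUA"), 0.25^5)
})

test_that("length mismatch between model and sequence is an error", {
  m <- group_x_model(5)
  expect_error(sequence_probability(m, "UAAUCA"), "length")
})

test_that("relative mean probability averages only the positive chains", {
  expect_equal(relative_mean_probability(0, 0, 0), 0)
  expect_equal(relative_mean_probability(0.42, 0.42, 0.42), 0.42)
  expect_equal(relative_mean_probability(0.3, 0, 0.1), 0.2)
  expect_error(relative_mean_probability(1.2, 0, 0), "\\[0, 1\\]")
  expect_error(relative_mean_probability(-0.1, 0, 0), "\\[0, 1\\]")
  # bracketing: q4 always lies between the extreme positive members
  set.seed(42)
  for (i in 1:200) {
    q <- stats::runif(3) * stats::rbinom(3, 1, 0.6)
    q4 <- relative_mean_probability(q[1], q[2], q[3])
    pos <- q[q > 0]
    if (length(pos) == 0) {
      expect_identical(q4, 0)
    } else {
      expect_gte(q4, min(pos))
      expect_lte(q4, max(pos))
    }
  }
})

test_that("profile batch output equals one-by-one scoring and keeps order", {
  set.seed(5)
  train <- generate_random_sirnas(50, length = 7)
  models <- fit_markov_models(train)
  probes <- generate_random_sirnas(20, length = 7)
  prof <- profile_sequences(models, probes)
  expect_equal(nrow(prof), 20)
  expect_equal(prof$id, probes$id)
  single <- do.call(rbind, lapply(probes$seq, function(s) {
    profile_sequences(models, s)[, -1]
  }))
  expect_equal(prof[, -1], single, ignore_attr = TRUE)
  empty <- profile_sequences(models, character(0))
  expect_equal(nrow(empty), 0)
})

test_that("fitting order 1 recovers the group-X conditionals, improving with n", {
  err_at <- function(n, seed) {
    m <- fit_markov(generate_group_x(n, seed = seed), order = 1)
    truth <- group_x_model(5)
    max(abs(m$transitions[["2"]][c("U", "C"), ] -
            truth$transitions[["2"]][c("U", "C"), ]))
  }
  e_small <- err_at(1000, seed = 101)
  e_big <- err_at(100000, seed = 101)
  expect_lt(e_big, e_small)
  m <- fit_markov(generate_group_x(10000, seed = 202), order = 1)
  expect_lt(abs(m$transitions[["2"]]["U", "A"] - 0.75), 0.02)
  expect_equal(m$transitions[["2"]]["C", "G"], 1)
})

test_that("pseudocount keeps every valid-alphabet sequence away from zero", {
  train <- c("UAAUC", "UACCG", "CGAUC", "CGCCG")
  probes <- generate_random_sirnas(50, length = 5, seed = 9)$seq
  for (h in 1:3) {
    m0 <- fit_markov(train, order = h)
    m1 <- fit_markov(train, order = h, pseudocount = 0.5)
    p0 <- sequence_probability(m0, probes)
    p1 <- sequence_probability(m1, probes)
    expect_true(any(p0 == 0))  # unseen events are hard zeros unsmoothed
    expect_true(all(p1 > 0))
    expect_equal(sum(m1$initial), 1, tolerance = 1e-12)
  }
})

test_that("entropy score is |ln q4|, decreasing, and undefined at zero", {
  expect_equal(entropy_score(1), 0)
  expect_equal(entropy_score(0.0087890625), abs(log(9 / 1024)))
  expect_equal(entropy_score(0.0087890625), 4.7342472, tolerance = 1e-7)
  q <- sort(stats::runif(20, 0.01, 1))
  expect_true(all(diff(entropy_score(q)) <= 0))
  expect_error(entropy_score(0), "\\(0, 1\\]")
})

test_that("a fitted model round-trips through its JSON serialization", {
  set.seed(13)
  train <- generate_random_sirnas(40, length = 6)$seq
  for (h in c(1, 3)) {
    m <- fit_markov(train, order = h)
    path <- withr::local_tempfile(fileext = ".json")
    write_markov_model(m, path)
    m2 <- read_markov_model(path)
    expect_identical(m2$order, m$order)
    expect_equal(m2$initial, m$initial)
    for (j in names(m$transitions)) {
      expect_equal(m2$transitions[[j]], m$transitions[[j]])
    }
    probes <- generate_random_sirnas(20, length = 6)$seq
    expect_identical(sequence_probability(m2, probes),
                     sequence_probability(m, probes))
  }
})

test_that("homogeneous estimation pools transition counts across positions", {
  seqs <- c("UAAAA", "UAUUU")  # A->A three times, U->U twice, U->A twice, A->U once
  m <- fit_markov(seqs, order = 1, position_specific = FALSE)
  tr <- m$transitions[["2"]]
  expect_equal(tr["A", "A"], 3 / 4)
  expect_equal(tr["A", "U"], 1 / 4)
  expect_equal(tr["U", "A"], 1 / 2)
  expect_equal(tr["U", "U"], 1 / 2)
  expect_identical(m$transitions[["2"]], m$transitions[["5"]])
})
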