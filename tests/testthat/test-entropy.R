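test_that("self match-length profiles match the brute-force values", {
  # frozen values computed with the brute-force oracle
  expect_identical(self_match_lengths(tr("u", c("z", "z", "z", "z")))$lambdas,
                   c(1L, 2L, 3L, 2L))
  expect_identical(self_match_lengths(tr("u", c("x", "y", "x", "y", "x")))$lambdas,
                   c(1L, 1L, 3L, 3L, 2L))
  # all-distinct: no repeats possible
  expect_identical(self_match_lengths(tr("u", letters[1:7]))$lambdas,
                   rep(1L, 7))
  # oracle flag routes to the reference implementation, same result
  A <- tr("u", c("a", "b", "a", "a", "b", "a", "b"))
  expect_identical(self_match_lengths(A)$lambdas,
                   self_match_lengths(A, oracle = TRUE)$lambdas)
})

test_that("the three R/C++ implementations agree on random sequences", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    a <- sample.int(sample(2:5, 1), n, replace = TRUE)
    ta <- sort(runif(n, 0, 50))
    b <- sample.int(max(a), sample(5:30, 1), replace = TRUE)
    tb <- sort(runif(length(b), 0, 50))
    expect_identical(mobflow:::self_lambda_oracle(a), r_self_lambda(a))
    expect_identical(mobflow:::self_lambda_fast(a), r_self_lambda(a))
    for (tc in c(TRUE, FALSE)) {
      expect_identical(mobflow:::cross_lambda_oracle(a, ta, b, tb, tc),
                       r_cross_lambda(a, ta, b, tb, tc))
      expect_identical(mobflow:::cross_lambda_fast(a, ta, b, tb, tc),
                       r_cross_lambda(a, ta, b, tb, tc))
    }
  }
})

test_that("match-length profiles are invariant under symbol relabeling", {
  # underpins canonical-pattern enumeration: profiles depend only on the
  # equality pattern of the sequence, not on the labels
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    sig <- sample(2:6, 1)
    a <- sample.int(sig, n, replace = TRUE)
    perm <- sample(sig)
    expect_identical(mobflow:::self_lambda_fast(a),
                     mobflow:::self_lambda_fast(perm[a]))
    b <- sample.int(sig, n, replace = TRUE)
    ta <- as.numeric(1:n); tb <- ta - 0.5
    expect_identical(mobflow:::cross_lambda_fast(a, ta, b, tb, TRUE),
                     mobflow:::cross_lambda_fast(perm[a], ta, perm[b], tb, TRUE))
  }
})

test_that("entropy rate follows the match-length estimator", {
  A <- tr("u", c("x", "y", "x", "y", "x"))
  est <- entropy_rate(A)
  expect_equal(est$value, 5 * log2(5) / 10)
  expect_s3_class(est, "entropy_estimate")
  # all-distinct sequence: exactly log2(N)
  expect_equal(entropy_rate(tr("u", letters[1:16]))$value, 4)
  expect_error(entropy_rate(tr("u", "a", 1)), "N < 2")
})

test_that("shannon entropy of visit frequencies is the closed form", {
  expect_equal(shannon_entropy(tr("u", rep("a", 10))), 0)
  expect_equal(shannon_entropy(tr("u", rep(c("a", "b", "c", "d"), 5))), 2)
  expect_equal(shannon_entropy(tr("u", c("a", "a", "b", "c"))), 1.5)
})

test_that("cross-entropy handles informative, disjoint and time-gated alters", {
  A <- tr("a", c("x", "y"), c(10, 11))
  B <- tr("b", c("x", "y"), c(1, 2))
  expect_identical(cross_match_lengths(A, B)$lambdas, c(3L, 2L))
  expect_equal(cross_entropy(A, B)$value, 2 * 1 / 5)
  # disjoint alter: no matches, Lambda all 1, value exactly log2(N_B)
  D <- tr("d", c("q", "r", "q"), c(1, 2, 3))
  expect_identical(cross_match_lengths(A, D)$lambdas, c(1L, 1L))
  expect_equal(cross_entropy(A, D)$value, log2(3))
  expect_equal(unname(cross_entropy(A, D)$weights), 0L)
  # only B events strictly before t_i count as previous
  B2 <- tr("b", c("x", "y"), c(10.5, 11.5))
  expect_identical(cross_match_lengths(A, B2)$lambdas, c(1L, 1L))
  # simultaneous events are not previous: B's y at exactly t_2 is unusable
  B3 <- tr("b", c("x", "y"), c(9, 11))
  expect_identical(cross_match_lengths(A, B3)$lambdas, c(2L, 1L))
  expect_error(cross_entropy(tr("a", "x", 1), tr("b", "x", 1)), "N_B >= 2")
})

test_that("cross-entropy is bounded by log2(N_B) and relaxing time helps", {
  set.seed(21)
  for (rep in 1:15) {
    A <- tr("a", sample(letters[1:4], 20, TRUE), sort(runif(20, 0, 100)))
    B <- tr("b", sample(letters[1:5], 25, TRUE), sort(runif(25, 0, 100)))
    expect_lte(cross_entropy(A, B)$value, log2(B$N))
    lam_tc <- cross_match_lengths(A, B, TRUE)$lambdas
    lam_un <- cross_match_lengths(A, B, FALSE)$lambdas
    expect_true(all(lam_un >= lam_tc))
  }
})

test_that("an earlier copy of the ego is at least as predictive as the ego", {
  set.seed(5)
  loc <- sample(letters[1:5], 400, TRUE)
  A <- tr("a", loc, 1001:1400)
  B <- tr("a", loc, 1:400)
  expect_lte(cross_entropy(A, B)$value, entropy_rate(A)$value)
})

test_that("cumulative cross-entropy reduces, weights and maxes correctly", {
  A <- tr("a", c("x", "y"), c(10, 11))
  B <- tr("b", c("x", "y"), c(1, 2))
  D <- tr("d", c("q", "r", "q"), c(1, 2, 3))
  # singleton reduction, to full precision
  expect_identical(cumulative_cross_entropy(A, list(B))$value,
                   cross_entropy(A, B)$value)
  # disjoint alter adds nothing: profile and value equal the informative
  # alter's, and its weight is zero
  cum <- cumulative_cross_entropy(A, list(B, D))
  expect_identical(as.integer(cum$profile$lambdas),
                   cross_match_lengths(A, B)$lambdas)
  expect_equal(cum$value, cross_entropy(A, B)$value)
  expect_equal(unname(cum$weights), c(2L, 0L))
  # reference length is the match-weighted mean of alter lengths
  expect_equal(cum$N_ref, B$N)
  # all-disjoint set: unweighted mean reference and a no-match flag
  cum0 <- cumulative_cross_entropy(A, list(D))
  expect_true(cum0$no_match)
  expect_equal(cum0$N_ref, D$N)
})

test_that("adding an alter never decreases any cumulative match length", {
  set.seed(31)
  for (rep in 1:10) {
    A <- tr("a", sample(letters[1:4], 30, TRUE), sort(runif(30, 0, 100)))
    alters <- lapply(1:3, function(j) {
      tr(paste0("b", j), sample(letters[1:4], 25, TRUE), sort(runif(25, 0, 100)))
    })
    lam2 <- cumulative_cross_entropy(A, alters[1:2])$profile$lambdas
    lam3 <- cumulative_cross_entropy(A, alters)$profile$lambdas
    expect_true(all(lam3 >= lam2))
  }
})

test_that("including the ego's past joins the ego under the strict time gate", {
  set.seed(41)
  A <- tr("a", sample(letters[1:3], 60, TRUE), sort(runif(60, 0, 100)))
  B <- tr("b", sample(letters[1:3], 40, TRUE), sort(runif(40, 0, 100)))
  without <- cumulative_cross_entropy(A, list(B))
  with_ego <- cumulative_cross_entropy(A, list(B), include_ego_past = TRUE)
  expect_true(all(with_ego$profile$lambdas >= without$profile$lambdas))
  expect_true(A$user_id %in% with_ego$alter_ids)
})

test_that("the alternative alter-weight rule counts only set maxima", {
  set.seed(51)
  A <- tr("a", sample(letters[1:3], 40, TRUE), sort(runif(40, 0, 100)))
  alters <- lapply(1:2, function(j) {
    tr(paste0("b", j), sample(letters[1:3], 30, TRUE), sort(runif(30, 0, 100)))
  })
  any_w <- cumulative_cross_entropy(A, alters, weight_rule = "any_match")$weights
  max_w <- cumulative_cross_entropy(A, alters, weight_rule = "max_attaining")$weights
  expect_true(all(max_w <= any_w))
})

test_that("estimates serialize to JSON records", {
  A <- tr("a", c("x", "y", "x"), 1:3)
  B <- tr("b", c("x", "y"), c(0.1, 0.2))
  rec <- jsonlite::fromJSON(estimate_json(cross_entropy(A, B)))
  expect_equal(rec$user, "a")
  expect_equal(rec$mode, "cross")
  expect_equal(rec$N_A, 3)
})
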