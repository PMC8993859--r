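#' Match-length profile of a trajectory against its own past
#'
#' For each position i of the sequence, the profile records
#' \eqn{\Lambda_i = L_i + 1}, where \eqn{L_i} is the length of the longest
#' contiguous substring starting at i that also occurs contiguously within
#' the prefix (positions 1..i-1), capped at \eqn{N - i + 1}. \eqn{\Lambda_1 = 1}.
#' Equivalently, \eqn{\Lambda_i} is the length of the shortest substring
#' starting at i not seen previously. These match lengths drive the
#' Lempel-Ziv entropy-rate estimator of [entropy_rate()].
#'
#' @param A A [trajectory()].
#' @param oracle If `TRUE`, use the quadratic brute-force reference
#'   implementation instead of the indexed fast path (they agree exactly;
#'   the oracle exists for verification).
#' @return A `match_length_profile`: list with integer `lambdas`, `mode`
#'   (`"self"`), and `constraint` description.
#' @export
self_match_lengths <- function(A, oracle = FALSE) {
  A <- as_trajectory(A)
  codes <- encode_locs(A$loc)$a
  lam <- if (oracle) self_lambda_oracle(codes) else self_lambda_fast(codes)
  structure(list(lambdas = lam, mode = "self", constraint = "index-prefix"),
            class = "match_length_profile")
}

#' Cross-parsed match-length profile of one trajectory in another
#'
#' \eqn{\Lambda_i(A|B) = L_i + 1}, where \eqn{L_i} is the length of the
#' longest contiguous substring of A starting at position i that occurs
#' contiguously within the portion of B whose timestamps are strictly
#' earlier than \eqn{t_i} (when `time_constrained`; otherwise within all of
#' B). Events of B at exactly \eqn{t_i} are not "previous". If no symbol
#' matches, \eqn{\Lambda_i = 1}.
#'
#' @param A Target trajectory (the ego).
#' @param B Reference trajectory (the alter).
#' @param time_constrained Restrict B to events before each target event
#'   (default `TRUE`, the estimator's definition).
#' @param oracle Use the brute-force reference implementation.
#' @return A `match_length_profile` with `mode = "cross"`.
#' @export
cross_match_lengths <- function(A, B, time_constrained = TRUE, oracle = FALSE) {
  A <- as_trajectory(A); B <- as_trajectory(B)
  enc <- encode_locs(A$loc, B$loc)
  f <- if (oracle) cross_lambda_oracle else cross_lambda_fast
  lam <- f(enc$a, A$time, enc$b, B$time, time_constrained)
  structure(list(lambdas = lam, mode = "cross",
                 constraint = if (time_constrained) "time-constrained" else "unconstrained"),
            class = "match_length_profile")
}

#' @export
print.match_length_profile <- function(x, ...) {
  cat(sprintf("<match_length_profile> mode %s (%s), N = %d, sum(Lambda) = %d\n",
              x$mode, x$constraint, length(x$lambdas), sum(x$lambdas)))
  invisible(x)
}

new_entropy_estimate <- function(value, mode, user, N_A, N_ref, profile,
                                 alter_ids = NULL, weights = NULL,
                                 no_match = FALSE) {
  structure(list(value = value, mode = mode, user = user, N_A = N_A,
                 N_ref = N_ref, profile = profile, alter_ids = alter_ids,
                 weights = weights, no_match = no_match),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate> %s: %.4f bits (user %s, N_A = %d, reference length %.1f)\n",
              x$mode, x$value, x$user, x$N_A, x$N_ref))
  if (isTRUE(x$no_match)) cat("  flagged: no alter produced any match\n")
  invisible(x)
}

#' Entropy rate of a trajectory (bits per visit)
#'
#' The non-parametric match-length estimator
#' \deqn{\hat S_A = \frac{N \log_2 N}{\sum_{i=1}^N \Lambda_i},}
#' which accounts for both visit frequencies and temporal ordering. For a
#' sequence with no repeated structure it equals \eqn{\log_2 N}; in the
#' absence of temporal structure it converges to the Shannon entropy of the
#' visit distribution.
#'
#' @param A A [trajectory()] with at least two events.
#' @return An `entropy_estimate` (`mode = "self"`) with the profile attached.
#' @examples
#' tr <- trajectory("u", c("x", "y", "x", "y", "x"), 1:5)
#' entropy_rate(tr)$value # 5 * log2(5) / 10
#' @export
entropy_rate <- function(A) {
  A <- as_trajectory(A)
  if (A$N < 2) stop("entropy rate undefined for N < 2")
  prof <- self_match_lengths(A)
  val <- A$N * log2(A$N) / sum(prof$lambdas)
  new_entropy_estimate(val, "self", A$user_id, A$N, A$N, prof)
}

#' Shannon entropy of the visit distribution (bits)
#'
#' Ignores temporal order entirely: \eqn{-\sum_\ell p_\ell \log_2 p_\ell}
#' over empirical visit frequencies.
#'
#' @param A A [trajectory()].
#' @return Entropy in bits (plain numeric).
#' @export
shannon_entropy <- function(A) {
  A <- as_trajectory(A)
  p <- tabulate(factor(A$loc)) / A$N
  -sum(p * log2(p))
}

#' Cross-entropy of an ego's sequence given an alter's past (bits)
#'
#' \deqn{\hat S_{A|B} = \frac{N_A \log_2 N_B}{\sum_{i=1}^{N_A} \Lambda_i(A|B)},}
#' the information needed to encode A's next visit using only B's earlier
#' history. Bounded above by \eqn{\log_2 N_B}, attained exactly when B never
#' matches A.
#'
#' @param A Ego trajectory (\eqn{N_A \ge 1}).
#' @param B Alter trajectory (\eqn{N_B \ge 2}).
#' @param time_constrained Passed to [cross_match_lengths()].
#' @return An `entropy_estimate` (`mode = "cross"`).
#' @export
cross_entropy <- function(A, B, time_constrained = TRUE) {
  A <- as_trajectory(A); B <- as_trajectory(B)
  if (A$N < 1 || B$N < 2) stop("cross-entropy needs N_A >= 1 and N_B >= 2")
  prof <- cross_match_lengths(A, B, time_constrained)
  w <- sum(prof$lambdas > 1L)
  val <- A$N * log2(B$N) / sum(prof$lambdas)
  new_entropy_estimate(val, "cross", A$user_id, A$N, B$N, prof,
                       alter_ids = B$user_id, weights = setNames(w, B$user_id))
}

#' Cumulative cross-entropy over a set of alters (bits)
#'
#' Generalizes [cross_entropy()] to a set \eqn{\mathcal B}:
#' \eqn{\Lambda_i(A|\mathcal B) = \max_B \Lambda_i(A|B)} is the longest
#' cross-parsed match over any alter, and the reference length is the
#' match-weighted mean \eqn{N_{A\mathcal B} = \sum w_B N_B / \sum w_B},
#' where \eqn{w_B} counts the positions of A at which B yields a non-empty
#' match (\eqn{\Lambda_i(A|B) > 1}). With a singleton set the estimate
#' equals [cross_entropy()] exactly. If no alter matches anywhere, the
#' unweighted mean length is used and the estimate is flagged `no_match`.
#'
#' @param A Ego trajectory.
#' @param alters List of alter trajectories (rank order is irrelevant here).
#' @param include_ego_past If `TRUE`, A's own sequence joins the alter set
#'   under the same strictly-earlier time constraint, so the estimate
#'   measures alters plus the ego's own past.
#' @param weight_rule `"any_match"` (default): \eqn{w_B} counts positions
#'   where B matches at all; `"max_attaining"`: positions where B attains
#'   the set-maximum match length.
#' @return An `entropy_estimate` (`mode = "cumulative"`) carrying per-alter
#'   weights.
#' @export
cumulative_cross_entropy <- function(A, alters, include_ego_past = FALSE,
                                     weight_rule = c("any_match", "max_attaining")) {
  weight_rule <- match.arg(weight_rule)
  A <- as_trajectory(A)
  if (inherits(alters, "trajectory")) alters <- list(alters)
  if (length(alters) == 0L) stop("alter set must be nonempty")
  if (include_ego_past) alters <- c(alters, list(A))
  ids <- vapply(alters, function(B) B$user_id, character(1))
  lens <- vapply(alters, function(B) B$N, numeric(1))
  lam_mat <- vapply(alters, function(B) {
    as.integer(cross_match_lengths(A, B, time_constrained = TRUE)$lambdas)
  }, integer(A$N))
  lam_mat <- matrix(lam_mat, nrow = A$N)
  lam <- apply(lam_mat, 1, max)
  w <- if (weight_rule == "any_match") {
    colSums(lam_mat > 1L)
  } else {
    colSums(lam_mat == lam & lam_mat > 1L)
  }
  no_match <- all(w == 0)
  N_ref <- if (no_match) mean(lens) else sum(w * lens) / sum(w)
  prof <- structure(list(lambdas = lam, mode = "cumulative",
                         constraint = "time-constrained"),
                    class = "match_length_profile")
  val <- A$N * log2(N_ref) / sum(lam)
  new_entropy_estimate(val, "cumulative", A$user_id, A$N, N_ref, prof,
                       alter_ids = ids, weights = setNames(w, ids),
                       no_match = no_match)
}

#' Serialize an entropy or predictability estimate to JSON
#' @param est An `entropy_estimate` or `predictability_estimate`.
#' @return A JSON string.
#' @export
estimate_json <- function(est) {
  rec <- list(user = est$user, mode = est$mode, value_bits = est$value,
              N_A = est$N_A, reference_length = est$N_ref,
              alter_ids = est$alter_ids, weights = as.list(est$weights))
  if (!is.null(est$pi)) {
    rec$pi <- est$pi
    rec$clipped <- est$clipped
  }
  jsonlite::toJSON(rec[!vapply(rec, is.null, logical(1))],
                   auto_unbox = TRUE, digits = NA)
}
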