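#' Fano-bound predictability from an entropy and a location count
#'
#' Inverts Fano's inequality
#' \deqn{S = H(\Pi) + (1 - \Pi)\log_2(n - 1)}
#' for the predictability \eqn{\Pi}, the upper bound on how often an ideal
#' algorithm can guess the next location among `n` alternatives given a
#' source with entropy `S` bits. The right-hand side decreases strictly from
#' \eqn{\log_2 n} at \eqn{\Pi = 1/n} to 0 at \eqn{\Pi = 1}, so the root is
#' unique and found by bisection. Special cases: `n = 1` or `S = 0` give
#' \eqn{\Pi = 1}; `S >= log2(n)` (possible for the estimator on short
#' sequences) is clipped to the random-guessing bound \eqn{\Pi = 1/n} and
#' flagged.
#'
#' @param S Entropy in bits (scalar, >= 0).
#' @param n Number of distinct locations (>= 1).
#' @param tol Bisection interval tolerance on \eqn{\Pi}; the default keeps
#'   the round-trip residual on S below 1e-8 for any realistic n.
#' @return A `predictability_estimate`: list with `pi`, `n`, `S`, `tol`,
#'   `clipped`.
#' @examples
#' fano_predictability(1, 2)$pi   # 0.5
#' fano_predictability(0, 50)$pi  # 1
#' @export
fano_predictability <- function(S, n, tol = 1e-12) {
  if (!is.finite(S) || S < 0) stop("S must be a nonnegative finite number")
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(round(n))
  mk <- function(pi, clipped = FALSE)
    structure(list(pi = pi, n = n, S = S, tol = tol, clipped = clipped),
              class = "predictability_estimate")
  if (n == 1L || S == 0) return(mk(1))
  if (S >= log2(n)) return(mk(1 / n, clipped = TRUE))
  h2 <- function(x) {
    # binary entropy, safe at the endpoints
    ifelse(x <= 0 | x >= 1, 0, -x * log2(x) - (1 - x) * log2(1 - x))
  }
  f <- function(pi) h2(pi) + (1 - pi) * log2(n - 1) - S
  lo <- 1 / n; hi <- 1
  # f(lo) = log2(n) - S > 0, f(hi) = -S < 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  mk((lo + hi) / 2)
}

#' @export
print.predictability_estimate <- function(x, ...) {
  cat(sprintf("<predictability_estimate> Pi = %.4f (S = %.4f bits, n = %d)%s\n",
              x$pi, x$S, x$n, if (x$clipped) " [clipped to 1/n]" else ""))
  invisible(x)
}

#' Perplexity of an entropy value
#'
#' \eqn{2^S}: the number of equally likely locations that would produce the
#' same uncertainty. An entropy rate of 3 bits is as uncertain as choosing
#' uniformly among 8 locations.
#'
#' @param S Entropy in bits (vectorized).
#' @return Effective location count `2^S`.
#' @export
perplexity <- function(S) {
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be nonnegative")
  2^S
}

#' Cross-predictability of an ego given an entropy estimate
#'
#' Applies [fano_predictability()] to a cross or cumulative cross-entropy
#' estimate using the ego's own distinct-location count \eqn{n_A} — the bound
#' concerns guessing the ego's next location among the ego's alternatives.
#'
#' @param est An `entropy_estimate` of mode `"cross"` or `"cumulative"` (the
#'   self mode is accepted too, giving the ego's own predictability).
#' @param ego The ego [trajectory()] the estimate refers to.
#' @return A `predictability_estimate` carrying the source estimate's user
#'   and mode.
#' @export
cross_predictability <- function(est, ego) {
  stopifnot(inherits(est, "entropy_estimate"))
  ego <- as_trajectory(ego)
  if (!identical(est$user, ego$user_id))
    stop("estimate is for user ", est$user, ", not ego ", ego$user_id)
  out <- fano_predictability(est$value, ego$n)
  out$user <- ego$user_id
  out$mode <- est$mode
  out
}
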