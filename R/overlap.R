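#' Overlapped distinct location ratio (ODLR)
#'
#' The fraction of the ego's distinct locations also visited by an alter:
#' \deqn{\eta_{A|B} = |Y_A \cap Y_B| / |Y_A|.}
#' Overlap is computed over each user's full distinct-location set for the
#' whole observation window, with no time constraint — the time dimension
#' enters the analysis only through the entropy estimators.
#'
#' @param A Ego [trajectory()] (must have visited at least one location).
#' @param B Alter trajectory.
#' @return An `overlap_result`: list with `eta`, `ego`, `alters`,
#'   `n_ego_locations`, `n_overlap`.
#' @export
odlr <- function(A, B) {
  codlr(A, list(B))
}

#' Cumulative overlapped distinct location ratio (CODLR)
#'
#' Generalizes [odlr()] to a set of alters by taking the union of the
#' pairwise intersections:
#' \deqn{\eta_{A|\mathcal B} =
#'   |\cup_{B \in \mathcal B} (Y_A \cap Y_B)| / |Y_A|.}
#' With a singleton set it equals [odlr()] exactly, and it is monotone
#' nondecreasing as alters are added.
#'
#' @param A Ego trajectory.
#' @param alters Nonempty list of alter trajectories.
#' @return An `overlap_result`.
#' @export
codlr <- function(A, alters) {
  A <- as_trajectory(A)
  if (inherits(alters, "trajectory")) alters <- list(alters)
  if (length(alters) == 0L) stop("alter set must be nonempty")
  if (length(A$Y) < 1L) stop("ego has no visited locations")
  covered <- unique(unlist(lapply(alters, function(B) {
    intersect(A$Y, as_trajectory(B)$Y)
  })))
  structure(list(eta = length(covered) / length(A$Y),
                 ego = A$user_id,
                 alters = vapply(alters, function(B) B$user_id, character(1)),
                 n_ego_locations = length(A$Y),
                 n_overlap = length(covered)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> eta = %.4f (%d of %d ego locations; %d alters)\n",
              x$eta, x$n_overlap, x$n_ego_locations, length(x$alters)))
  invisible(x)
}
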