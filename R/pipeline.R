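#' Alter-accumulation curve for one ego
#'
#' Adds the ego's retained alters in rank order and, at each k = 1..k_max,
#' records the cumulative cross-entropy over the top-k alters, the
#' corresponding Fano cross-predictability (using the ego's
#' distinct-location count), and the cumulative distinct-location overlap
#' (CODLR). Each requested variant computes the estimators with or without
#' the ego's own past joined to the alter set.
#'
#' @param net An `ego_network` with at least `k_max` retained alters.
#' @param ds The `checkin_dataset` with all trajectories.
#' @param k_max Number of alters to accumulate (default 10).
#' @param include_ego_past Logical vector of variants to compute (default
#'   both `FALSE` and `TRUE`).
#' @return An `accumulation_curve`: data.frame with columns `ego`, `flavor`,
#'   `include_ego`, `k`, `S_bits`, `Pi`, `eta`.
#' @export
accumulation_curve <- function(net, ds, k_max = 10L,
                               include_ego_past = c(FALSE, TRUE)) {
  stopifnot(inherits(net, "ego_network"), inherits(ds, "checkin_dataset"))
  ego <- ds$trajectories[[net$ego]]
  if (is.null(ego)) stop("no trajectory for ego ", net$ego)
  ranked <- net$alters[net$alters$retained, , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  if (nrow(ranked) < k_max)
    stop("ego ", net$ego, " has ", nrow(ranked), " retained alters < k_max = ",
         k_max, "; restrict to eligible egos first (see select_eligible_egos)")
  alter_ids <- ranked$alter[seq_len(k_max)]
  alters <- ds$trajectories[alter_ids]
  lam_mat <- vapply(alters, function(B) {
    as.integer(cross_match_lengths(ego, B, time_constrained = TRUE)$lambdas)
  }, integer(ego$N))
  lam_mat <- matrix(lam_mat, nrow = ego$N)
  lam_ego <- as.integer(cross_match_lengths(ego, ego, time_constrained = TRUE)$lambdas)
  w_alt <- colSums(lam_mat > 1L)
  n_alt <- vapply(alters, function(B) B$N, numeric(1))
  rows <- list()
  for (with_ego in include_ego_past) {
    lam_cum <- if (with_ego) lam_ego else rep(1L, ego$N)
    covered <- character(0)
    for (k in seq_len(k_max)) {
      lam_cum <- pmax(lam_cum, lam_mat[, k])
      w <- w_alt[seq_len(k)]
      lens <- n_alt[seq_len(k)]
      if (with_ego) {
        w <- c(w, sum(lam_ego > 1L))
        lens <- c(lens, ego$N)
      }
      N_ref <- if (all(w == 0)) mean(lens) else sum(w * lens) / sum(w)
      S <- ego$N * log2(N_ref) / sum(lam_cum)
      covered <- union(covered, intersect(ego$Y, alters[[k]]$Y))
      rows[[length(rows) + 1L]] <- data.frame(
        ego = ego$user_id, flavor = net$flavor, include_ego = with_ego,
        k = k, S_bits = S, Pi = fano_predictability(S, ego$n)$pi,
        eta = length(covered) / ego$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Extrapolate an accumulation curve to infinitely many alters
#'
#' Fits the saturating form
#' \deqn{\Pi(k) = \Pi_\infty - (\Pi_\infty - \Pi(1)) e^{-(k-1)/\kappa}}
#' to the cumulative cross-predictability by least squares (\eqn{\Pi(1)} is
#' pinned to the observed first point) and reports the asymptote
#' \eqn{\Pi_\infty}. Initialization is fixed (\eqn{\Pi_\infty}: max point +
#' 0.05, \eqn{\kappa}: 3) so the fit is deterministic. A constant curve
#' returns its constant.
#'
#' @param curve An `accumulation_curve`, or a numeric vector of per-k values.
#' @param include_ego Which variant of the curve to fit (when `curve` is an
#'   `accumulation_curve`).
#' @param measure Column to extrapolate (default `"Pi"`).
#' @return A `saturation_fit` with `pi_infinity`, `kappa`, residual sum of
#'   squares and the k-range used; `coef()` and `predict()` methods apply.
#' @export
saturation_extrapolate <- function(curve, include_ego = FALSE, measure = "Pi") {
  if (inherits(curve, "accumulation_curve")) {
    sub <- curve[curve$include_ego == include_ego, , drop = FALSE]
    y <- sub[[measure]][order(sub$k)]
  } else {
    y <- as.numeric(curve)
  }
  if (length(y) < 4L) stop("need at least 4 curve points to extrapolate")
  k <- seq_along(y)
  p1 <- y[1]
  mk <- function(pinf, kappa, rss)
    structure(list(pi_infinity = pinf, kappa = kappa, p1 = p1, rss = rss,
                   k_range = range(k), n = length(y)),
              class = "saturation_fit")
  if (diff(range(y)) < 1e-12) return(mk(y[1], NA_real_, 0))
  resid_fn <- function(p) y - (p[1] - (p[1] - p1) * exp(-(k - 1) / p[2]))
  # Levenberg-Marquardt from the documented start (kappa = 3) plus a fixed
  # fallback grid: the exponential has a spurious step-like local minimum at
  # kappa -> 0 that a single distant start can fall into
  fits <- lapply(c(3, 0.5, 1, 2, 5, 8), function(k0) {
    tryCatch(minpack.lm::nls.lm(
      par = c(pinf = max(y) + 0.05, kappa = k0), fn = resid_fn,
      lower = c(-Inf, 1e-9),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 1000)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  if (length(fits) == 0L || !any(is.finite(dev)))
    stop("saturation fit did not converge from any start")
  best <- fits[[which.min(dev)]]
  if (min(dev) > max(1e-6, 0.25 * sum((y - mean(y))^2)))
    warning("saturation fit explains little of the curve (RSS ",
            format(min(dev)), ")")
  mk(unname(best$par["pinf"]), unname(best$par["kappa"]), best$deviance)
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(pi_infinity = object$pi_infinity, kappa = object$kappa)
}

#' @export
predict.saturation_fit <- function(object, k = NULL, ...) {
  if (is.null(k)) k <- seq(object$k_range[1], object$k_range[2])
  if (is.na(object$kappa)) return(rep(object$pi_infinity, length(k)))
  object$pi_infinity - (object$pi_infinity - object$p1) * exp(-(k - 1) / object$kappa)
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> Pi_infinity = %.4f, kappa = %.3f (RSS %.3g over k = %d..%d)\n",
              x$pi_infinity, x$kappa, x$rss, x$k_range[1], x$k_range[2]))
  invisible(x)
}

curve_pi_at <- function(curve, k, include_ego = FALSE) {
  sub <- curve[curve$include_ego == include_ego & curve$k == k, , drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  sub$Pi[1]
}

#' Predictability ratio of social ties to non-social colocators
#'
#' For each ego, the ratio \eqn{\Pi_{ego|social}(k_{social}) /
#' \Pi_{ego|colocators}(k)} over a range of colocator counts; aggregated
#' over egos as the mean with a seeded nonparametric bootstrap 95% CI. Also
#' reports the (linearly interpolated) colocator count at which the mean
#' ratio crosses 1 — the point where accumulated colocators match the
#' social information.
#'
#' @param social_curves,coloc_curves Named per-ego lists of
#'   [accumulation_curve()]s over the same ego set.
#' @param k_social Number of top social ties in the numerator (default 1).
#' @param k_coloc_range Colocator counts for the denominator (default 1:10).
#' @param include_ego Curve variant to compare (default `FALSE`).
#' @param n_boot,seed Bootstrap replicates and RNG seed for the CIs.
#' @return A `ratio_curve` data.frame (columns `k_coloc`, `mean_ratio`,
#'   `ci_lo`, `ci_hi`, `n_egos`) with attributes `k_social` and `crossing`.
#' @export
predictability_ratio <- function(social_curves, coloc_curves, k_social = 1L,
                                 k_coloc_range = 1:10, include_ego = FALSE,
                                 n_boot = 1000L, seed = NULL) {
  egos <- intersect(names(social_curves), names(coloc_curves))
  if (length(egos) == 0L) stop("no common egos between the two curve sets")
  rows <- list()
  excluded <- 0L
  for (kc in k_coloc_range) {
    r <- vapply(egos, function(e) {
      num <- curve_pi_at(social_curves[[e]], k_social, include_ego)
      den <- curve_pi_at(coloc_curves[[e]], kc, include_ego)
      if (!is.finite(den) || den == 0) return(NA_real_)
      num / den
    }, numeric(1))
    if (anyNA(r)) {
      excluded <- excluded + sum(is.na(r))
      warning(sum(is.na(r)), " egos excluded at k_coloc = ", kc,
              " (zero or missing denominator)")
    }
    r <- r[!is.na(r)]
    ci <- boot_ci_mean(r, n_boot = n_boot, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      k_coloc = kc, mean_ratio = mean(r), ci_lo = ci[1], ci_hi = ci[2],
      n_egos = length(r))
  }
  out <- do.call(rbind, rows)
  crossing <- NA_real_
  below <- which(out$mean_ratio <= 1)
  if (length(below)) {
    j <- below[1]
    if (j == 1L) {
      crossing <- out$k_coloc[1]
    } else {
      r1 <- out$mean_ratio[j - 1]; r2 <- out$mean_ratio[j]
      crossing <- out$k_coloc[j - 1] +
        (r1 - 1) / (r1 - r2) * (out$k_coloc[j] - out$k_coloc[j - 1])
    }
  }
  attr(out, "k_social") <- k_social
  attr(out, "crossing") <- crossing
  class(out) <- c("ratio_curve", "data.frame")
  out
}

population_mean_curve <- function(curves, n_boot = 1000L, seed = NULL) {
  all <- do.call(rbind, curves)
  parts <- split(all, list(all$flavor, all$include_ego, all$k), drop = TRUE)
  rows <- lapply(parts, function(d) {
    ci <- boot_ci_mean(d$Pi, n_boot = n_boot, seed = seed)
    data.frame(flavor = d$flavor[1], include_ego = d$include_ego[1], k = d$k[1],
               mean_S = mean(d$S_bits), mean_Pi = mean(d$Pi),
               Pi_ci_lo = ci[1], Pi_ci_hi = ci[2],
               mean_eta = mean(d$eta), n_egos = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$flavor, out$include_ego, out$k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Colocation-network lag sweep
#'
#' Builds one lagged colocation network per lag on the grid, restricts to
#' the egos eligible (at least `min_alters` retained alters) at every lag,
#' and computes the population-mean accumulation curve per lag.
#'
#' @param ds A `checkin_dataset`.
#' @param lags Lag grid in hours (default 0.5 to 12 in steps of 0.5).
#' @param k_max Alters to accumulate.
#' @param min_alters Eligibility threshold per lag (default `k_max`).
#' @param filter_random Apply [filter_better_than_random()] per network.
#' @param n_boot,seed Bootstrap settings for the population CIs.
#' @return A `lag_sweep` list: `lags`, common `egos`, and per-lag
#'   population-mean curves.
#' @export
lag_sweep <- function(ds, lags = seq(0.5, 12, by = 0.5), k_max = 10L,
                      min_alters = k_max, filter_random = TRUE,
                      n_boot = 1000L, seed = NULL) {
  nets_by_lag <- lapply(lags, function(Tl) {
    nets <- build_colocation_networks(ds, lag_window(Tl))
    if (filter_random) nets <- lapply(nets, filter_better_than_random, ds = ds)
    nets
  })
  names(nets_by_lag) <- format(lags)
  egos <- common_egos_across_lags(nets_by_lag, min_alters = min_alters)
  if (length(egos) == 0L)
    stop("no common eligible egos across the lag grid; the sweep is undefined")
  curves <- lapply(nets_by_lag, function(nets) {
    per_ego <- lapply(egos, function(e) {
      accumulation_curve(nets[[e]], ds, k_max = k_max,
                         include_ego_past = FALSE)
    })
    names(per_ego) <- egos
    population_mean_curve(per_ego, n_boot = n_boot, seed = seed)
  })
  structure(list(lags = lags, egos = egos, curves = curves),
            class = "lag_sweep")
}

#' @export
print.lag_sweep <- function(x, ...) {
  cat(sprintf("<lag_sweep> %d lags (%.1f..%.1f h), %d common egos\n",
              length(x$lags), min(x$lags), max(x$lags), length(x$egos)))
  invisible(x)
}

#' Regress cumulative cross-predictability on location overlap
#'
#' At each accumulation depth k, pairs each ego's CODLR with its cumulative
#' cross-predictability and reports the OLS slope and intercept and the
#' Pearson correlation with its p-value.
#'
#' @param curves Named per-ego list of [accumulation_curve()]s (one flavor).
#' @param ks Accumulation depths to analyze (default 1:10).
#' @param include_ego Curve variant (default `FALSE`).
#' @return Data.frame with columns `k`, `slope`, `intercept`, `pearson_r`,
#'   `p_value`, `n_egos`.
#' @export
overlap_vs_predictability <- function(curves, ks = 1:10, include_ego = FALSE) {
  if (length(curves) < 3L) stop("need at least 3 egos for the regression")
  all <- do.call(rbind, curves)
  all <- all[all$include_ego == include_ego, , drop = FALSE]
  rows <- lapply(ks, function(k) {
    d <- all[all$k == k, , drop = FALSE]
    fit <- lm(Pi ~ eta, data = d)
    ct <- suppressWarnings(cor.test(d$eta, d$Pi, method = "pearson"))
    data.frame(k = k, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               pearson_r = unname(ct$estimate), p_value = ct$p.value,
               n_egos = nrow(d))
  })
  do.call(rbind, rows)
}

#' Per-ego comparison of social and colocator predictability
#'
#' For each ego, a paired one-sided t-test of social versus colocator
#' cumulative cross-predictability across the accumulation depths
#' k = 1..k_max, and a Spearman rank correlation of predictability against
#' k per flavor (does information accumulate?). Reports the fraction of
#' egos whose social ties are significantly more informative, and the
#' fraction of ego-flavor curves that increase significantly. P-values are
#' reported raw by default; `p_adjust` applies a correction across egos.
#'
#' @param social_curves,coloc_curves Named per-ego curve lists.
#' @param p_ttest,p_spearman Significance thresholds (defaults 0.01, 0.05).
#' @param include_ego Curve variant (default `FALSE`).
#' @param p_adjust Method for [stats::p.adjust()] (default `"none"`).
#' @return A list: `frac_social_higher`, `frac_increasing`, per-ego tables,
#'   and the number of degenerate egos excluded.
#' @export
social_vs_colocator_test <- function(social_curves, coloc_curves,
                                     p_ttest = 0.01, p_spearman = 0.05,
                                     include_ego = FALSE, p_adjust = "none") {
  egos <- intersect(names(social_curves), names(coloc_curves))
  if (length(egos) == 0L) stop("no common egos")
  t_p <- setNames(rep(NA_real_, length(egos)), egos)
  rho <- list()
  excluded <- 0L
  for (e in egos) {
    s <- social_curves[[e]]; s <- s[s$include_ego == include_ego, ]
    k <- coloc_curves[[e]]; k <- k[k$include_ego == include_ego, ]
    s <- s[order(s$k), ]; k <- k[order(k$k), ]
    d <- s$Pi - k$Pi
    if (sd(d) < 1e-12) { excluded <- excluded + 1L } else {
      t_p[e] <- t.test(s$Pi, k$Pi, paired = TRUE,
                       alternative = "greater")$p.value
    }
    for (fl in c("social", "coloc")) {
      y <- if (fl == "social") s$Pi else k$Pi
      if (sd(y) < 1e-12) next
      ct <- suppressWarnings(cor.test(seq_along(y), y, method = "spearman"))
      rho[[paste(e, fl)]] <- c(rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  t_p_adj <- stats::p.adjust(t_p, method = p_adjust)
  rho_tab <- if (length(rho)) do.call(rbind, rho) else
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("rho", "p")))
  list(frac_social_higher = mean(t_p_adj < p_ttest, na.rm = TRUE),
       frac_increasing = if (nrow(rho_tab)) {
         mean(rho_tab[, "rho"] > 0 &
                stats::p.adjust(rho_tab[, "p"], method = p_adjust) < p_spearman)
       } else NA_real_,
       t_p_values = t_p, spearman = rho_tab, n_excluded = excluded)
}

#' Run the full information-flow analysis on a dataset
#'
#' End-to-end orchestration: builds social and colocation networks, drops
#' alters carrying no better-than-random information, selects egos eligible
#' in both flavors, and computes per-ego accumulation curves (with and
#' without the ego's own past) plus population means.
#'
#' @param ds A `checkin_dataset` (already filtered to active users).
#' @param k_max Alters to accumulate (default 10).
#' @param min_alters Eligibility threshold (default `k_max`).
#' @param window Colocation [lag_window()].
#' @param n_boot,seed Bootstrap settings for population CIs.
#' @return An `infoflow_result` with the networks, eligible egos, per-ego
#'   curves by flavor, and population-mean curves.
#' @export
run_infoflow <- function(ds, k_max = 10L, min_alters = k_max,
                         window = lag_window(), n_boot = 1000L, seed = NULL) {
  social <- build_social_networks(ds, window)
  coloc <- build_colocation_networks(ds, window)
  social <- lapply(social, filter_better_than_random, ds = ds)
  coloc <- lapply(coloc, filter_better_than_random, ds = ds)
  egos <- select_eligible_egos(social, coloc, min_alters = min_alters)
  if (length(egos) == 0L) stop("no eligible egos; generate a denser dataset")
  curve_set <- function(nets) {
    out <- lapply(egos, function(e) accumulation_curve(nets[[e]], ds, k_max))
    names(out) <- egos
    out
  }
  social_curves <- curve_set(social)
  coloc_curves <- curve_set(coloc)
  ego_baseline <- vapply(egos, function(e) {
    tr <- ds$trajectories[[e]]
    fano_predictability(entropy_rate(tr)$value, tr$n)$pi
  }, numeric(1))
  structure(list(
    egos = egos, k_max = k_max,
    social_networks = social[egos], coloc_networks = coloc[egos],
    social_curves = social_curves, coloc_curves = coloc_curves,
    ego_predictability = ego_baseline,
    population = rbind(population_mean_curve(social_curves, n_boot, seed),
                       population_mean_curve(coloc_curves, n_boot, seed))),
    class = "infoflow_result")
}

#' @export
print.infoflow_result <- function(x, ...) {
  cat(sprintf("<infoflow_result> %d eligible egos, k_max = %d\n",
              length(x$egos), x$k_max))
  cat(sprintf("  mean ego self-predictability: %.2f%%\n",
              100 * mean(x$ego_predictability)))
  pop <- x$population
  for (fl in unique(pop$flavor)) {
    p <- pop[pop$flavor == fl & !pop$include_ego & pop$k == x$k_max, ]
    cat(sprintf("  %s: mean Pi at k = %d is %.2f%% (ego past excluded)\n",
                fl, x$k_max, 100 * p$mean_Pi))
  }
  invisible(x)
}

#' Write pipeline outputs as CSV
#'
#' Writes the per-ego accumulation curves, the population means, and the
#' network edge tables to `dir`. Output is byte-identical across runs with
#' the same inputs and seed.
#'
#' @param res An `infoflow_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_infoflow_csv <- function(res, dir) {
  stopifnot(inherits(res, "infoflow_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(curves = file.path(dir, "curves.csv"),
             population = file.path(dir, "population.csv"),
             networks = file.path(dir, "networks.csv"))
  curves <- rbind(do.call(rbind, res$social_curves),
                  do.call(rbind, res$coloc_curves))
  write.csv(curves, paths["curves"], row.names = FALSE)
  write.csv(res$population, paths["population"], row.names = FALSE)
  nets <- rbind(network_edges_df(res$social_networks),
                network_edges_df(res$coloc_networks))
  write.csv(nets, paths["networks"], row.names = FALSE)
  invisible(paths)
}
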