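hours <- function(h) h * 3600

test_that("social alters are ranked by colocation frequency with the ego", {
  # b colocates 5 times, c colocates 9 times within the contiguous window
  ego_times <- hours(seq(1, 28, by = 2)) # 14 events
  users <- list(
    ego = list(loc = rep("p", 14), time = ego_times),
    b = list(loc = rep("p", 5), time = ego_times[1:5] + 60),
    c = list(loc = rep("p", 9), time = ego_times[1:9] + 120),
    d = list(loc = rep("q", 3), time = ego_times[1:3])) # friend, no coloc
  ds <- make_ds(users, edges = rbind(c("ego", "b"), c("ego", "c"),
                                     c("ego", "d"), c("ego", "ghost")))
  nets <- build_social_networks(ds)
  alt <- nets[["ego"]]$alters
  expect_equal(alt$alter[order(alt$rank)], c("c", "b", "d"))
  expect_equal(sort(alt$weight, decreasing = TRUE), c(9, 5, 0))
  # the friend without a trajectory is excluded entirely
  expect_false("ghost" %in% alt$alter)
})

test_that("the CDR social-tie threshold of 30 reciprocal calls is inclusive", {
  mk_calls <- function(n_ab, n_ba) {
    data.frame(caller = c(rep("a", n_ab), rep("b", n_ba)),
               callee = c(rep("b", n_ab), rep("a", n_ba)),
               time = seq_len(n_ab + n_ba) * 100)
  }
  users <- list(a = list(loc = c("x", "y"), time = hours(c(1, 2))),
                b = list(loc = c("x", "y"), time = hours(c(1, 2)) + 60))
  # 15 each way: 2 * min = 30, tie
  ds30 <- make_ds(users, calls = mk_calls(15, 15))
  expect_true("b" %in% build_social_networks(ds30)[["a"]]$alters$alter)
  # 15 + 14: 2 * min = 28 < 30, no tie
  ds29 <- make_ds(users, calls = mk_calls(15, 14))
  expect_false("a" %in% names(build_social_networks(ds29)))
})

test_that("colocation windows count same-location visits inside the band", {
  base <- hours(12)
  users <- list(
    ego = list(loc = "p", time = base),
    near = list(loc = "p", time = base + 20 * 60), # 20 min later
    lagged = list(loc = "p", time = base + hours(2) + 20 * 60), # 2 h 20 min
    elsewhere = list(loc = "q", time = base + 60))
  ds <- make_ds(users)
  # default contiguous window: |dt| <= 30 min
  nets <- build_colocation_networks(ds)
  expect_equal(nets[["ego"]]$alters$alter, "near")
  expect_equal(nets[["ego"]]$alters$weight, 1)
  # T = 2.5 h band [2 h, 2.5 h]: only the lagged visitor counts
  nets_lag <- build_colocation_networks(ds, lag_window(2.5))
  expect_equal(nets_lag[["ego"]]$alters$alter, "lagged")
  expect_equal(nets_lag[["ego"]]$flavor, "lagged-colocation")
})

test_that("declared friends and call partners are excluded from colocation", {
  base <- hours(5)
  users <- list(ego = list(loc = c("p", "p"), time = c(base, base + hours(3))),
                friend = list(loc = "p", time = base + 300),
                stranger = list(loc = "p", time = base + 600))
  ds <- make_ds(users, edges = rbind(c("ego", "friend")))
  nets <- build_colocation_networks(ds)
  expect_equal(nets[["ego"]]$alters$alter, "stranger")
  # with a call instead of an edge, same exclusion
  ds2 <- make_ds(users, calls = data.frame(caller = "ego", callee = "friend",
                                           time = 1))
  expect_equal(build_colocation_networks(ds2)[["ego"]]$alters$alter, "stranger")
})

test_that("colocation weights are symmetric and monotone in the half-width", {
  set.seed(9)
  users <- lapply(1:6, function(i) {
    list(loc = sample(c("p", "q", "r"), 30, TRUE),
         time = sort(runif(30, 0, hours(48))))
  })
  names(users) <- paste0("u", 1:6)
  ds <- make_ds(users)
  cp <- mobflow:::colocation_pair_counts(ds, lag_window(0.5))
  w <- tapply(cp$n, paste(cp$ego, cp$alter), sum)
  for (key in names(w)) {
    rev_key <- paste(rev(strsplit(key, " ")[[1]]), collapse = " ")
    expect_equal(unname(w[key]), unname(w[rev_key]))
  }
  # wider half-width at the same T never loses a colocation
  cp_wide <- mobflow:::colocation_pair_counts(
    ds, lag_window(T = 0.75, half_width = 0.75))
  w_wide <- tapply(cp_wide$n, paste(cp_wide$ego, cp_wide$alter), sum)
  for (key in names(w)) expect_gte(unname(w_wide[key]), unname(w[key]))
})

test_that("calendar bucketing approximates the sliding window", {
  base <- hours(12)
  users <- list(ego = list(loc = "p", time = base + 100),
                other = list(loc = "p", time = base + 200))
  ds <- make_ds(users)
  cp <- mobflow:::colocation_pair_counts(ds, mode = "calendar")
  expect_equal(sum(cp$n[cp$ego == "ego"]), 1)
  expect_error(mobflow:::colocation_pair_counts(ds, lag_window(2.5),
                                                mode = "calendar"))
})

test_that("alters with no better-than-random information are dropped", {
  set.seed(13)
  ego_loc <- sample(c("a", "b", "c"), 60, TRUE)
  ego_t <- hours(seq_len(60))
  users <- list(
    ego = list(loc = ego_loc, time = ego_t),
    copycat = list(loc = ego_loc, time = ego_t - 120), # time-shifted copy
    sometimes = list(loc = c(ego_loc[1:50], rep("zz", 10)), # mostly a copy
                     time = ego_t - 90),
    disjoint = list(loc = sample(c("x", "y"), 60, TRUE), time = ego_t + 30))
  # declare all three as friends: a friend sharing no locations stays in the
  # social network (weight 0) until the information filter removes it
  ds <- make_ds(users, edges = rbind(c("ego", "copycat"), c("ego", "sometimes"),
                                     c("ego", "disjoint")))
  net <- filter_better_than_random(build_social_networks(ds)[["ego"]], ds)
  ret <- net$alters$alter[net$alters$retained]
  expect_setequal(ret, c("copycat", "sometimes"))
  expect_true("disjoint" %in% net$alters$alter[!net$alters$retained])
  # ranks are a permutation over survivors
  expect_setequal(net$alters$rank[net$alters$retained], 1:2)
})

test_that("ego eligibility requires the alter minimum in both flavors", {
  fake_net <- function(ego, n_alters) {
    mobflow:::new_ego_network(ego, "social", 0.5, data.frame(
      alter = paste0("x", seq_len(n_alters)), weight = 1,
      retained = TRUE, rank = seq_len(n_alters)))
  }
  social <- list(a = fake_net("a", 10), b = fake_net("b", 10))
  coloc <- list(a = fake_net("a", 9), b = fake_net("b", 10))
  expect_equal(suppressWarnings(select_eligible_egos(social, coloc)), "b")
  coloc$a <- fake_net("a", 10)
  expect_setequal(select_eligible_egos(social, coloc), c("a", "b"))
  # lag intersection
  lagged <- list(`0.5` = list(a = fake_net("a", 10), b = fake_net("b", 10),
                              c = fake_net("c", 10)),
                 `1.0` = list(b = fake_net("b", 10), c = fake_net("c", 10),
                              d = fake_net("d", 10)))
  expect_setequal(common_egos_across_lags(lagged), c("b", "c"))
  lagged$`1.0` <- list(d = fake_net("d", 3))
  expect_warning(out <- common_egos_across_lags(lagged), "no egos")
  expect_length(out, 0)
})

test_that("network edge tables round-trip rank and retention flags", {
  users <- list(ego = list(loc = rep("p", 4), time = hours(c(1, 5, 9, 13))),
                u1 = list(loc = rep("p", 4), time = hours(c(1, 5, 9, 13)) + 60),
                u2 = list(loc = "p", time = hours(1) + 120))
  ds <- make_ds(users)
  nets <- build_colocation_networks(ds)
  df <- network_edges_df(nets)
  expect_setequal(names(df), c("ego", "alter", "flavor", "lag_hours",
                               "weight", "rank", "retained"))
  ego_rows <- df[df$ego == "ego", ]
  expect_equal(ego_rows$alter[ego_rows$rank == 1], "u1")
})
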