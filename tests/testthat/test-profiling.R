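fit_small_net <- function(n = 600, seed = 71, k = 3) {
  edges <- data.frame(a = c("t", "u", "u"), b = c("u", "v", "w"))
  d <- sample_tree(edges, n = n, strength = 0.75, n_states = k, seed = seed)
  chow_liu(d, root = "t")
}

test_that("tornado entries replay exactly through the posterior", {
  net <- fit_small_net()
  tn <- tornado(net, "t", 1)
  prior <- posterior(net, NULL, "t")[[1]]
  for (r in seq_len(nrow(tn))) {
    ev <- stats::setNames(tn$state[r], tn$node[r])
    expect_equal(tn$posterior[r], posterior(net, ev, "t")[[1]],
                 tolerance = 1e-12)
    expect_equal(tn$delta[r], tn$posterior[r] - prior, tolerance = 1e-12)
  }
  expect_true(all(diff(abs(tn$delta)) <= 1e-12))   # sorted by |delta|
  expect_true(all(abs(tn$delta) <= 1))
})

test_that("tornado flattens for independent nodes and peaks for copies", {
  # attach an independent node and a deterministic copy of the target
  d <- data.frame(t = rep(1:2, each = 100))
  set.seed(1); d$ind <- sample.int(2, 200, replace = TRUE)
  d$copy <- d$t
  net <- chow_liu(d, root = "t", prior_count = 0)
  tn <- tornado(net, "t", 2)
  expect_lt(max(abs(tn$delta[tn$node == "ind"])), 0.12)
  expect_equal(max(tn$posterior[tn$node == "copy"]), 1, tolerance = 1e-9)
})

test_that("greedy profile steps obey Bayes-rule and odds identities", {
  net <- fit_small_net(n = 800, seed = 31)
  prof <- dynamic_profile(net, "t", 1)
  st <- prof$steps
  expect_equal(st$bayes_factor[1], 1)
  expect_equal(st$generalized_bayes_factor[1], 1)
  p_s <- st$posterior_pct[1] / 100
  for (r in 2:nrow(st)) {
    psh <- st$posterior_pct[r] / 100
    ph <- st$marginal_likelihood_pct[r] / 100
    phs <- st$likelihood_pct[r] / 100
    expect_equal(psh * ph, phs * p_s, tolerance = 1e-9)   # Bayes identity
    expect_equal(st$bayes_factor[r], psh / p_s, tolerance = 1e-12)
    odds <- function(p) p / (1 - p)
    expect_equal(st$generalized_bayes_factor[r], odds(psh) / odds(p_s),
                 tolerance = 1e-9)
  }
  expect_true(all(diff(st$posterior_pct) > 0))   # strictly improving greedy
})

test_that("the first greedy step matches the exhaustive best single evidence", {
  net <- fit_small_net(n = 500, seed = 13)
  prof <- dynamic_profile(net, "t", 2, max_steps = 1)
  best <- -Inf
  for (v in setdiff(net$nodes, "t"))
    for (s in seq_along(net$states[[v]]))
      best <- max(best, posterior(net, stats::setNames(s, v), "t")[[2]])
  expect_equal(prof$steps$posterior_pct[2] / 100, best, tolerance = 1e-12)
  # tornado's best single-evidence posterior can never beat it
  tn <- tornado(net, "t", 2)
  expect_lte(max(tn$posterior), prof$steps$posterior_pct[2] / 100 + 1e-12)
})

test_that("profile means are the evidence-weighted conditional means", {
  ft <- generate_feature_table(n = 400, feature_names = c(
    "energy", "entropy", "contrast"), duplicate = NULL,
    class_shift = c(energy = 3), rho = 0.7, seed = 3)
  disc <- discretize_apply(ft, discretize_fit(ft, n_states = 3))
  net <- chow_liu(disc, root = "energy")
  prof <- dynamic_profile(net, "energy", 1, disc = disc, max_steps = 2)
  cm <- attr(disc, "cond_means")
  # a-priori column: state-probability-weighted unconditional means
  for (v in net$nodes) {
    w <- posterior(net, NULL, v)
    expect_equal(prof$means[v, "a_priori"], sum(w * cm[[v]]),
                 tolerance = 1e-9)
  }
  # evidence nodes pin their mean to the evidenced state's conditional mean
  ev_node <- prof$steps$node[2]
  ev_state <- prof$steps$state[2]
  expect_equal(prof$means[ev_node, "step_1"],
               cm[[ev_node]][[ev_state]], tolerance = 1e-12)
})

test_that("optimization tree agrees with exhaustive enumeration", {
  net <- fit_small_net(n = 400, seed = 7)
  # trivial thresholds
  expect_equal(optimization_tree(net, "t", 1, threshold = 0)$path, "a_priori")
  expect_equal(nrow(optimization_tree(net, "t", 1, threshold = 1)), 0)

  thr <- 0.75
  ot <- optimization_tree(net, "t", 1, threshold = thr, max_depth = 2)
  # oracle: all single and ordered-pair evidence sets
  others <- sort(setdiff(net$nodes, "t"))
  qualifying <- character(0)
  singles_below <- list()
  for (v in others) for (s in seq_along(net$states[[v]])) {
    post <- posterior(net, stats::setNames(s, v), "t")[[1]]
    key <- paste0(v, "=", net$states[[v]][s])
    if (post >= thr) qualifying <- c(qualifying, key)
    else singles_below[[key]] <- stats::setNames(s, v)
  }
  for (key in names(singles_below)) {
    ev <- singles_below[[key]]
    for (v in others[others > names(ev)])
      for (s in seq_along(net$states[[v]])) {
        ev2 <- c(ev, stats::setNames(s, v))
        if (evidence_probability(net, ev2) <= 0) next
        if (posterior(net, ev2, "t")[[1]] >= thr)
          qualifying <- c(qualifying,
                          paste0(key, " + ", v, "=", net$states[[v]][s]))
      }
  }
  expect_setequal(ot$path, qualifying)
  expect_true(all(ot$posterior >= thr))
})

test_that("segment normalized means hit the normalization endpoints", {
  x <- c(1, 2, 3, 10, 11, 12)
  ft <- data.frame(f = x, class = rep(c("a", "b"), 3))
  states <- c(1, 1, 1, 2, 2, 2)
  sp <- segment_profile(ft, states, n_draws = 800, seed = 2)
  expect_equal(sp[["1"]]$normalized_mean, (2 - 1) / 11)
  expect_equal(sp[["2"]]$normalized_mean, (11 - 1) / 11)
})

test_that("segment tests agree on clear nulls and clear effects", {
  set.seed(44)
  n <- 120
  same <- rnorm(n)
  shifted <- c(rnorm(n / 2), rnorm(n / 2, 5))   # 5 pooled-sd shift
  ft <- data.frame(null_feat = same, shift_feat = shifted,
                   class = rep(c("a", "b"), n / 2))
  states <- rep(1:2, each = n / 2)
  sp <- segment_profile(ft, states, n_draws = 3000, seed = 10)
  s1 <- sp[["1"]]
  expect_false(s1$t_significant[s1$feature == "null_feat"])
  expect_false(s1$best_significant[s1$feature == "null_feat"])
  expect_true(s1$t_significant[s1$feature == "shift_feat"])
  expect_true(s1$best_significant[s1$feature == "shift_feat"])
  expect_lt(s1$t_p_value[s1$feature == "shift_feat"], 1e-6)
})

test_that("under-filled states are flagged and skipped", {
  ft <- data.frame(f = rnorm(10), class = rep(c("a", "b"), 5))
  states <- c(rep(1, 9), 2)
  sp <- segment_profile(ft, states, n_draws = 500, seed = 1)
  expect_equal(attr(sp, "skipped"), "2")
  expect_true(is.na(sp[["2"]]$t_p_value))
})

test_that("BEST recovers a known mean difference with a seeded chain", {
  set.seed(20)
  x <- rnorm(150, 3, 1); y <- rnorm(150, 0, 1)
  b1 <- best_test(x, y, n_draws = 4000, seed = 5)
  b2 <- best_test(x, y, n_draws = 4000, seed = 5)
  expect_identical(b1$draws, b2$draws)          # seeded determinism
  expect_true(b1$significant)
  expect_lt(abs(b1$mu_diff - 3), 0.5)
  expect_true(b1$hdi[1] < b1$mu_diff && b1$mu_diff < b1$hdi[2])
  expect_gt(b1$acceptance, 0.05)
})

test_that("the HDI is the shortest interval with the requested mass", {
  set.seed(9)
  x <- rnorm(4000)
  h <- hdi(x, 0.95)
  expect_lt(h[1], 0); expect_gt(h[2], 0)
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.95 - 1e-9)
  expect_lt(h[2] - h[1], 2 * 2.2)   # close to the central 95% width
  skewed <- c(rexp(4000), -0.01)
  hs <- hdi(skewed, 0.9)
  expect_lt(hs[1], stats::quantile(skewed, 0.05))  # leans into the mode
})

test_that("target evaluation is exact for a perfect predictor", {
  d <- data.frame(t = rep(1:3, each = 50), m = rep(1:3, each = 50))
  ft <- data.frame(t = as.numeric(d$t), m = as.numeric(d$m),
                   class = rep(c("x", "y"), 75))
  disc <- structure(d, class = c("discrete_table", "data.frame"),
                    labels = list(t = c("1", "2", "3"), m = c("1", "2", "3")),
                    cond_means = list(t = c(`1` = 1, `2` = 2, `3` = 3),
                                      m = c(`1` = 1, `2` = 2, `3` = 3)))
  net <- chow_liu(d, root = "t", prior_count = 0)
  perf <- evaluate_target(net, ft, disc, "t")
  expect_equal(perf$per_state$reliability_pct, rep(100, 3))
  expect_equal(perf$per_state$precision_pct, rep(100, 3))
  expect_equal(perf$per_state$purity_pct, perf$per_state$reliability_pct)
  expect_equal(perf$per_state$roc_index_pct, rep(100, 3))
  expect_equal(perf$per_state$gini_pct, rep(100, 3))
  expect_equal(unname(perf$global["RMSE"]), 0, tolerance = 1e-9)
  expect_equal(unname(perf$global["R"]), 1, tolerance = 1e-9)
  expect_equal(unname(perf$global["R2"]),
               unname(perf$global["R"])^2, tolerance = 1e-9)
  expect_equal(perf$per_state$occurrence, rep(50L, 3))
})

test_that("an uninformative predictor sits at chance-level discrimination", {
  set.seed(123)
  n <- 2000
  d <- data.frame(t = sample.int(4, n, replace = TRUE),
                  m = sample.int(4, n, replace = TRUE))
  ft <- data.frame(t = as.numeric(d$t) + rnorm(n, 0, 0.1),
                   m = as.numeric(d$m), class = rep(c("x", "y"), n / 2))
  disc <- discretize_apply(ft[, c("t", "m"), drop = FALSE],
                           discretize_fit(ft[, c("t", "m")], n_states = 4))
  d2 <- data.frame(t = d$t, m = d$m)
  attr(d2, "labels") <- attr(disc, "labels")
  attr(d2, "cond_means") <- attr(disc, "cond_means")
  class(d2) <- c("discrete_table", "data.frame")
  net <- suppressWarnings(chow_liu(d, root = "t"))
  if (nrow(net$arcs) == 0) net <- fit_cpts(net, d)
  perf <- evaluate_target(net, ft, d2, "t")
  aucs <- perf$per_state$roc_index_pct
  expect_true(all(abs(aucs[!is.na(aucs)] - 50) < 6))
  ginis <- perf$per_state$gini_pct
  expect_true(all(abs(ginis[!is.na(ginis)]) < 12))
})

test_that("misclassification neighborhoods name the receiving states", {
  d <- data.frame(t = c(rep(1, 30), rep(2, 30)),
                  m = c(rep(1, 30), rep(1, 10), rep(2, 20)))
  ft <- data.frame(t = as.numeric(d$t), m = as.numeric(d$m),
                   class = rep(c("x", "y"), 30))
  disc <- structure(d, class = c("discrete_table", "data.frame"),
                    labels = list(t = c("1", "2"), m = c("1", "2")),
                    cond_means = list(t = c(`1` = 1, `2` = 2),
                                      m = c(`1` = 1, `2` = 2)))
  net <- chow_liu(d, root = "t", prior_count = 0)
  perf <- evaluate_target(net, ft, disc, "t")
  row2 <- perf$per_state[perf$per_state$state == "2", ]
  if (row2$reliability_pct < 100)
    expect_match(row2$neighborhood, "^1 \\(\\d+\\)$")
  expect_equal(sum(perf$confusion), 60)
})
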