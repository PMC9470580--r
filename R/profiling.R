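#' Tornado sensitivity analysis of a target state
#'
#' For every non-target node and each of its states, places hard evidence
#' on that state, computes the exact posterior of `target_state`, and
#' records the delta against the prior. Entries are sorted by absolute
#' delta descending (strongest influences on top). Evidence with zero
#' model probability is skipped with a warning.
#'
#' @param net A fitted `tree_bn`.
#' @param target Target node (default: network root).
#' @param target_state State of interest (label or 1-based index).
#' @return `data.frame` (`node`, `state`, `posterior`, `prior`, `delta`).
#' @export
tornado <- function(net, target = net$root, target_state) {
  ts <- match_state(net, target, target_state)
  prior <- posterior(net, NULL, target)[[ts]]
  rows <- list()
  for (v in setdiff(net$nodes, target)) {
    for (s in seq_along(net$states[[v]])) {
      ev <- stats::setNames(s, v)
      if (evidence_probability(net, ev) <= 0) {
        warning("impossible evidence skipped: ", v, "=", net$states[[v]][s])
        next
      }
      post <- posterior(net, ev, target)[[ts]]
      rows[[length(rows) + 1L]] <-
        data.frame(node = v, state = net$states[[v]][s],
                   posterior = post, prior = prior, delta = post - prior,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$delta), out$node, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

match_state <- function(net, node, state) {
  labs <- net$states[[node]]
  i <- if (is.numeric(state)) as.integer(state) else match(as.character(state), labs)
  if (is.na(i) || i < 1L || i > length(labs))
    stop("invalid state '", state, "' for node '", node, "'")
  i
}

#' Greedy dynamic profile of a target state
#'
#' Starting from the a-priori distribution, greedily accumulates the
#' single (node, state) hard evidence that most increases the posterior
#' of `target_state`, until no strict improvement or `max_steps` is
#' reached. Each step reports the posterior `P(s|H)`, the marginal
#' likelihood of the accumulated evidence `P(H)`, the likelihood
#' `P(H|s) = P(H) P(s|H) / P(s)`, the Bayes factor `BF = P(s|H) / P(s)`,
#' the generalized Bayes factor (posterior odds / prior odds) and, when a
#' `discrete_table` is supplied, prior and posterior state-probability-
#' weighted means of every continuous node.
#'
#' @param net A fitted `tree_bn`.
#' @param target Target node (default: network root).
#' @param target_state State whose probability is maximized.
#' @param disc Optional `discrete_table` (for conditional means).
#' @param max_steps Maximum evidence pieces to accumulate.
#' @return List of class `"dynamic_profile"`: `steps` (`data.frame` with
#'   one row per step, step 0 = a-priori) and `means` (matrix
#'   feature x step of posterior means, `NULL` without `disc`).
#' @export
dynamic_profile <- function(net, target = net$root, target_state,
                            disc = NULL, max_steps = Inf) {
  ts <- match_state(net, target, target_state)
  p_s <- posterior(net, NULL, target)[[ts]]
  steps <- data.frame(step = 0L, node = "a_priori", state = "",
                      posterior_pct = 100 * p_s, marginal_likelihood_pct = 100,
                      likelihood_pct = 100, bayes_factor = 1,
                      generalized_bayes_factor = 1, stringsAsFactors = FALSE)
  ev <- stats::setNames(integer(0), character(0))
  means <- if (!is.null(disc)) list(a_priori = posterior_means(net, ev, disc))
  best <- p_s
  while (length(ev) < min(max_steps, length(net$nodes) - 1L)) {
    cand <- setdiff(net$nodes, c(target, names(ev)))
    if (!length(cand)) break
    top <- NULL
    for (v in cand) for (s in seq_along(net$states[[v]])) {
      ev2 <- c(ev, stats::setNames(s, v))
      if (evidence_probability(net, ev2) <= 0) next
      post <- posterior(net, ev2, target)[[ts]]
      if (is.null(top) || post > top$post) top <- list(v = v, s = s, post = post)
    }
    if (is.null(top) || top$post <= best) break
    ev <- c(ev, stats::setNames(top$s, top$v))
    best <- top$post
    p_h <- evidence_probability(net, ev)
    p_sh <- top$post
    p_hs <- p_h * p_sh / p_s
    odds <- function(p) p / (1 - p)
    steps <- rbind(steps, data.frame(
      step = length(ev), node = top$v,
      state = net$states[[top$v]][top$s],
      posterior_pct = 100 * p_sh, marginal_likelihood_pct = 100 * p_h,
      likelihood_pct = 100 * p_hs, bayes_factor = p_sh / p_s,
      generalized_bayes_factor = odds(p_sh) / odds(p_s),
      stringsAsFactors = FALSE))
    if (!is.null(disc))
      means[[paste0("step_", length(ev))]] <- posterior_means(net, ev, disc)
  }
  out <- list(steps = steps,
              means = if (!is.null(disc)) do.call(cbind, means),
              target = target, target_state = net$states[[target]][ts])
  class(out) <- "dynamic_profile"
  out
}

#' @export
print.dynamic_profile <- function(x, ...) {
  cat(sprintf("Dynamic profile of %s = %s\n", x$target, x$target_state))
  print(x$steps, digits = 4)
  invisible(x)
}

#' Posterior means of continuous nodes given evidence
#'
#' Expected continuous value per node: the posterior state distribution
#' weighted by the per-state conditional means recorded on the
#' `discrete_table`. With empty evidence these are the prior means.
#'
#' @param net A fitted `tree_bn`.
#' @param evidence Named hard-evidence vector (possibly empty).
#' @param disc A `discrete_table` carrying `cond_means`.
#' @return Named numeric vector over the network's nodes.
#' @export
posterior_means <- function(net, evidence, disc) {
  cm <- attr(disc, "cond_means")
  ev <- evidence_indices(net, evidence)
  vapply(net$nodes, function(v) {
    m <- cm[[v]]
    if (is.null(m)) return(NA_real_)
    w <- if (v %in% names(ev)) {
      w0 <- rep(0, length(m)); w0[ev[[v]]] <- 1; w0
    } else posterior(net, ev, v)
    ok <- !is.na(m)
    sum(w[ok] * m[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Evidence optimization tree
#'
#' Depth-first enumeration of hard-evidence sets (nodes taken in fixed
#' lexicographic order, bounded depth) whose exact posterior for
#' `target_state` meets `threshold`. A qualifying path is reported and
#' not extended further, so each reported path is minimal along its
#' branch. The empty path qualifies when the prior already meets the
#' threshold.
#'
#' @param net A fitted `tree_bn`.
#' @param target Target node (default: network root).
#' @param target_state State of interest.
#' @param threshold Required posterior probability, in `(0, 1)` (0 and 1
#'   allowed as degenerate bounds).
#' @param max_depth Maximum number of evidence pieces per path (default 3).
#' @return `data.frame` (`path`, `posterior`, `depth`); zero rows when no
#'   path reaches the threshold.
#' @export
optimization_tree <- function(net, target = net$root, target_state,
                              threshold, max_depth = 3L) {
  ts <- match_state(net, target, target_state)
  res <- list()
  emit <- function(ev, post) {
    lab <- if (length(ev) == 0L) "a_priori" else
      paste(names(ev), vapply(seq_along(ev), function(q)
        net$states[[names(ev)[q]]][ev[q]], character(1)),
        sep = "=", collapse = " + ")
    res[[length(res) + 1L]] <<- data.frame(path = lab, posterior = post,
                                           depth = length(ev),
                                           stringsAsFactors = FALSE)
  }
  nodes <- sort(setdiff(net$nodes, target))
  recurse <- function(ev, from) {
    post <- if (evidence_probability(net, ev) > 0)
      posterior(net, ev, target)[[ts]] else return(invisible())
    if (post >= threshold) { emit(ev, post); return(invisible()) }
    if (length(ev) >= max_depth) return(invisible())
    for (v in nodes[nodes > from | from == ""])
      for (s in seq_along(net$states[[v]]))
        recurse(c(ev, stats::setNames(s, v)), v)
  }
  recurse(stats::setNames(integer(0), character(0)), "")
  if (!length(res))
    return(data.frame(path = character(0), posterior = numeric(0),
                      depth = integer(0)))
  out <- do.call(rbind, res)
  out <- out[order(-out$posterior, out$depth, out$path), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group Bayesian estimation (BEST) test
#'
#' Kruschke-style two-group comparison: each group is modeled with a
#' Student-t likelihood sharing a normality parameter; priors are broad
#' (means: normal centered on the pooled mean with 1000 pooled-sd scale;
#' scales: uniform on pooled sd / 1000 .. pooled sd * 1000; normality:
#' 1 + exponential with mean 29). Sampling is a seeded component-wise
#' random-walk Metropolis chain; the first half is discarded as burn-in.
#' The difference of means is judged credibly non-zero when the 95%
#' highest-density interval excludes 0.
#'
#' @param x,y Numeric samples for the two groups (each `>= 2` values).
#' @param n_draws Total MCMC draws (default 20000).
#' @param seed Optional RNG seed.
#' @param prob HDI mass (default 0.95).
#' @return List of class `"best_test"`: `mu_diff` (posterior mean
#'   difference), `hdi` (interval), `significant`, `draws` (post burn-in
#'   mean-difference draws), `acceptance`.
#' @export
best_test <- function(x, y, n_draws = 20000L, seed = NULL, prob = 0.95) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(x, y)
  m0 <- mean(pooled)
  s0 <- stats::sd(pooled)
  if (s0 == 0) s0 <- 1e-6
  lo_s <- s0 / 1000; hi_s <- s0 * 1000

  loglik <- function(v, mu, ls, lnu) {
    s <- exp(ls); nu <- 1 + exp(lnu)
    sum(stats::dt((v - mu) / s, df = nu, log = TRUE)) - length(v) * ls
  }
  lprior_mu <- function(mu) stats::dnorm(mu, m0, 1000 * s0, log = TRUE)
  lprior_ls <- function(ls) {          # sd ~ Uniform + log-scale Jacobian
    s <- exp(ls)
    if (s < lo_s || s > hi_s) -Inf else ls
  }
  lprior_lnu <- function(lnu) {        # nu - 1 ~ Exp(mean 29), Jacobian
    -log(29) - exp(lnu) / 29 + lnu
  }

  th <- list(mu1 = mean(x), mu2 = mean(y),
             ls1 = log(max(stats::sd(x), lo_s * 2)),
             ls2 = log(max(stats::sd(y), lo_s * 2)),
             lnu = log(29))
  ll1 <- loglik(x, th$mu1, th$ls1, th$lnu)
  ll2 <- loglik(y, th$mu2, th$ls2, th$lnu)
  step <- c(mu1 = 2.5 * stats::sd(x) / sqrt(length(x)),
            mu2 = 2.5 * stats::sd(y) / sqrt(length(y)),
            ls1 = 1.5 / sqrt(length(x)), ls2 = 1.5 / sqrt(length(y)),
            lnu = 0.4)
  step[step == 0 | !is.finite(step)] <- 0.1

  draws <- numeric(n_draws)
  acc <- 0L; tries <- 0L
  for (it in seq_len(n_draws)) {
    for (parm in names(step)) {
      tries <- tries + 1L
      prop <- th
      prop[[parm]] <- th[[parm]] + stats::rnorm(1, 0, step[[parm]])
      p1 <- if (parm %in% c("mu1", "ls1", "lnu"))
        loglik(x, prop$mu1, prop$ls1, prop$lnu) else ll1
      p2 <- if (parm %in% c("mu2", "ls2", "lnu"))
        loglik(y, prop$mu2, prop$ls2, prop$lnu) else ll2
      lpost_new <- p1 + p2 + lprior_mu(prop$mu1) + lprior_mu(prop$mu2) +
        lprior_ls(prop$ls1) + lprior_ls(prop$ls2) + lprior_lnu(prop$lnu)
      lpost_old <- ll1 + ll2 + lprior_mu(th$mu1) + lprior_mu(th$mu2) +
        lprior_ls(th$ls1) + lprior_ls(th$ls2) + lprior_lnu(th$lnu)
      if (is.finite(lpost_new) &&
          log(stats::runif(1)) < lpost_new - lpost_old) {
        th <- prop; ll1 <- p1; ll2 <- p2; acc <- acc + 1L
      }
    }
    draws[it] <- th$mu1 - th$mu2
  }
  keep <- draws[(floor(n_draws / 2) + 1L):n_draws]
  interval <- hdi(keep, prob = prob)
  structure(list(mu_diff = mean(keep), hdi = interval,
                 significant = interval[1L] > 0 || interval[2L] < 0,
                 draws = keep, acceptance = acc / tries),
            class = "best_test")
}

#' @export
print.best_test <- function(x, ...) {
  cat(sprintf("BEST: mean difference %.4g, 95%% HDI [%.4g, %.4g] -> %s\n",
              x$mu_diff, x$hdi[1L], x$hdi[2L],
              if (x$significant) "credibly non-zero" else "not credibly non-zero"))
  invisible(x)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing the requested posterior mass.
#'
#' @param draws Numeric sample.
#' @param prob Mass (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.95) {
  s <- sort(draws)
  n <- length(s)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(s[1L], s[n]))
  widths <- s[(m + 1L):n] - s[1L:(n - m)]
  i <- which.min(widths)
  c(s[i], s[i + m])
}

#' Segment profiles of the target's states
#'
#' For each target state: per feature, the normalized conditional mean
#' `(mean within state - global min) / (global max - global min)`
#' (radar-chart coordinates in `[0, 1]`), a two-tailed Welch t test of
#' the state's rows against the rest, and a BEST test (see [best_test()])
#' judged on the 95% HDI. States with fewer than 2 rows are flagged and
#' their tests skipped.
#'
#' @param features Feature table (continuous columns).
#' @param states Discrete target column (integer indices or factor),
#'   one per row.
#' @param state_labels Optional labels (default: sorted unique states).
#' @param n_draws BEST draws per test (default 20000).
#' @param seed Optional RNG seed (offset per state/feature for
#'   reproducibility).
#' @param alpha Welch-test significance level (default 0.05).
#' @return Named list of class `"segment_profiles"`, one `data.frame`
#'   per state (`feature`, `normalized_mean`, `t_p_value`,
#'   `t_significant`, `best_significant`, `hdi_lo`, `hdi_hi`), with a
#'   `skipped` attribute naming under-filled states.
#' @export
segment_profile <- function(features, states, state_labels = NULL,
                            n_draws = 20000L, seed = NULL, alpha = 0.05) {
  X <- feature_columns(features)
  st <- if (is.factor(states)) as.integer(states) else as.integer(states)
  labs <- state_labels %||%
    (if (is.factor(states)) levels(states) else as.character(sort(unique(st))))
  skipped <- character(0)
  out <- lapply(seq_along(labs), function(s) {
    sel <- st == s
    res <- data.frame(feature = names(X),
                      normalized_mean = NA_real_, t_p_value = NA_real_,
                      t_significant = NA, best_significant = NA,
                      hdi_lo = NA_real_, hdi_hi = NA_real_,
                      stringsAsFactors = FALSE)
    for (f in seq_along(X)) {
      x <- X[[f]]
      rng <- range(x)
      res$normalized_mean[f] <- if (diff(rng) > 0)
        (mean(x[sel]) - rng[1L]) / diff(rng) else 0.5
      if (sum(sel) < 2L || sum(!sel) < 2L) next
      tt <- stats::t.test(x[sel], x[!sel])
      res$t_p_value[f] <- tt$p.value
      res$t_significant[f] <- tt$p.value < alpha
      bt <- best_test(x[sel], x[!sel], n_draws = n_draws,
                      seed = if (!is.null(seed)) seed + 1000L * s + f)
      res$best_significant[f] <- bt$significant
      res$hdi_lo[f] <- bt$hdi[1L]; res$hdi_hi[f] <- bt$hdi[2L]
    }
    if (sum(sel) < 2L) skipped <<- c(skipped, labs[s])
    res
  })
  names(out) <- labs
  structure(out, class = "segment_profiles", skipped = skipped)
}

#' Target-prediction performance report
#'
#' Predicts each row's target state from hard evidence on all other
#' nodes (exact posterior argmax; ties to the lowest state index) and
#' reports, per state: occurrence (actual count), reliability
#' (100 * correct / actual, also reported as purity), precision
#' (100 * correct / predicted), one-vs-rest ROC index (AUC, %) of the
#' state's posterior probability, Gini index (2 AUC - 100) and the
#' neighborhood (states receiving that state's misclassified rows,
#' ordered by count). The global numeric fit maps each row's posterior
#' to a predicted continuous value via the per-state conditional means
#' and reports R, R2, RMSE and NRMSE (RMSE / target range).
#'
#' @param net A fitted `tree_bn`.
#' @param features Feature table with the continuous target column.
#' @param disc The fitted `discrete_table`.
#' @param target Target node (default: network root).
#' @return List of class `"performance_report"`: `per_state`
#'   (`data.frame`), `global` (named numeric), `confusion` (matrix
#'   actual x predicted).
#' @export
evaluate_target <- function(net, features, disc, target = net$root) {
  X <- feature_columns(features)
  labs <- net$states[[target]]
  k <- length(labs)
  actual <- as.integer(as.data.frame(disc)[[target]])
  probs <- predict(net, disc, target = target, type = "prob")
  pred <- apply(probs, 1L, which.max)

  confusion <- matrix(0L, k, k, dimnames = list(actual = labs, predicted = labs))
  for (r in seq_along(actual))
    confusion[actual[r], pred[r]] <- confusion[actual[r], pred[r]] + 1L

  per_state <- do.call(rbind, lapply(seq_len(k), function(s) {
    occ <- sum(actual == s)
    predicted <- sum(pred == s)
    correct <- confusion[s, s]
    auc <- if (occ > 0 && occ < length(actual)) {
      100 * as.numeric(pROC::auc(pROC::roc(
        response = actual == s, predictor = probs[, s],
        levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    } else NA_real_
    errs <- confusion[s, , drop = TRUE][-s]
    nb <- if (occ > correct) {
      ord <- order(-errs, names(errs))
      nz <- errs[ord][errs[ord] > 0]
      paste0(names(nz), " (", nz, ")", collapse = "; ")
    } else ""
    data.frame(state = labs[s], occurrence = occ,
               reliability_pct = if (occ > 0) 100 * correct / occ else NA_real_,
               precision_pct = if (predicted > 0)
                 100 * correct / predicted else NA_real_,
               purity_pct = if (occ > 0) 100 * correct / occ else NA_real_,
               roc_index_pct = auc,
               gini_pct = if (is.na(auc)) NA_real_ else 2 * auc - 100,
               neighborhood = nb, stringsAsFactors = FALSE)
  }))
  rownames(per_state) <- NULL

  cm <- attr(disc, "cond_means")[[target]]
  ok <- !is.na(cm)
  pv <- as.vector(probs[, ok, drop = FALSE] %*% cm[ok]) /
    rowSums(probs[, ok, drop = FALSE])
  av <- X[[target]]
  r <- stats::cor(pv, av)
  rmse <- sqrt(mean((pv - av)^2))
  global <- c(R = r, R2 = r^2, RMSE = rmse, NRMSE = rmse / diff(range(av)))
  structure(list(per_state = per_state, global = global,
                 confusion = confusion),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Target performance by state:\n")
  print(x$per_state, digits = 4)
  cat(sprintf("Global: R = %.4f, R2 = %.4f, RMSE = %.4f, NRMSE = %.4f\n",
              x$global["R"], x$global["R2"], x$global["RMSE"],
              x$global["NRMSE"]))
  invisible(x)
}
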