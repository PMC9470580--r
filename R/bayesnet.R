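#' Learn a tree-structured Bayesian network (Chow-Liu)
#'
#' Computes pairwise mutual information between all node pairs, builds the
#' maximum-weight spanning tree over it (Kruskal with a stable
#' lexicographic tie-break on node-name pairs, for determinism), orients
#' every arc away from `root`, and fits smoothed conditional probability
#' tables. The resulting tree maximizes total arc MI, the optimal
#' tree-structured approximation to the joint distribution.
#'
#' Pairs with zero estimated MI contribute no edge; if every pair has zero
#' MI the result is a forest of isolated nodes (with a warning). In a
#' forest, components not containing `root` are rooted at their
#' lexicographically first node.
#'
#' @param data A `discrete_table` (see [discretize_apply()]) or a
#'   `data.frame` of factors / integer state columns.
#' @param root Node the arcs point away from (default: first column).
#'   Conventionally the analysis target.
#' @param prior_count Dirichlet smoothing count per CPT cell (default 1).
#' @param pseudo_count Smoothing for the MI estimates used as edge weights
#'   (default 0 = raw frequencies).
#' @return Object of class `"tree_bn"`: list with `nodes`, `states`
#'   (per-node state labels), `arcs` (`data.frame` parent/child), `root`,
#'   `cpts` (root nodes: probability vector; children: matrix
#'   `[parent_state, child_state]`), `mi` (edge-weight matrix), `n`,
#'   `prior_count`.
#' @examples
#' d <- data.frame(a = rep(1:2, 50), b = rep(1:2, 50))
#' net <- chow_liu(d, root = "a")
#' net$arcs
#' @export
chow_liu <- function(data, root = NULL, prior_count = 1, pseudo_count = 0) {
  df <- as.data.frame(data)
  nodes <- names(df)
  if (length(nodes) < 2L) stop("need at least 2 nodes")
  if (nrow(df) < 1L) stop("need at least 1 row")
  states <- table_states(data)
  root <- root %||% nodes[1L]
  if (!root %in% nodes) stop("root '", root, "' is not a column of `data`")

  p <- length(nodes)
  mi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
    mi[a, b] <- mi[b, a] <-
      mutual_information(df[[a]], df[[b]], pseudo_count = pseudo_count)
  }

  edges <- max_spanning_tree(mi)
  if (nrow(edges) == 0L)
    warning("all pairwise MI are zero: returning a forest of isolated nodes")

  arcs <- orient_arcs(nodes, edges, root)
  net <- structure(list(nodes = nodes, states = states, arcs = arcs,
                        root = root, cpts = NULL, mi = mi,
                        n = nrow(df), prior_count = prior_count),
                   class = "tree_bn")
  fit_cpts(net, data, prior_count = prior_count)
}

# state labels per column: discrete_table labels, else factor levels /
# sorted unique values
table_states <- function(data) {
  labs <- attr(data, "labels")
  df <- as.data.frame(data)
  out <- lapply(names(df), function(f) {
    if (!is.null(labs[[f]])) labs[[f]]
    else if (is.factor(df[[f]])) levels(df[[f]])
    else as.character(sort(unique(df[[f]])))
  })
  names(out) <- names(df)
  out
}

# Kruskal maximum-weight spanning tree with lexicographic tie-break.
# Returns a data.frame(a, b) of undirected edges (a < b lexicographically).
max_spanning_tree <- function(mi) {
  nodes <- rownames(mi)
  p <- length(nodes)
  cand <- do.call(rbind, lapply(seq_len(p - 1L), function(a)
    data.frame(a = nodes[a], b = nodes[(a + 1L):p],
               w = mi[a, (a + 1L):p], stringsAsFactors = FALSE)))
  swap <- cand$b < cand$a
  tmp <- cand$a[swap]; cand$a[swap] <- cand$b[swap]; cand$b[swap] <- tmp
  cand <- cand[cand$w > 0, , drop = FALSE]
  cand <- cand[order(-cand$w, cand$a, cand$b), , drop = FALSE]
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  keep <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    ra <- find(cand$a[e]); rb <- find(cand$b[e])
    if (ra != rb) { parent[[ra]] <- rb; keep[e] <- TRUE }
  }
  cand[keep, c("a", "b"), drop = FALSE]
}

# orient undirected edges away from `root` (BFS); extra components rooted
# at their lexicographically first node
orient_arcs <- function(nodes, edges, root) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges$a[e]]] <- c(adj[[edges$a[e]]], edges$b[e])
    adj[[edges$b[e]]] <- c(adj[[edges$b[e]]], edges$a[e])
  }
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  arcs <- data.frame(parent = character(0), child = character(0),
                     stringsAsFactors = FALSE)
  comp_roots <- c(root, setdiff(sort(nodes), root))
  for (r in comp_roots) {
    if (visited[[r]]) next
    queue <- r; visited[[r]] <- TRUE
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in sort(adj[[u]])) {
        if (!visited[[v]]) {
          visited[[v]] <- TRUE
          arcs <- rbind(arcs, data.frame(parent = u, child = v,
                                         stringsAsFactors = FALSE))
          queue <- c(queue, v)
        }
      }
    }
  }
  rownames(arcs) <- NULL
  arcs
}

#' Fit conditional probability tables on a fixed tree structure
#'
#' Estimates every CPT entry as `(count + prior_count) /
#' (total + prior_count * k)` with `k` the number of child states
#' (Dirichlet smoothing; `prior_count = 0` gives the MLE). Unseen parent
#' configurations fall back to the uniform prior.
#'
#' @param net A `tree_bn`.
#' @param data Discrete data with the network's columns.
#' @param prior_count Smoothing count (default: the network's).
#' @return The network with `cpts` (re)fitted.
#' @export
fit_cpts <- function(net, data, prior_count = net$prior_count) {
  df <- as.data.frame(data)
  idx <- state_indices(net, df)
  parent_of <- stats::setNames(net$arcs$parent, net$arcs$child)
  cpts <- lapply(net$nodes, function(v) {
    k <- length(net$states[[v]])
    if (is.na(parent_of[v])) {
      cnt <- tabulate(idx[[v]], nbins = k)
      pr <- (cnt + prior_count) / (sum(cnt) + prior_count * k)
      stats::setNames(pr, net$states[[v]])
    } else {
      pa <- parent_of[[v]]
      kp <- length(net$states[[pa]])
      cnt <- matrix(tabulate(idx[[pa]] + kp * (idx[[v]] - 1L), nbins = kp * k),
                    kp, k)
      pr <- (cnt + prior_count) / (rowSums(cnt) + prior_count * k)
      dimnames(pr) <- list(net$states[[pa]], net$states[[v]])
      pr
    }
  })
  names(cpts) <- net$nodes
  net$cpts <- cpts
  net$prior_count <- prior_count
  net$n <- nrow(df)
  net
}

# map data columns to 1-based state indices per the network's state labels
state_indices <- function(net, df, nodes = net$nodes) {
  out <- lapply(nodes, function(v) {
    if (!v %in% names(df)) stop("data lacks node column '", v, "'")
    x <- df[[v]]
    labs <- net$states[[v]]
    i <- if (is.numeric(x) && !is.factor(x)) as.integer(x)
         else match(as.character(x), labs)
    if (anyNA(i) || any(i < 1L | i > length(labs)))
      stop("invalid states in column '", v, "'")
    i
  })
  names(out) <- nodes
  as.data.frame(out)
}

parents_of <- function(net) {
  pa <- stats::setNames(rep(NA_character_, length(net$nodes)), net$nodes)
  pa[net$arcs$child] <- net$arcs$parent
  pa
}

# children-before-parents elimination order: peel leaves repeatedly
elimination_order <- function(net) {
  pa <- parents_of(net)
  ord <- character(0)
  remaining <- net$nodes
  while (length(remaining)) {
    leaves <- setdiff(remaining, pa[remaining])  # no remaining child
    ord <- c(ord, leaves)
    remaining <- setdiff(remaining, leaves)
  }
  ord
}

# normalize user evidence to a named integer vector of state indices
evidence_indices <- function(net, evidence) {
  if (length(evidence) == 0L) return(stats::setNames(integer(0), character(0)))
  nm <- names(evidence)
  if (is.null(nm) || any(nm == "")) stop("evidence must be a named vector")
  if (anyDuplicated(nm)) stop("duplicate evidence nodes: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  bad <- setdiff(nm, net$nodes)
  if (length(bad)) stop("evidence on unknown node(s): ",
                        paste(bad, collapse = ", "))
  out <- integer(length(nm))
  for (q in seq_along(nm)) {
    labs <- net$states[[nm[q]]]
    v <- evidence[[q]]
    i <- if (is.numeric(v)) as.integer(v) else match(as.character(v), labs)
    if (is.na(i) || i < 1L || i > length(labs))
      stop("invalid state '", v, "' for node '", nm[q], "'")
    out[q] <- i
  }
  stats::setNames(out, nm)
}

#' Probability of hard evidence under the network
#'
#' Marginal probability `P(H)` of a joint hard-evidence assignment,
#' computed exactly by message passing up the tree (sum over all
#' completions of the factorized joint). Empty evidence has probability 1.
#'
#' @param net A fitted `tree_bn`.
#' @param evidence Named vector mapping nodes to states (labels or
#'   1-based indices); may be empty.
#' @return Probability in `(0, 1]` (0 is possible for unsmoothed CPTs).
#' @export
evidence_probability <- function(net, evidence = NULL) {
  ev <- evidence_indices(net, evidence)
  pa <- parents_of(net)
  # lambda[[v]]: vector over states of v combining v's evidence and the
  # messages from v's children
  lambda <- lapply(net$states, function(s) rep(1, length(s)))
  for (v in names(ev)) {
    ind <- rep(0, length(net$states[[v]]))
    ind[ev[[v]]] <- 1
    lambda[[v]] <- ind
  }
  prob <- 1
  for (v in elimination_order(net)) {
    if (is.na(pa[[v]])) {
      prob <- prob * sum(net$cpts[[v]] * lambda[[v]])
    } else {
      msg <- as.vector(net$cpts[[v]] %*% lambda[[v]])   # over parent states
      lambda[[pa[[v]]]] <- lambda[[pa[[v]]]] * msg
    }
  }
  prob
}

#' Exact posterior of a query node given hard evidence
#'
#' `P(query | evidence)` computed exactly on the tree: for each query
#' state the evidence is extended with it and the evidence probabilities
#' are normalized. Errors if the evidence itself has probability 0 under
#' the model, naming the contradictory evidence.
#'
#' @param net A fitted `tree_bn`.
#' @param evidence Named vector of hard evidence (possibly empty / `NULL`);
#'   must not include `query`.
#' @param query Node to query.
#' @return Named probability vector over the query node's states.
#' @export
posterior <- function(net, evidence = NULL, query) {
  if (!query %in% net$nodes) stop("unknown query node '", query, "'")
  ev <- evidence_indices(net, evidence)
  if (query %in% names(ev)) stop("query node must not carry evidence")
  labs <- net$states[[query]]
  joint <- vapply(seq_along(labs), function(s)
    evidence_probability(net, c(ev, stats::setNames(s, query))), numeric(1))
  tot <- sum(joint)
  if (tot <= 0)
    stop("evidence has zero probability under the model: ",
         paste(names(ev), vapply(seq_along(ev), function(q)
           net$states[[names(ev)[q]]][ev[q]], character(1)),
           sep = "=", collapse = ", "))
  stats::setNames(joint / tot, labs)
}

#' Minimum description length score of a fitted network
#'
#' Two-part code: the data term is the negative base-2 log-likelihood of
#' the rows under the fitted (smoothed) CPTs; the structure term charges
#' `log2(n) / 2` bits per free CPT parameter. Lower totals indicate a
#' better complexity/fit trade-off.
#'
#' @param net A fitted `tree_bn`.
#' @param data Discrete data (rows to encode).
#' @return List of class `"mdl_score"`: `data_bits`, `structure_bits`,
#'   `total_bits`, `n_parameters`.
#' @export
mdl_score <- function(net, data) {
  df <- as.data.frame(data)
  idx <- state_indices(net, df)
  pa <- parents_of(net)
  ll2 <- 0
  npar <- 0
  for (v in net$nodes) {
    k <- length(net$states[[v]])
    if (is.na(pa[[v]])) {
      ll2 <- ll2 + sum(log2(net$cpts[[v]][idx[[v]]]))
      npar <- npar + (k - 1)
    } else {
      ll2 <- ll2 + sum(log2(net$cpts[[v]][cbind(idx[[pa[[v]]]], idx[[v]])]))
      npar <- npar + (k - 1) * length(net$states[[pa[[v]]]])
    }
  }
  data_bits <- -ll2
  structure_bits <- 0.5 * log2(nrow(df)) * npar
  structure(list(data_bits = data_bits, structure_bits = structure_bits,
                 total_bits = data_bits + structure_bits,
                 n_parameters = npar),
            class = "mdl_score")
}

#' @export
print.mdl_score <- function(x, ...) {
  cat(sprintf("MDL: %.2f bits (data %.2f + structure %.2f; %d parameters)\n",
              x$total_bits, x$data_bits, x$structure_bits, x$n_parameters))
  invisible(x)
}

#' @export
print.tree_bn <- function(x, ...) {
  cat(sprintf("Tree Bayesian network: %d nodes, %d arcs, root '%s' (n = %d)\n",
              length(x$nodes), nrow(x$arcs), x$root, x$n))
  if (nrow(x$arcs))
    cat(paste0("  ", x$arcs$parent, " -> ", x$arcs$child, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.tree_bn <- function(object, ...) {
  arcs <- object$arcs
  if (nrow(arcs)) {
    arcs$kl_force_bits <- vapply(seq_len(nrow(arcs)), function(e)
      arc_kl_force(object, arcs$parent[e], arcs$child[e]), numeric(1))
    arcs <- arcs[order(-arcs$kl_force_bits), , drop = FALSE]
    rownames(arcs) <- NULL
  }
  out <- list(nodes = object$nodes, root = object$root, n = object$n,
              arcs = arcs,
              states_per_node = vapply(object$states, length, integer(1)))
  class(out) <- "summary.tree_bn"
  out
}

#' @export
print.summary.tree_bn <- function(x, ...) {
  cat(sprintf("Tree Bayesian network: %d nodes, root '%s', fitted on n = %d\n",
              length(x$nodes), x$root, x$n))
  cat("States per node:\n")
  print(x$states_per_node)
  if (nrow(x$arcs)) {
    cat("Arcs by KL force (bits):\n")
    print(x$arcs, digits = 4)
  } else cat("No arcs (empty forest)\n")
  invisible(x)
}

#' @export
coef.tree_bn <- function(object, ...) object$cpts

#' @export
logLik.tree_bn <- function(object, data, ...) {
  sc <- mdl_score(object, data)
  structure(-sc$data_bits * log(2), df = sc$n_parameters,
            nobs = nrow(as.data.frame(data)), class = "logLik")
}

#' Simulate rows from a fitted tree network
#'
#' Ancestral sampling: roots from their marginal CPTs, children from the
#' CPT row selected by the sampled parent state.
#'
#' @param object A fitted `tree_bn`.
#' @param nsim Number of rows.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return `data.frame` of factors (levels = state labels).
#' @export
simulate.tree_bn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pa <- parents_of(object)
  ord <- rev(elimination_order(object))   # parents before children
  out <- stats::setNames(vector("list", length(object$nodes)), object$nodes)
  for (v in ord) {
    k <- length(object$states[[v]])
    if (is.na(pa[[v]])) {
      out[[v]] <- sample.int(k, nsim, replace = TRUE, prob = object$cpts[[v]])
    } else {
      pstates <- out[[pa[[v]]]]
      u <- stats::runif(nsim)
      cum <- t(apply(object$cpts[[v]], 1L, cumsum))
      out[[v]] <- vapply(seq_len(nsim), function(r)
        findInterval(u[r], cum[pstates[r], ], left.open = TRUE) + 1L,
        integer(1))
    }
  }
  df <- as.data.frame(out[object$nodes])
  for (v in object$nodes)
    df[[v]] <- factor(object$states[[v]][df[[v]]],
                      levels = object$states[[v]])
  df
}

#' Predict the target state for observed rows
#'
#' For each row, places hard evidence on every non-target node present in
#' `newdata` and returns the exact posterior over the target; the
#' predicted state is the argmax (ties broken toward the lowest state
#' index, for determinism).
#'
#' @param object A fitted `tree_bn`.
#' @param newdata Discrete data (states as labels, factors or indices).
#' @param target Node to predict (default: the network root).
#' @param type `"state"` for predicted state indices (with labels as
#'   names) or `"prob"` for the posterior matrix (rows x states).
#' @param ... Unused.
#' @export
predict.tree_bn <- function(object, newdata, target = object$root,
                            type = c("state", "prob"), ...) {
  type <- match.arg(type)
  df <- as.data.frame(newdata)
  others <- intersect(setdiff(object$nodes, target), names(df))
  idx <- state_indices(object, df, nodes = others)
  labs <- object$states[[target]]
  probs <- t(vapply(seq_len(nrow(df)), function(r) {
    ev <- stats::setNames(as.integer(idx[r, others]), others)
    posterior(object, ev, target)
  }, numeric(length(labs))))
  colnames(probs) <- labs
  if (type == "prob") return(probs)
  st <- apply(probs, 1L, which.max)   # which.max: first (lowest) index on ties
  stats::setNames(st, labs[st])
}

#' Plot a tree network
#'
#' Simple layered layout: the root on top, children below their parents.
#'
#' @param x A `tree_bn`.
#' @param ... Passed to [graphics::text()].
#' @export
plot.tree_bn <- function(x, ...) {
  pa <- parents_of(x)
  depth <- stats::setNames(rep(0L, length(x$nodes)), x$nodes)
  for (v in rev(elimination_order(x))) # parents first
    if (!is.na(pa[[v]])) depth[[v]] <- depth[[pa[[v]]]] + 1L
  ypos <- -depth
  xpos <- stats::setNames(rep(0, length(x$nodes)), x$nodes)
  for (d in sort(unique(depth))) {
    at <- names(depth)[depth == d]
    xpos[at] <- seq_along(at) - (length(at) + 1) / 2
  }
  graphics::plot(xpos, ypos, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = range(xpos) + c(-0.5, 0.5),
                 ylim = range(ypos) + c(-0.5, 0.5))
  for (e in seq_len(nrow(x$arcs)))
    graphics::arrows(xpos[[x$arcs$parent[e]]], ypos[[x$arcs$parent[e]]] - 0.08,
                     xpos[[x$arcs$child[e]]], ypos[[x$arcs$child[e]]] + 0.08,
                     length = 0.08, col = "grey40")
  graphics::text(xpos, ypos, names(xpos), ...)
  invisible(x)
}
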