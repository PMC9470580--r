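#' Exact pairwise marginal of two nodes under the fitted network
#'
#' @param net A fitted `tree_bn`.
#' @param a,b Distinct node names.
#' @return Matrix `P(a, b)` (rows = states of `a`) summing to 1.
#' @export
pairwise_marginal <- function(net, a, b) {
  if (a == b) stop("`a` and `b` must differ")
  ka <- length(net$states[[a]]); kb <- length(net$states[[b]])
  P <- matrix(0, ka, kb, dimnames = list(net$states[[a]], net$states[[b]]))
  for (i in seq_len(ka)) for (j in seq_len(kb))
    P[i, j] <- evidence_probability(net, stats::setNames(c(i, j), c(a, b)))
  P / sum(P)
}

#' Kullback-Leibler force of an arc
#'
#' Information lost by deleting the arc: the KL divergence (bits) between
#' the fitted joint distribution and the same network with the arc
#' removed and the child carrying its marginal instead of its conditional.
#' On a tree this reduces exactly to the mutual information of the two
#' endpoints under the fitted joint, computed here from the exact pairwise
#' marginal.
#'
#' @param net A fitted `tree_bn`.
#' @param parent,child Endpoints of an arc in the network.
#' @return KL force in bits (`>= 0`).
#' @export
arc_kl_force <- function(net, parent, child) {
  hit <- net$arcs$parent == parent & net$arcs$child == child
  if (!any(hit)) stop("no arc ", parent, " -> ", child, " in the network")
  mi_from_joint(pairwise_marginal(net, parent, child))
}

#' Pearson correlation of two continuous feature columns
#'
#' Product-moment correlation on the continuous (pre-discretization)
#' values. Constant columns are an error.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant column")
  stats::cor(x, y)
}

#' Likelihood-ratio (G) test of independence for two discrete columns
#'
#' `G = 2 sum O ln(O / E)` over non-empty cells of the contingency table,
#' referred to a chi-square distribution with `(r - 1)(c - 1)` degrees of
#' freedom.
#'
#' @param x,y Discrete samples of equal length.
#' @return List `statistic` (G), `df`, `p_value`.
#' @export
gkl_independence_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  tab <- table(x, y)
  if (sum(tab) == 0L) stop("empty contingency table")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = 0, df = 0L, p_value = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = G, df = df,
       p_value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Arc-strength report
#'
#' One row per arc of the fitted network, sorted by KL force descending:
#' KL force and endpoint mutual information in bits (computed from the
#' smoothed fitted joint, matching inference; identical for a tree arc),
#' Pearson correlation of the endpoints' continuous columns, relative
#' weight (KL / max KL), overall contribution (100 * KL / sum KL) and the
#' G-test p-value on the discrete columns.
#'
#' @param net A fitted `tree_bn`.
#' @param features Feature table with the continuous columns.
#' @param disc The `discrete_table` the network was fitted on.
#' @return `data.frame` of class `"arc_strengths"`.
#' @export
strength_table <- function(net, features, disc) {
  arcs <- net$arcs
  if (nrow(arcs) == 0L) stop("network has no arcs")
  X <- feature_columns(features)
  out <- do.call(rbind, lapply(seq_len(nrow(arcs)), function(e) {
    p <- arcs$parent[e]; ch <- arcs$child[e]
    pm <- pairwise_marginal(net, p, ch)
    data.frame(parent = p, child = ch,
               kl_divergence = mi_from_joint(pm),
               mutual_information = mi_from_joint(pm),
               pearson_r = pearson_r(X[[p]], X[[ch]]),
               p_value = gkl_independence_test(disc[[p]], disc[[ch]])$p_value,
               stringsAsFactors = FALSE)
  }))
  out$relative_weight <- out$kl_divergence / max(out$kl_divergence)
  out$contribution_pct <- 100 * out$kl_divergence / sum(out$kl_divergence)
  out <- out[order(-out$kl_divergence, out$parent, out$child), ,
             drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("parent", "child", "kl_divergence", "relative_weight",
                 "contribution_pct", "mutual_information", "pearson_r",
                 "p_value")]
  class(out) <- c("arc_strengths", "data.frame")
  out
}

#' Node-force report
#'
#' Per node: outgoing force = sum of KL forces of arcs leaving the node,
#' incoming force = sum over arcs entering it, total = outgoing + incoming.
#' Sorted by total force descending.
#'
#' @param strengths An `"arc_strengths"` table (or any `data.frame` with
#'   `parent`, `child`, `kl_divergence` columns).
#' @param nodes Optional node universe (to include isolated nodes as
#'   zero rows).
#' @return `data.frame` (`node`, `outgoing`, `incoming`, `total`).
#' @export
node_force <- function(strengths, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(strengths$parent, strengths$child)))
  outg <- vapply(nodes, function(v)
    sum(strengths$kl_divergence[strengths$parent == v]), numeric(1))
  inc <- vapply(nodes, function(v)
    sum(strengths$kl_divergence[strengths$child == v]), numeric(1))
  out <- data.frame(node = nodes, outgoing = unname(outg),
                    incoming = unname(inc),
                    total = unname(outg + inc), stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-association report
#'
#' Per non-target node: mutual information with the target (bits, from
#' the exact fitted pairwise marginal), normalized MI as a percentage of
#' the target's entropy, relative significance (MI / max MI), prior mean
#' of the node's continuous values, and the G-test p-value against the
#' target. Sorted by MI descending.
#'
#' @param net A fitted `tree_bn`.
#' @param features Feature table with continuous columns.
#' @param disc The fitted `discrete_table`.
#' @param target Target node (default: network root).
#' @return `data.frame` of class `"target_associations"`.
#' @export
target_table <- function(net, features, disc, target = net$root) {
  if (!target %in% net$nodes) stop("unknown target '", target, "'")
  X <- feature_columns(features)
  h_t <- shannon_entropy(posterior(net, NULL, target))
  others <- setdiff(net$nodes, target)
  out <- do.call(rbind, lapply(others, function(v) {
    mi <- mi_from_joint(pairwise_marginal(net, v, target))
    data.frame(node = v, mutual_information = mi,
               normalized_mi_pct = 100 * mi / h_t,
               prior_mean = mean(X[[v]]),
               p_value = gkl_independence_test(disc[[v]], disc[[target]])$p_value,
               stringsAsFactors = FALSE)
  }))
  out$relative_significance <- out$mutual_information /
    max(out$mutual_information)
  out <- out[order(-out$mutual_information, out$node),
             c("node", "mutual_information", "normalized_mi_pct",
               "relative_significance", "prior_mean", "p_value"),
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_associations", "data.frame")
  out
}
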