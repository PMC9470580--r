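# Independent oracles used across the suite: literal enumerations and
# double-loop summations, deliberately naive so they share no code with
# the implementation they check.

# all state-combination rows for a network (data.frame of indices)
enum_grid <- function(net) {
  expand.grid(lapply(net$states, seq_along), KEEP.OUT.ATTRS = FALSE)
}

# joint probability of one full assignment by multiplying CPT entries
enum_row_prob <- function(net, row) {
  pa <- structure(rep(NA_character_, length(net$nodes)), names = net$nodes)
  pa[net$arcs$child] <- net$arcs$parent
  p <- 1
  for (v in net$nodes) {
    p <- p * if (is.na(pa[[v]])) net$cpts[[v]][row[[v]]]
             else net$cpts[[v]][row[[pa[[v]]]], row[[v]]]
  }
  unname(p)
}

enum_evidence_prob <- function(net, evidence) {
  g <- enum_grid(net)
  keep <- rep(TRUE, nrow(g))
  for (v in names(evidence)) {
    s <- evidence[[v]]
    if (!is.numeric(s)) s <- match(s, net$states[[v]])
    keep <- keep & g[[v]] == s
  }
  sum(vapply(which(keep), function(r) enum_row_prob(net, g[r, ]), numeric(1)))
}

enum_posterior <- function(net, evidence, query) {
  k <- length(net$states[[query]])
  joint <- vapply(seq_len(k), function(s)
    enum_evidence_prob(net, c(as.list(evidence),
                              stats::setNames(list(s), query))), numeric(1))
  stats::setNames(joint / sum(joint), net$states[[query]])
}

# random tree network with random CPTs (for inference property tests)
random_tree_net <- function(n_nodes, max_states = 4L) {
  nodes <- paste0("v", seq_len(n_nodes))
  k <- sample(2:max_states, n_nodes, replace = TRUE)
  # random tree: each node i>1 attaches to a random earlier node
  arcs <- if (n_nodes > 1L)
    data.frame(parent = nodes[vapply(2:n_nodes, function(i)
      sample.int(i - 1L, 1L), integer(1))], child = nodes[-1L],
      stringsAsFactors = FALSE)
  else data.frame(parent = character(0), child = character(0))
  states <- lapply(seq_len(n_nodes), function(i) paste0("s", seq_len(k[i])))
  names(states) <- nodes
  rdir <- function(m) { x <- stats::rgamma(m, 1) + 0.05; x / sum(x) }
  cpts <- lapply(seq_len(n_nodes), function(i) {
    v <- nodes[i]
    paname <- arcs$parent[arcs$child == v]
    if (length(paname) == 0L) stats::setNames(rdir(k[i]), states[[v]])
    else {
      kp <- length(states[[paname]])
      m <- t(vapply(seq_len(kp), function(j) rdir(k[i]), numeric(k[i])))
      dimnames(m) <- list(states[[paname]], states[[v]])
      m
    }
  })
  names(cpts) <- nodes
  structure(list(nodes = nodes, states = states, arcs = arcs,
                 root = nodes[1L], cpts = cpts, mi = NULL,
                 n = 0L, prior_count = 0),
            class = "tree_bn")
}

# literal double-loop texture statistics on a normalized matrix
haralick_oracle <- function(P) {
  M <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:M) mux <- mux + i * px[i]
  for (j in 1:M) muy <- muy + j * py[j]
  sx <- 0; sy <- 0
  for (i in 1:M) sx <- sx + (i - mux)^2 * px[i]
  for (j in 1:M) sy <- sy + (j - muy)^2 * py[j]
  sx <- sqrt(sx); sy <- sqrt(sy)
  acc <- con <- c1 <- c2 <- cp <- cs <- dis <- ene <- ent <- h1 <- h2 <- 0
  for (i in 1:M) for (j in 1:M) {
    p <- P[i, j]
    acc <- acc + i * j * p
    con <- con + (i - j)^2 * p
    c1 <- c1 + (i - mux) * (j - muy) * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    if (p > 0) ent <- ent - p * log(p)
    h1 <- h1 + p / (1 + abs(i - j))
    h2 <- h2 + p / (1 + (i - j)^2)
  }
  c1 <- c1 / (sx * sy)
  c2 <- (acc - mux * muy) / (sx * sy)
  sa <- 0; pk <- numeric(2 * M)
  for (i in 1:M) for (j in 1:M) pk[i + j] <- pk[i + j] + P[i, j]
  for (kk in 2:(2 * M)) sa <- sa + kk * pk[kk]
  sv <- 0
  for (kk in 2:(2 * M)) sv <- sv + (kk - sa)^2 * pk[kk]
  c(autocorrelation = acc, cluster_prominence = cp, cluster_shade = cs,
    contrast = con, correlation1 = c1, correlation2 = c2,
    dissimilarity = dis, energy = ene, entropy = ent,
    homogeneity1 = h1, homogeneity2 = h2, max_probability = max(P),
    sum_variance = sv)
}

# brute-force co-occurrence by scanning every pixel pair
cooccurrence_oracle <- function(img, dr, dc, M, symmetric = FALSE) {
  cnt <- matrix(0, M, M)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
      cnt[img[r, c], img[r2, c2]] <- cnt[img[r, c], img[r2, c2]] + 1
      if (symmetric)
        cnt[img[r2, c2], img[r, c]] <- cnt[img[r2, c2], img[r, c]] + 1
    }
  }
  cnt / sum(cnt)
}

# all spanning trees of the complete graph on `nodes` (for exhaustive
# Chow-Liu comparison on small node sets)
all_spanning_trees <- function(nodes) {
  p <- length(nodes)
  pairs <- t(utils::combn(nodes, 2))
  combs <- utils::combn(nrow(pairs), p - 1L)
  trees <- list()
  for (ci in seq_len(ncol(combs))) {
    sel <- pairs[combs[, ci], , drop = FALSE]
    # spanning check by union-find
    par <- stats::setNames(nodes, nodes)
    find <- function(x) { while (par[[x]] != x) x <- par[[x]]; x }
    ok <- TRUE
    for (e in seq_len(nrow(sel))) {
      ra <- find(sel[e, 1L]); rb <- find(sel[e, 2L])
      if (ra == rb) { ok <- FALSE; break }
      par[[ra]] <- rb
    }
    if (ok) trees[[length(trees) + 1L]] <- sel
  }
  trees
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
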