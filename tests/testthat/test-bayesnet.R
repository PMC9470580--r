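test_that("entropy matches closed forms and rejects bad input", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("mutual information matches the literal double-loop estimator", {
  # product table: independence
  x <- rep(1:2, each = 50); y <- rep(1:2, times = 50)
  expect_equal(mutual_information(x, y), 0, tolerance = 1e-12)
  # perfect copy, uniform 2 states
  z <- rep(1:2, 50)
  expect_equal(mutual_information(z, z), 1)
  # literal double loop on joint counts [[4,1],[1,4]]
  x2 <- c(rep(1, 5), rep(2, 5)); y2 <- c(rep(1, 4), 2, 1, rep(2, 4))
  p <- matrix(c(4, 1, 1, 4), 2, 2) / 10
  mi_oracle <- 0
  for (i in 1:2) for (j in 1:2)
    mi_oracle <- mi_oracle +
      p[i, j] * log2(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
  expect_equal(mutual_information(x2, y2), mi_oracle, tolerance = 1e-12)
  # identity MI = H(X) - H(X|Y)
  set.seed(31)
  a <- sample.int(3, 200, replace = TRUE)
  b <- ifelse(runif(200) < 0.7, a, sample.int(3, 200, replace = TRUE))
  pj <- table(a, b) / 200
  hx <- shannon_entropy(rowSums(pj))
  hxy <- sum(colSums(pj) * apply(pj, 2, function(col)
    shannon_entropy(col / sum(col))))
  expect_equal(mutual_information(a, b), hx - hxy, tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI is symmetric and bounded by the marginal entropies", {
  set.seed(12)
  for (rep in 1:10) {
    x <- sample.int(4, 300, replace = TRUE)
    y <- ifelse(runif(300) < 0.5, x, sample.int(4, 300, replace = TRUE))
    mi <- mutual_information(x, y)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    hx <- shannon_entropy(table(x) / 300)
    hy <- shannon_entropy(table(y) / 300)
    expect_lte(mi, min(hx, hy) + 1e-9)
    expect_gte(mi, 0)
  }
})

test_that("conditional MI separates chains from direct dependence", {
  set.seed(19)
  x <- sample.int(2, 400, replace = TRUE)
  y <- sample.int(2, 400, replace = TRUE)
  z <- sample.int(2, 400, replace = TRUE)
  # exact independence by construction of a balanced design
  g <- expand.grid(x = 1:2, y = 1:2, z = 1:2)
  g <- g[rep(1:8, each = 50), ]
  expect_equal(conditional_mutual_information(g$x, g$y, g$z), 0,
               tolerance = 1e-9)
  # constant z reduces to plain MI
  expect_equal(conditional_mutual_information(x, y, rep(1, 400)),
               mutual_information(x, y))
  # deterministic chain x -> z -> y: CMI(x, y | z) = 0, MI(x, y) > 0
  zc <- x; yc <- zc
  expect_equal(conditional_mutual_information(x, yc, zc), 0, tolerance = 1e-9)
  expect_gt(mutual_information(x, yc), 0.9)
})

test_that("Gaussian entropy and MI follow the determinant formulas", {
  expect_equal(gaussian_entropy(matrix(1)), 0.5 * log(2 * pi * exp(1)))
  expect_equal(gaussian_entropy(diag(2)), log(2 * pi * exp(1)))
  C <- matrix(c(1, 0.9, 0.9, 1), 2)
  # consistency: H(X) + H(Y) - H(X,Y) = MI
  mi <- gaussian_entropy(matrix(1)) * 2 - gaussian_entropy(C)
  expect_equal(gaussian_mi(C, matrix(1), matrix(1)), mi, tolerance = 1e-12)
  expect_equal(gaussian_mi(C, matrix(1), matrix(1)), -0.5 * log(1 - 0.81),
               tolerance = 1e-12)
  expect_equal(gaussian_mi(diag(2), matrix(1), matrix(1)), 0)
  near <- matrix(c(1, 1 - 1e-14, 1 - 1e-14, 1), 2)
  expect_error(gaussian_mi(near, matrix(1), matrix(1)), "singular")
  expect_error(gaussian_entropy(matrix(c(1, 2, 2, 1), 2)), "positive-definite")
})

test_that("Chow-Liu recovers a strong chain and beats all other trees", {
  d <- sample_tree(data.frame(a = c("A", "B"), b = c("B", "C")),
                   n = 5000, strength = 0.85, n_states = 3, seed = 41)
  net <- chow_liu(d, root = "A")
  got <- sort(edge_key(net$arcs$parent, net$arcs$child))
  expect_equal(got, c("A~B", "B~C"))
  # exhaustive: the selected tree has maximal total MI of all 3 trees
  w <- function(a, b) mutual_information(d[[a]], d[[b]])
  weights <- c("A~B,B~C" = w("A", "B") + w("B", "C"),
               "A~B,A~C" = w("A", "B") + w("A", "C"),
               "A~C,B~C" = w("A", "C") + w("B", "C"))
  expect_equal(sum(vapply(seq_len(nrow(net$arcs)), function(e)
    w(net$arcs$parent[e], net$arcs$child[e]), numeric(1))),
    max(weights), tolerance = 1e-12)
})

test_that("two nodes give the single root-to-other arc", {
  d <- data.frame(p = c(rep(1, 20), rep(2, 20), 1, 2),
                  q = c(rep(1, 20), rep(2, 20), 2, 1))
  net <- chow_liu(d, root = "q")
  expect_equal(net$arcs$parent, "q")
  expect_equal(net$arcs$child, "p")
})

test_that("independent nodes have near-zero pairwise MI", {
  set.seed(23)
  d <- as.data.frame(replicate(4, sample.int(3, 10000, replace = TRUE)))
  net <- chow_liu(d)
  off <- net$mi[upper.tri(net$mi)]
  expect_true(all(off < 0.01))
})

test_that("Chow-Liu weight dominates random spanning trees", {
  d <- sample_tree(data.frame(a = c("A", "B", "B", "D"),
                              b = c("B", "C", "D", "E")),
                   n = 2000, strength = 0.6, n_states = 3, seed = 77)
  net <- chow_liu(d, root = "A")
  w <- function(a, b) net$mi[a, b]
  tree_weight <- sum(vapply(seq_len(nrow(net$arcs)), function(e)
    w(net$arcs$parent[e], net$arcs$child[e]), numeric(1)))
  nodes <- net$nodes
  set.seed(99)
  for (rep in 1:100) {
    # random spanning tree: random attachment to already-connected set
    perm <- sample(nodes)
    wt <- 0
    for (i in 2:length(perm))
      wt <- wt + w(perm[i], perm[sample.int(i - 1, 1)])
    expect_lte(wt, tree_weight + 1e-12)
  }
})

test_that("CPT fitting applies Dirichlet smoothing as specified", {
  d <- data.frame(r = c(1, 1, 1, 2), ch = c(1, 1, 2, 2))
  net <- chow_liu(d, root = "r", prior_count = 0)
  expect_equal(unname(net$cpts$r), c(0.75, 0.25))
  # unseen parent configuration under prior 1 falls back to uniform
  d2 <- data.frame(r = c(1, 1, 2, 2), ch = c(1, 1, 2, 2))
  net2 <- chow_liu(d2, root = "r")
  net2$states$r <- c("1", "2", "3")   # extend with a never-seen parent state
  net2 <- fit_cpts(net2, d2, prior_count = 1)
  expect_equal(unname(net2$cpts$ch["3", ]), c(0.5, 0.5))
})

test_that("fitted root marginal approaches the sampling distribution", {
  d <- sample_tree(data.frame(a = "A", b = "B"), n = 4000, strength = 0.7,
                   n_states = 4, seed = 5)
  net <- chow_liu(d, root = "A")
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(net$cpts$A - 0.25) <= 3 * se + 2 / 4000))
})

test_that("MDL prefers the arc exactly when the dependence warrants it", {
  d <- sample_tree(data.frame(a = "A", b = "B"), n = 1000, strength = 0.9,
                   n_states = 2, seed = 55)
  tree <- chow_liu(d, root = "A")
  empty <- tree
  empty$arcs <- empty$arcs[0, ]
  empty <- fit_cpts(empty, d)
  expect_lt(mdl_score(tree, d)$total_bits, mdl_score(empty, d)$total_bits)

  set.seed(66)
  dind <- data.frame(A = sample.int(2, 1000, replace = TRUE),
                     B = sample.int(2, 1000, replace = TRUE))
  tree2 <- chow_liu(dind, root = "A")
  if (nrow(tree2$arcs) > 0) {
    empty2 <- tree2
    empty2$arcs <- empty2$arcs[0, ]
    empty2 <- fit_cpts(empty2, dind)
    expect_lt(mdl_score(empty2, dind)$total_bits,
              mdl_score(tree2, dind)$total_bits)
  }
  # hand arithmetic: single free parameter, uniform 2-state data, n = 4
  d4 <- data.frame(A = c(1, 2, 1, 2), B = c(1, 1, 2, 2))
  net4 <- suppressWarnings(chow_liu(d4, root = "A", prior_count = 0))
  net4$arcs <- net4$arcs[0, ]
  net4 <- fit_cpts(net4, d4, prior_count = 0)
  sc <- mdl_score(net4, d4)
  expect_equal(sc$structure_bits, 0.5 * log2(4) * 2)  # one free param per node
  expect_equal(sc$data_bits, 8)                       # 2 bits per uniform row
  expect_equal(sc$total_bits, sc$data_bits + sc$structure_bits)
})

test_that("exact inference reproduces the enumeration oracle", {
  set.seed(101)
  for (rep in 1:12) {
    net <- random_tree_net(sample(2:6, 1))
    # random evidence on a random subset
    nev <- sample(0:(length(net$nodes) - 1L), 1)
    evn <- sample(net$nodes, nev)
    ev <- stats::setNames(vapply(evn, function(v)
      sample.int(length(net$states[[v]]), 1), integer(1)), evn)
    expect_equal(evidence_probability(net, ev), enum_evidence_prob(net, ev),
                 tolerance = 1e-12)
    q <- sample(setdiff(net$nodes, evn), 1)
    expect_equal(posterior(net, ev, q), enum_posterior(net, ev, q),
                 tolerance = 1e-10)
  }
})

test_that("inference handles the textbook special cases", {
  net <- random_tree_net(5)
  expect_equal(evidence_probability(net, NULL), 1, tolerance = 1e-12)
  # full assignment equals the product of CPT entries along the factorization
  full <- vapply(net$nodes, function(v)
    sample.int(length(net$states[[v]]), 1), integer(1))
  expect_equal(evidence_probability(net, full),
               enum_row_prob(net, as.list(full)), tolerance = 1e-14)
  # empty evidence posterior = marginal; 2-node net: evidence on the
  # neighbor returns the CPT row
  d <- data.frame(a = c(1, 1, 1, 2, 2, 2, 1, 2), b = c(1, 1, 2, 2, 2, 1, 1, 2))
  net2 <- chow_liu(d, root = "a", prior_count = 0)
  expect_equal(posterior(net2, c(a = 1), "b"),
               net2$cpts$b["1", ], tolerance = 1e-12)
  bayes_inv <- net2$cpts$a * net2$cpts$b[, "2"]
  expect_equal(posterior(net2, c(b = 2), "a"),
               bayes_inv / sum(bayes_inv), tolerance = 1e-12)
})

test_that("contradictory evidence is reported by name", {
  d <- data.frame(a = c(1, 1, 2, 2), b = c(1, 1, 2, 2))
  net <- chow_liu(d, root = "a", prior_count = 0)
  expect_error(posterior(net, c(a = 1, b = 2), "b"), "carry evidence")
  expect_error(posterior(net, c(b = 2), "a"), NA)
  # force a zero: unsmoothed CPT has P(b=2 | a=1) = 0
  net$cpts$a <- stats::setNames(c(1, 0), net$states$a)
  expect_error(posterior(net, c(a = 2), "b"), "zero probability.*a=2")
})

test_that("structure recovery holds on an 8-node tree at n = 5000", {
  edges <- data.frame(a = c("n1", "n2", "n2", "n4", "n4", "n6", "n1"),
                      b = c("n2", "n3", "n4", "n5", "n6", "n7", "n8"))
  truth <- sort(edge_key(edges$a, edges$b))
  hits <- 0L
  for (rep in 1:100) {
    d <- sample_tree(edges, n = 5000, strength = 0.55, n_states = 3,
                     seed = 1000 + rep)
    net <- chow_liu(d, root = "n1")
    got <- sort(edge_key(net$arcs$parent, net$arcs$child))
    if (identical(got, truth)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("simulation and refitting round-trip the model", {
  net <- random_tree_net(4)
  d <- simulate(net, nsim = 4000, seed = 9)
  expect_equal(names(d), net$nodes)
  refit <- fit_cpts(net, d, prior_count = 1)
  # marginals of a large simulation track the model's marginals
  for (v in net$nodes) {
    expect_lt(max(abs(posterior(refit, NULL, v) - posterior(net, NULL, v))),
              0.05)
  }
})

test_that("prediction returns exact posterior argmax with low-index ties", {
  d <- sample_tree(data.frame(a = "A", b = "B"), n = 500, strength = 0.8,
                   n_states = 3, seed = 3)
  net <- chow_liu(d, root = "A")
  pr <- predict(net, d, target = "A", type = "prob")
  st <- predict(net, d, target = "A", type = "state")
  expect_equal(dim(pr), c(500L, 3L))
  expect_equal(unname(st), unname(apply(pr, 1, which.max)))
  expect_equal(rowSums(pr), rep(1, 500), tolerance = 1e-9)
})
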