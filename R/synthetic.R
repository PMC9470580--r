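#' Specification of one synthetic texture class
#'
#' @param label Class label.
#' @param n Number of images.
#' @param size Image side length in pixels (`>= 16`).
#' @param blur_sigma Gaussian smoothing radius in pixels (0 = raw noise;
#'   larger = smoother texture, hence higher GLCM energy/homogeneity and
#'   lower entropy).
#' @param mean,sd Intensity mean and standard deviation of the underlying
#'   noise field (8-bit scale).
#' @return List of class `"texture_spec"`.
#' @export
texture_spec <- function(label, n, size = 64L, blur_sigma = 0,
                         mean = 128, sd = 40) {
  if (size < 16L) stop("`size` must be at least 16")
  if (n < 1L) stop("`n` must be at least 1")
  if (sd <= 0) stop("`sd` must be positive")
  structure(list(label = label, n = as.integer(n), size = as.integer(size),
                 blur_sigma = blur_sigma, mean = mean, sd = sd),
            class = "texture_spec")
}

# banded row-normalized Gaussian smoothing operator (truncated at 3 sigma);
# rows near the border renormalize over the in-image support
blur_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  K <- outer(seq_len(n), seq_len(n), function(i, j)
    ifelse(abs(i - j) <= r, stats::dnorm(j - i, sd = sigma), 0))
  K / rowSums(K)
}

#' Generate synthetic two-class texture images
#'
#' Each image is a white-noise field, smoothed by a separable Gaussian
#' filter at the class's `blur_sigma`, then affinely rescaled to the full
#' 8-bit range. Smoother classes yield higher GLCM energy and homogeneity
#' and lower entropy, giving a provable ground-truth ordering for
#' pipeline validation. Fully reproducible under `seed`. An image whose
#' post-blur dynamic range collapses (blur radius on the order of the
#' image size) triggers a degenerate-texture warning.
#'
#' @param specs List of [texture_spec()]s covering two classes.
#' @param seed RNG seed.
#' @return List with `images` (list of integer matrices 0..255) and
#'   `labels` (character vector).
#' @export
generate_textures <- function(specs, seed = 1L) {
  if (inherits(specs, "texture_spec")) specs <- list(specs)
  set.seed(seed)
  images <- list(); labels <- character(0)
  for (sp in specs) {
    K <- blur_operator(sp$size, sp$blur_sigma)
    for (m in seq_len(sp$n)) {
      noise <- matrix(stats::rnorm(sp$size^2, sp$mean, sp$sd),
                      sp$size, sp$size)
      sm <- K %*% noise %*% t(K)
      rng <- range(sm)
      if (diff(rng) < 1) # below one 8-bit quantum before rescaling
        warning("degenerate near-constant texture generated (class '",
                sp$label, "'); blur radius too large for image size")
      img <- if (diff(rng) < 1e-12) matrix(128L, sp$size, sp$size)
             else matrix(as.integer(round((sm - rng[1L]) / diff(rng) * 255)),
                         sp$size, sp$size)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, sp$label)
    }
  }
  names(images) <- sprintf("%s_%03d", labels, stats::ave(seq_along(labels),
                                                         labels, FUN = seq_along))
  list(images = images, labels = labels)
}

#' Sample discrete data from a known tree-structured distribution
#'
#' Ancestral sampling over an undirected tree: the root is drawn from
#' `root_marginal` (default uniform); every child copies its parent's
#' state with probability `strength` and otherwise is uniform over the
#' remaining states. `strength = 1` makes all columns identical;
#' `strength = 1/k` makes children independent of their parents. All
#' nodes share `n_states` states so the copy mechanism is well defined.
#'
#' @param edges Two-column matrix or `data.frame` of undirected tree
#'   edges (node names).
#' @param n Number of rows.
#' @param strength Copy probability in `(0, 1]`, scalar or one per edge.
#' @param n_states States per node (default 4).
#' @param root Root node (default: first node of the first edge).
#' @param root_marginal Root state distribution (default uniform).
#' @param seed RNG seed.
#' @return `data.frame` of integer states in `1..n_states`, with a
#'   `tree_edges` attribute recording the ground truth.
#' @export
sample_tree <- function(edges, n, strength = 0.9, n_states = 4L,
                        root = NULL, root_marginal = NULL, seed = 1L) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("a", "b")
  nodes <- unique(c(edges$a, edges$b))
  if (nrow(edges) != length(nodes) - 1L)
    stop("`edges` must form a tree (n - 1 edges over n nodes)")
  if (length(strength) == 1L) strength <- rep(strength, nrow(edges))
  if (any(strength <= 0 | strength > 1)) stop("`strength` must lie in (0, 1]")
  root <- root %||% edges$a[1L]
  root_marginal <- root_marginal %||% rep(1 / n_states, n_states)
  set.seed(seed)

  out <- stats::setNames(vector("list", length(nodes)), nodes)
  out[[root]] <- sample.int(n_states, n, replace = TRUE, prob = root_marginal)
  todo <- edges; todo$strength <- strength
  done <- root
  while (nrow(todo)) {
    ready <- todo$a %in% done | todo$b %in% done
    if (!any(ready)) stop("`edges` are not connected")
    e <- which(ready)[1L]
    pa <- if (todo$a[e] %in% done) todo$a[e] else todo$b[e]
    ch <- setdiff(c(todo$a[e], todo$b[e]), pa)
    s <- todo$strength[e]
    copy <- stats::runif(n) < s
    other <- sample.int(n_states - 1L, n, replace = TRUE)
    child <- ifelse(copy, out[[pa]],
                    ifelse(other < out[[pa]], other, other + 1L))
    out[[ch]] <- as.integer(child)
    done <- c(done, ch)
    todo <- todo[-e, , drop = FALSE]
  }
  structure(as.data.frame(out[nodes]), tree_edges = edges[, c("a", "b")])
}

#' Generate a correlated two-class feature table
#'
#' Draws Gaussian features with a requested correlation structure,
#' duplicates one column pair exactly (emulating two algebraically
#' identical feature variants), and shifts chosen feature means between
#' the two classes. Without an explicit `sigma`, features are generated
#' along a dependency chain with correlation `rho` between consecutive
#' features, which is guaranteed positive-definite.
#'
#' @param n Total rows (split evenly over two classes).
#' @param feature_names Feature columns to generate (default: the 13
#'   texture feature names).
#' @param sigma Optional explicit correlation matrix (features x
#'   features, PSD; checked) for the non-duplicated features.
#' @param rho Chain correlation used when `sigma` is `NULL` (default 0.6).
#' @param duplicate Length-2 character: `duplicate[2]` is an exact copy
#'   of `duplicate[1]` (default the two correlation variants). `NULL` to
#'   disable.
#' @param class_shift Named numeric: between-class mean shift (in sd
#'   units) per feature (default: shift on `energy` and `entropy`).
#' @param class_labels Two class labels.
#' @param seed RNG seed.
#' @return Feature table `data.frame` with the features plus `class`.
#' @export
generate_feature_table <- function(n = 200L,
                                   feature_names = glcm_feature_names(),
                                   sigma = NULL, rho = 0.6,
                                   duplicate = c("correlation1", "correlation2"),
                                   class_shift = c(energy = 2, entropy = -1.5),
                                   class_labels = c("class_a", "class_b"),
                                   seed = 1L) {
  set.seed(seed)
  base <- if (is.null(duplicate)) feature_names else
    setdiff(feature_names, duplicate[2L])
  p <- length(base)
  if (is.null(sigma)) {
    sigma <- outer(seq_len(p), seq_len(p), function(i, j) rho^abs(i - j))
    dimnames(sigma) <- list(base, base)
  } else {
    sigma <- as.matrix(sigma)
    if (!all(base %in% rownames(sigma)))
      stop("`sigma` must cover all non-duplicated features")
    sigma <- sigma[base, base]
    ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("`sigma` is not positive semi-definite")
  }
  Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  colnames(Z) <- base
  cls <- rep(class_labels, length.out = 2L)
  classes <- rep(cls, c(ceiling(n / 2), floor(n / 2)))
  for (f in names(class_shift)) {
    if (!f %in% base) next
    Z[, f] <- Z[, f] + class_shift[[f]] * (classes == cls[2L])
  }
  out <- as.data.frame(Z)
  if (!is.null(duplicate)) out[[duplicate[2L]]] <- out[[duplicate[1L]]]
  out <- out[intersect(feature_names, names(out))]
  out$class <- classes
  out
}
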