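#' Shannon entropy of a discrete distribution
#'
#' `H(p) = -sum p log2 p` over positive entries (0 log 0 = 0), in bits.
#'
#' @param p Probability vector (non-negative, summing to 1 within 1e-6).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("`p` must sum to 1")
  pos <- p > 0
  -sum(p[pos] * log2(p[pos]))
}

#' Mutual information of two discrete samples
#'
#' Estimates `MI(X, Y) = sum p(x, y) log2 p(x, y) / (p(x) p(y))` from the
#' joint frequency table of two equal-length state columns, optionally
#' smoothed by adding `pseudo_count` to every cell. Equivalently
#' `H(X) - H(X|Y)`. Reported in bits.
#'
#' @param x,y Discrete samples (factors, integers or characters) of equal
#'   length.
#' @param pseudo_count Added to every joint cell before normalization
#'   (default 0).
#' @return Mutual information in bits (`>= 0` up to smoothing).
#' @export
mutual_information <- function(x, y, pseudo_count = 0) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) == 0L) stop("empty samples")
  tab <- table(x, y) + pseudo_count
  mi_from_joint(tab / sum(tab))
}

mi_from_joint <- function(p) {
  px <- rowSums(p); py <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log2(p[idx] / (px[idx[, 1L]] * py[idx[, 2L]])))
}

#' Conditional mutual information of two samples given a third
#'
#' `CMI(X, Y | Z) = sum_z p(z) sum_{x,y} p(x,y|z) log2 p(x,y|z) /
#' (p(x|z) p(y|z))`, estimated from frequencies, in bits. Conditioning on
#' a constant (or empty) `z` reduces to [mutual_information()].
#'
#' @param x,y,z Equal-length discrete samples; `z` may be `NULL`.
#' @param pseudo_count Added to every joint (x, y) cell within each z slice.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(x, y, z = NULL, pseudo_count = 0) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (is.null(z) || length(unique(z)) <= 1L)
    return(mutual_information(x, y, pseudo_count))
  if (length(z) != length(x)) stop("`z` must match the length of `x`")
  n <- length(x)
  cmi <- 0
  for (zv in unique(z)) {
    sel <- z == zv
    cmi <- cmi + sum(sel) / n * mutual_information(x[sel], y[sel], pseudo_count)
  }
  cmi
}

#' Differential entropy of a multivariate Gaussian
#'
#' `H = (n/2) ln(2 pi e) + (1/2) ln |C|` for covariance matrix `C`,
#' in nats.
#'
#' @param C Symmetric positive-definite covariance matrix.
#' @return Entropy in nats.
#' @export
gaussian_entropy <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || any(abs(C - t(C)) > 1e-8))
    stop("`C` must be a symmetric matrix")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("`C` must be positive-definite")
  n <- nrow(C)
  n / 2 * log(2 * pi * exp(1)) + 0.5 * sum(log(ev))
}

#' Gaussian mutual information from covariance blocks
#'
#' `MI(X, Y) = (1/2) ln(|C_x| |C_y| / |C_joint|)`, in nats.
#'
#' @param C_joint Joint covariance of `(X, Y)`.
#' @param C_x,C_y Marginal covariance blocks.
#' @return Mutual information in nats (`>= 0`).
#' @export
gaussian_mi <- function(C_joint, C_x, C_y) {
  dj <- det(as.matrix(C_joint))
  if (dj <= 1e-12) stop("joint covariance is (near-)singular: MI diverges")
  dx <- det(as.matrix(C_x)); dy <- det(as.matrix(C_y))
  if (dx <= 0 || dy <= 0) stop("marginal covariance blocks must be positive-definite")
  0.5 * log(dx * dy / dj)
}
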