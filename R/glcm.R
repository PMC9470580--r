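#' Quantize a grayscale image to a fixed number of gray levels
#'
#' Linearly bins the full representable intensity range of the input
#' (`[0, 2^bit_depth - 1]`) into `n_levels` equal-width bins, mapping each
#' pixel to a level in `1..n_levels`. The mapping is order-preserving and
#' independent of the actual intensities present, so two images quantized
#' with the same settings are on the same scale.
#'
#' @param image Integer matrix of pixel intensities (at least 2x2).
#' @param n_levels Number of output gray levels, `>= 2`.
#' @param bit_depth Bit depth of the input representation (default 8).
#' @return Integer matrix with values in `1..n_levels`; attribute
#'   `n_levels` records the quantization.
#' @examples
#' img <- matrix(0:255, 16, 16)
#' table(quantize_gray(img, 8))
#' @export
quantize_gray <- function(image, n_levels = 8L, bit_depth = 8L) {
  image <- as.matrix(image)
  if (!is.numeric(image) || nrow(image) < 2L || ncol(image) < 2L)
    stop("`image` must be a numeric matrix of at least 2x2 pixels")
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2L)
    stop("`n_levels` must be a single integer >= 2")
  n_levels <- as.integer(n_levels)
  max_val <- 2^bit_depth
  if (any(image < 0) || any(image >= max_val))
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  q <- pmin(floor(image * (n_levels / max_val)) + 1L, n_levels)
  q <- matrix(as.integer(q), nrow(image), ncol(image))
  attr(q, "n_levels") <- n_levels
  q
}

# Row/column displacement for the four canonical GLCM directions, with the
# image origin at the top-left (rows increase downward).
offset_displacement <- function(distance, angle) {
  if (!angle %in% c(0, 45, 90, 135))
    stop("`angle` must be one of 0, 45, 90, 135 degrees")
  if (!is.numeric(distance) || length(distance) != 1L || distance < 1)
    stop("`distance` must be a positive integer")
  d <- as.integer(distance)
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d))
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts ordered (reference, neighbor) gray-level pairs separated by the
#' displacement `(distance, angle)` and normalizes to pair probabilities
#' P(i, j | d, theta). Boundary pixels whose neighbor would fall outside
#' the image are skipped (no padding). In symmetric mode each pair is also
#' counted in the opposite direction, so the matrix equals its transpose.
#'
#' @param image Quantized integer matrix with levels `1..n_levels`
#'   (see [quantize_gray()]).
#' @param distance Pixel distance `d >= 1`.
#' @param angle Direction in degrees: 0, 45, 90 or 135.
#' @param n_levels Number of gray levels M; defaults to the `n_levels`
#'   attribute of `image`, else `max(image)`.
#' @param symmetric Accumulate pairs in both directions (default `TRUE`).
#' @return An `M x M` matrix of class `"glcm"` summing to 1, with
#'   attributes `distance`, `angle`, `symmetric`.
#' @export
cooccurrence <- function(image, distance = 1L, angle = 0,
                         n_levels = NULL, symmetric = TRUE) {
  image <- as.matrix(image)
  if (is.null(n_levels))
    n_levels <- attr(image, "n_levels") %||% max(image)
  n_levels <- as.integer(n_levels)
  if (any(image < 1L) || any(image > n_levels))
    stop("`image` must be quantized to levels 1..n_levels")
  dis <- offset_displacement(distance, angle)
  nr <- nrow(image); nc <- ncol(image)
  rows <- seq_len(nr); cols <- seq_len(nc)
  rr <- rows[rows + dis[1L] >= 1L & rows + dis[1L] <= nr]
  cc <- cols[cols + dis[2L] >= 1L & cols + dis[2L] <= nc]
  if (length(rr) == 0L || length(cc) == 0L)
    stop("offset (d=", distance, ", angle=", angle,
         ") yields no pixel pairs inside the image")
  ref <- image[rr, cc, drop = FALSE]
  nbr <- image[rr + dis[1L], cc + dis[2L], drop = FALSE]
  counts <- tabulate(ref + n_levels * (nbr - 1L), nbins = n_levels^2)
  P <- matrix(counts, n_levels, n_levels)
  if (symmetric) P <- P + t(P)
  P <- P / sum(P)
  structure(P, class = c("glcm", "matrix"),
            distance = as.integer(distance), angle = angle,
            symmetric = isTRUE(symmetric))
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d levels, d=%d, angle=%d%s\n", nrow(x),
              attr(x, "distance"), attr(x, "angle"),
              if (isTRUE(attr(x, "symmetric"))) ", symmetric" else ""))
  print(unclass(x), ...)
  invisible(x)
}

#' Haralick-family texture features of a co-occurrence matrix
#'
#' Computes the 13 scalar texture statistics used throughout the package
#' from a single normalized co-occurrence matrix: autocorrelation, contrast,
#' two algebraically equivalent correlation forms, cluster prominence,
#' cluster shade, dissimilarity, energy (angular second moment), entropy
#' (natural log), two homogeneity forms, maximum probability and sum
#' variance. Gray-level indices are 1-based.
#'
#' If the marginal variances are degenerate (a single gray level carries
#' all mass) the two correlation features are set to 0 and a warning is
#' issued.
#'
#' @param P Normalized co-occurrence matrix (entries `>= 0`, summing to 1).
#' @return Named numeric vector of the 13 features.
#' @examples
#' P <- matrix(c(0, .5, .5, 0), 2, 2)
#' haralick_features(P)
#' @export
haralick_features <- function(P) {
  P <- unclass(as.matrix(P))
  if (nrow(P) != ncol(P)) stop("`P` must be square")
  if (any(P < -1e-12)) stop("`P` must be non-negative")
  if (abs(sum(P) - 1) > 1e-9) stop("`P` must be normalized to sum 1")
  M <- nrow(P)
  i <- matrix(seq_len(M), M, M)        # row index (reference level)
  j <- t(i)                            # column index (neighbor level)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(M) * px); mu_y <- sum(seq_len(M) * py)
  var_x <- sum((seq_len(M) - mu_x)^2 * px)
  var_y <- sum((seq_len(M) - mu_y)^2 * py)
  sd_x <- sqrt(var_x); sd_y <- sqrt(var_y)

  # p_{x+y}(k), k = 2..2M
  k <- 2:(2 * M)
  pxy_sum <- vapply(k, function(kk) sum(P[i + j == kk]), numeric(1))
  sum_avg <- sum(k * pxy_sum)

  pos <- P > 0
  feats <- c(
    autocorrelation    = sum(i * j * P),
    contrast           = sum((i - j)^2 * P),
    correlation1       = NA_real_,
    correlation2       = NA_real_,
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * P),
    cluster_shade      = sum((i + j - mu_x - mu_y)^3 * P),
    dissimilarity      = sum(abs(i - j) * P),
    energy             = sum(P^2),
    entropy            = -sum(P[pos] * log(P[pos])),
    homogeneity1       = sum(P / (1 + abs(i - j))),
    homogeneity2       = sum(P / (1 + (i - j)^2)),
    max_probability    = max(P),
    sum_variance       = sum((k - sum_avg)^2 * pxy_sum)
  )
  if (sd_x * sd_y <= 0) {
    warning("degenerate texture: zero marginal variance, correlation features set to 0")
    feats[["correlation1"]] <- 0
    feats[["correlation2"]] <- 0
  } else {
    feats[["correlation1"]] <- sum((i - mu_x) * (j - mu_y) * P) / (sd_x * sd_y)
    feats[["correlation2"]] <- (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)
  }
  feats[sort(names(feats))]
}

#' Names of the implemented texture features
#' @return Character vector of the 13 feature names in canonical order.
#' @export
glcm_feature_names <- function() {
  sort(c("autocorrelation", "contrast", "correlation1", "correlation2",
         "cluster_prominence", "cluster_shade", "dissimilarity", "energy",
         "entropy", "homogeneity1", "homogeneity2", "max_probability",
         "sum_variance"))
}

#' Extract GLCM texture features from a set of labeled images
#'
#' For each image: quantize to `n_levels`, build one co-occurrence matrix
#' per `(distance, angle)` combination, compute the 13 texture features
#' for each matrix, and aggregate across offsets (default: arithmetic
#' mean, the standard rotation-robust choice). Returns one row per image.
#'
#' @param images Either a list of integer pixel matrices (0..255 for 8-bit),
#'   or a directory path containing PNG/TIFF images.
#' @param labels Class label per image (length = number of images), or,
#'   when `images` is a directory, the path of a two-column CSV
#'   (`filename,class`).
#' @param n_levels Gray levels for quantization (default 8).
#' @param distances Integer vector of pixel distances (default `1:4`).
#' @param angles Directions in degrees (default `c(0, 45, 90, 135)`).
#' @param symmetric Symmetric co-occurrence accumulation (default `TRUE`).
#' @param aggregate `"mean"` to average features over offsets, or `"none"`
#'   to return one row per image x offset (columns `distance`, `angle`
#'   appended).
#' @param bit_depth Image bit depth (default 8).
#' @return A `data.frame` with the 13 feature columns plus a final
#'   `class` column (and an `image` id column).
#' @export
extract_features <- function(images, labels, n_levels = 8L,
                             distances = 1:4, angles = c(0, 45, 90, 135),
                             symmetric = TRUE, aggregate = c("mean", "none"),
                             bit_depth = 8L) {
  aggregate <- match.arg(aggregate)
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    lab <- utils::read.csv(labels, stringsAsFactors = FALSE)
    if (ncol(lab) < 2L) stop("label CSV must have two columns: filename, class")
    paths <- file.path(images, lab[[1L]])
    imgs <- vector("list", length(paths))
    keep <- rep(TRUE, length(paths))
    for (m in seq_along(paths)) {
      im <- tryCatch(read_gray_image(paths[m]), error = function(e) {
        warning("skipping unreadable image '", paths[m], "': ",
                conditionMessage(e))
        NULL
      })
      if (is.null(im)) keep[m] <- FALSE else imgs[[m]] <- im
    }
    images <- imgs[keep]
    labels <- lab[[2L]][keep]
    names(images) <- lab[[1L]][keep]
  }
  if (!is.list(images) || length(images) == 0L)
    stop("no readable images supplied")
  if (length(labels) != length(images))
    stop("`labels` must match the number of images")
  if (length(distances) < 1L || length(angles) < 1L)
    stop("at least one offset (distance, angle) is required")

  offs <- expand.grid(distance = as.integer(distances), angle = angles,
                      KEEP.OUT.ATTRS = FALSE)
  ids <- names(images) %||% sprintf("image_%03d", seq_along(images))
  rows <- vector("list", length(images))
  for (m in seq_along(images)) {
    q <- quantize_gray(images[[m]], n_levels = n_levels, bit_depth = bit_depth)
    fmat <- t(vapply(seq_len(nrow(offs)), function(o) {
      P <- cooccurrence(q, distance = offs$distance[o], angle = offs$angle[o],
                        n_levels = n_levels, symmetric = symmetric)
      haralick_features(P)
    }, numeric(13L)))
    if (aggregate == "mean") {
      rows[[m]] <- data.frame(image = ids[m], t(colMeans(fmat)),
                              class = labels[m], stringsAsFactors = FALSE)
    } else {
      rows[[m]] <- data.frame(image = ids[m], offs, fmat,
                              class = labels[m], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a grayscale image from PNG or TIFF
#'
#' Color images are converted to gray by channel averaging; intensities are
#' rescaled to integer 0..255.
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return Integer matrix of 8-bit intensities.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "'"))
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3L])),
                                         drop = FALSE], c(1L, 2L), mean)
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Numeric feature columns of a feature table
#'
#' @param features Feature table (`data.frame` with a `class` column and
#'   optionally an `image` id column).
#' @return The `data.frame` restricted to the numeric feature columns.
#' @export
feature_columns <- function(features) {
  drop <- intersect(c("image", "class", "distance", "angle"), names(features))
  features[, setdiff(names(features), drop), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
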