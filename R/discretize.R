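#' Fit a discretization scheme for continuous features
#'
#' Computes ascending cut points per feature, either at empirical
#' quantiles (`"frequency"`, the default: cut k at the k/n_states
#' quantile, giving near-equal state occupancy) or equally spaced over
#' the observed range (`"width"`). Explicit cut points may be supplied
#' instead to mirror externally chosen state boundaries. Duplicate cut
#' points are collapsed (fewer states) with a warning; a constant feature
#' yields a single state and is flagged.
#'
#' State labels take the form `"<=c1", ..., ">c_{k-1}"`, closed on the
#' left state: a value exactly equal to a cut belongs to that cut's
#' `"<="` state.
#'
#' @param features Feature table (`data.frame`; non-numeric and
#'   `class`/`image` columns are ignored).
#' @param n_states Target number of states per feature (default 4).
#' @param method `"frequency"` (equal-frequency quantile cuts) or
#'   `"width"` (equal-width cuts).
#' @param cuts Optional named list `feature -> numeric vector of cuts`,
#'   overriding `method` for the named features.
#' @return Object of class `"discretization"`: named list with per-feature
#'   `cuts` and `labels`.
#' @examples
#' sch <- discretize_fit(data.frame(x = 1:8), n_states = 4)
#' sch$x$cuts   # 2, 4, 6
#' @export
discretize_fit <- function(features, n_states = 4L,
                           method = c("frequency", "width"), cuts = NULL) {
  method <- match.arg(method)
  if (!is.numeric(n_states) || n_states < 2L) stop("`n_states` must be >= 2")
  X <- feature_columns(features)
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  if (ncol(X) == 0L) stop("no numeric feature columns to discretize")
  if (nrow(X) < n_states) stop("need at least `n_states` rows to fit cuts")
  scheme <- lapply(names(X), function(f) {
    x <- X[[f]]
    cf <- if (!is.null(cuts) && f %in% names(cuts)) {
      sort(as.numeric(cuts[[f]]))
    } else if (diff(range(x)) == 0) {
      warning("feature '", f, "' is constant; single-state feature")
      numeric(0)
    } else if (method == "frequency") {
      q <- unname(stats::quantile(x, probs = seq_len(n_states - 1L) / n_states,
                                  type = 1))
      uq <- unique(q)
      if (length(uq) < length(q))
        warning("feature '", f, "' has duplicate quantiles; states collapsed to ",
                length(uq) + 1L)
      uq
    } else {
      rng <- range(x)
      seq(rng[1L], rng[2L], length.out = n_states + 1L)[-c(1L, n_states + 1L)]
    }
    list(cuts = cf, labels = state_labels(cf))
  })
  names(scheme) <- names(X)
  class(scheme) <- "discretization"
  scheme
}

state_labels <- function(cuts) {
  if (length(cuts) == 0L) return("all")
  fmt <- function(v) formatC(v, digits = 4, format = "g")
  c(paste0("<=", fmt(cuts)), paste0(">", fmt(cuts[length(cuts)])))
}

#' @export
print.discretization <- function(x, ...) {
  cat("Discretization scheme (", length(x), " features)\n", sep = "")
  for (f in names(x))
    cat(sprintf("  %-20s %s\n", f, paste(x[[f]]$labels, collapse = " | ")))
  invisible(x)
}

#' Apply a discretization scheme to continuous features
#'
#' Maps each value to the first state whose cut it does not exceed
#' (`v <= cut`), else the last state; values outside the training range
#' clamp to the end states, so the map is total and monotone. The result
#' also records, per feature and state, the conditional mean of the
#' underlying continuous values, used later for prior/posterior mean
#' reporting.
#'
#' @param features Feature table with the scheme's features present.
#' @param scheme A `"discretization"` from [discretize_fit()].
#' @return Object of class `"discrete_table"`: `data.frame` of integer
#'   state indices (1-based), with attributes `labels` (per-feature state
#'   labels), `cond_means` (per-feature per-state conditional means) and
#'   `continuous` (the input feature columns).
#' @export
discretize_apply <- function(features, scheme) {
  if (!inherits(scheme, "discretization")) stop("`scheme` must be a discretization")
  X <- feature_columns(features)
  missing_f <- setdiff(names(scheme), names(X))
  if (length(missing_f))
    stop("scheme covers features absent from the table: ",
         paste(missing_f, collapse = ", "))
  out <- lapply(names(scheme), function(f)
    discretize_value(X[[f]], scheme[[f]]$cuts))
  names(out) <- names(scheme)
  out <- as.data.frame(out)
  cond_means <- lapply(names(scheme), function(f) {
    k <- length(scheme[[f]]$labels)
    m <- vapply(seq_len(k), function(s) {
      v <- X[[f]][out[[f]] == s]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    names(m) <- scheme[[f]]$labels
    m
  })
  names(cond_means) <- names(scheme)
  structure(out, class = c("discrete_table", "data.frame"),
            labels = lapply(scheme, `[[`, "labels"),
            cond_means = cond_means,
            continuous = X[names(scheme)],
            scheme = scheme)
}

discretize_value <- function(v, cuts) {
  if (length(cuts) == 0L) return(rep(1L, length(v)))
  findInterval(v, cuts, left.open = TRUE) + 1L
}

#' @export
print.discrete_table <- function(x, ...) {
  cat(sprintf("Discrete table: %d rows x %d features\n", nrow(x), ncol(x)))
  labs <- attr(x, "labels")
  for (f in names(labs))
    cat(sprintf("  %-20s %s\n", f, paste(labs[[f]], collapse = " | ")))
  invisible(x)
}

#' State labels of a discrete table or network node
#' @param x A `discrete_table`.
#' @param node Feature name.
#' @return Character vector of state labels.
#' @export
node_states <- function(x, node) {
  labs <- attr(x, "labels")
  if (is.null(labs[[node]])) stop("unknown node '", node, "'")
  labs[[node]]
}
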