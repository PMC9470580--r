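#' Write / read a feature table as CSV
#'
#' Plain UTF-8 CSV with a header row, one image per row, `.` decimal
#' separator and the class label in the final column. Reading validates
#' the layout and fails on missing values, naming the offending row.
#'
#' @param features Feature table `data.frame` (numeric features +
#'   `class`, optional leading `image` column).
#' @param path Output/input file path.
#' @return `write_feature_csv`: the path, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  if (!"class" %in% names(features)) stop("feature table lacks a `class` column")
  ord <- c(intersect("image", names(features)),
           setdiff(names(features), c("image", "class")), "class")
  utils::write.csv(features[ord], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @return `read_feature_csv`: the feature table.
#' @export
read_feature_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"class" %in% names(out))
    stop("malformed feature CSV: no `class` column in header")
  num <- setdiff(names(out), c("image", "class"))
  for (f in num) if (!is.numeric(out[[f]]))
    stop("malformed feature CSV: non-numeric values in column '", f, "'")
  if (anyNA(out)) {
    bad <- which(!stats::complete.cases(out))
    stop("missing value(s) in row(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Serialize / restore a fitted tree network as JSON
#'
#' Stores nodes, state labels, arcs, CPT arrays, root and smoothing
#' count at full floating-point precision, so a write/read round trip
#' reproduces the CPTs exactly.
#'
#' @param net A fitted `tree_bn`.
#' @param path File path.
#' @return `write_network_json`: the path, invisibly;
#'   `read_network_json`: the `tree_bn`.
#' @export
write_network_json <- function(net, path) {
  payload <- list(
    nodes = net$nodes,
    states = net$states,
    arcs = net$arcs,
    root = net$root,
    n = net$n,
    prior_count = net$prior_count,
    cpts = lapply(net$cpts, function(ct)
      if (is.matrix(ct)) list(kind = "conditional", values = unclass(ct))
      else list(kind = "marginal", values = unname(ct)))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- lapply(x$states, as.character)
  cpts <- lapply(x$nodes, function(v) {
    ct <- x$cpts[[v]]
    if (ct$kind == "conditional") {
      m <- as.matrix(ct$values)
      pa <- x$arcs$parent[x$arcs$child == v]
      dimnames(m) <- list(states[[pa]], states[[v]])
      m
    } else stats::setNames(as.numeric(ct$values), states[[v]])
  })
  names(cpts) <- x$nodes
  structure(list(nodes = x$nodes, states = states,
                 arcs = as.data.frame(x$arcs, stringsAsFactors = FALSE),
                 root = x$root, cpts = cpts, mi = NULL,
                 n = x$n, prior_count = x$prior_count),
            class = "tree_bn")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror the arguments of [run_pipeline()]; unknown fields are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("images", "labels", "features", "out_dir", "n_levels",
             "distances", "angles", "symmetric", "n_bins", "n_states",
             "disc_method", "cuts", "prior_count", "target", "seed",
             "profile_steps", "best_draws", "run_segment_profile")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the full profiling pipeline
#'
#' Executes, in order: feature extraction (skipped when a precomputed
#' feature table is supplied), relative-entropy ranking, target
#' selection, discretization, Chow-Liu network learning with CPT
#' fitting, arc/node/target reports, tornado analysis, dynamic profiles
#' and optimization paths for every target state, target-performance
#' evaluation and (optionally) segment profiles. All stage outputs are
#' written as CSV/JSON under `out_dir` together with a manifest
#' recording the configuration, seeds and produced files.
#'
#' @param images List of pixel matrices or an image directory (ignored
#'   when `features` is given).
#' @param labels Class labels (or labels CSV path with an image
#'   directory).
#' @param features Optional precomputed feature table (`data.frame` or
#'   CSV path); skips the extraction stage.
#' @param out_dir Output directory (created if needed); `NULL` for no
#'   file output.
#' @param n_levels,distances,angles,symmetric GLCM settings
#'   (see [extract_features()]).
#' @param n_bins Ranking histogram bins.
#' @param n_states,disc_method,cuts Discretization settings.
#' @param prior_count CPT smoothing count.
#' @param target Optional target override (default: top-ranked feature).
#' @param seed Seed governing all randomness in the run.
#' @param profile_steps Maximum greedy profile steps.
#' @param best_draws BEST draws per segment test.
#' @param run_segment_profile Run the (MCMC-heavy) segment profiles
#'   (default `TRUE`).
#' @return List of class `"pipeline_result"` with all stage outputs and
#'   the manifest.
#' @export
run_pipeline <- function(images = NULL, labels = NULL, features = NULL,
                         out_dir = NULL, n_levels = 8L, distances = 1:4,
                         angles = c(0, 45, 90, 135), symmetric = TRUE,
                         n_bins = 10L, n_states = 4L,
                         disc_method = "frequency", cuts = NULL,
                         prior_count = 1, target = NULL, seed = 1L,
                         profile_steps = 3L, best_draws = 20000L,
                         run_segment_profile = TRUE) {
  stage <- "extract"
  result <- tryCatch({
    if (is.null(features)) {
      if (is.null(images)) stop("either `images` or `features` is required")
      features <- extract_features(images, labels, n_levels = n_levels,
                                   distances = distances, angles = angles,
                                   symmetric = symmetric)
      extracted <- TRUE
    } else {
      if (is.character(features)) features <- read_feature_csv(features)
      extracted <- FALSE
    }

    stage <- "rank"
    ranking <- relative_entropy_importance(features, n_bins = n_bins)
    stage <- "select_target"
    target <- target %||% select_target(ranking)

    stage <- "discretize"
    scheme <- discretize_fit(features, n_states = n_states,
                             method = disc_method, cuts = cuts)
    disc <- discretize_apply(features, scheme)

    stage <- "learn"
    net <- chow_liu(disc, root = target, prior_count = prior_count)

    stage <- "analyze"
    strengths <- strength_table(net, features, disc)
    forces <- node_force(strengths, nodes = net$nodes)
    targets <- target_table(net, features, disc, target)

    stage <- "profile"
    tlabs <- net$states[[target]]
    tornados <- lapply(stats::setNames(tlabs, tlabs), function(s)
      tornado(net, target, s))
    profiles <- lapply(stats::setNames(tlabs, tlabs), function(s)
      dynamic_profile(net, target, s, disc = disc, max_steps = profile_steps))
    segments <- if (run_segment_profile)
      segment_profile(features, as.data.frame(disc)[[target]],
                      state_labels = tlabs, n_draws = best_draws, seed = seed)

    stage <- "evaluate"
    performance <- evaluate_target(net, features, disc, target)

    list(features = features, ranking = ranking, target = target,
         scheme = scheme, disc = disc, net = net, strengths = strengths,
         forces = forces, targets = targets, tornado = tornados,
         profiles = profiles, segments = segments,
         performance = performance, extracted = extracted)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "glcmbayes",
    version = as.character(utils::packageVersion("glcmbayes")),
    seed = seed, target = result$target,
    config = list(n_levels = n_levels, distances = distances,
                  angles = angles, symmetric = symmetric, n_bins = n_bins,
                  n_states = n_states, disc_method = disc_method,
                  prior_count = prior_count, profile_steps = profile_steps,
                  best_draws = best_draws),
    stages = c("extract", "rank", "select_target", "discretize", "learn",
               "analyze", "profile", "evaluate"),
    outputs = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(obj, file) {
      p <- file.path(out_dir, file)
      utils::write.csv(obj, p, row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs, file)
    }
    write_feature_csv(result$features, file.path(out_dir, "features.csv"))
    manifest$outputs <- c(manifest$outputs, "features.csv")
    wr(result$ranking, "ranking.csv")
    wr(cbind(as.data.frame(result$disc)), "states.csv")
    write_network_json(result$net, file.path(out_dir, "network.json"))
    manifest$outputs <- c(manifest$outputs, "network.json")
    wr(result$strengths, "arc_strengths.csv")
    wr(result$forces, "node_forces.csv")
    wr(result$targets, "target_associations.csv")
    wr(do.call(rbind, lapply(names(result$tornado), function(s)
      cbind(target_state = s, result$tornado[[s]]))), "tornado.csv")
    wr(do.call(rbind, lapply(result$profiles, `[[`, "steps")),
       "dynamic_profiles.csv")
    if (!is.null(result$segments))
      wr(do.call(rbind, lapply(names(result$segments), function(s)
        cbind(state = s, result$segments[[s]]))), "segment_profiles.csv")
    wr(result$performance$per_state, "performance_states.csv")
    wr(data.frame(metric = names(result$performance$global),
                  value = unname(result$performance$global)),
       "performance_global.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c(manifest$outputs, "manifest.json")
  }
  result$manifest <- manifest
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("glcmbayes pipeline: %d rows, target '%s'\n",
              nrow(x$features), x$target))
  cat(sprintf("Network: %d arcs; top arc %s -> %s (%.4f bits)\n",
              nrow(x$strengths), x$strengths$parent[1L],
              x$strengths$child[1L], x$strengths$kl_divergence[1L]))
  cat(sprintf("Performance: R = %.4f, RMSE = %.4f\n",
              x$performance$global["R"], x$performance$global["RMSE"]))
  invisible(x)
}
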