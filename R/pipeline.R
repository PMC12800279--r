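# End-to-end orchestration: keypoints -> angles -> normalized cycles ->
# per-class clustering QC -> subsets -> validation -> phenotyping ->
# classification + attribution, gathered into a phenotype report.

#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with the defaults used
#' throughout the package.
#'
#' @param k Clusters per class for quality control (default 5).
#' @param n_iter Maximum k-means iterations (default 100).
#' @param seed Master seed for clustering, training and attribution.
#' @param normalization \code{"linear"} or \code{"block_average"} time
#'   normalization.
#' @param reversal_threshold Swapped-correlation threshold for reversed
#'   cluster detection.
#' @param n_permutations Permutations for the validation test.
#' @param mlp An \code{\link{mlp_config}}.
#' @param shap_samples Sampled orderings for Shapley attribution; 0 skips the
#'   attribution stage.
#' @param reference Optional 101 x 4 reference signature matrix for the
#'   validation stage (e.g. motion-capture derived), or \code{NULL} to skip.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(k = 5L, n_iter = 100L, seed = 1L,
                            normalization = "linear",
                            reversal_threshold = 0.9,
                            n_permutations = 8000L, mlp = mlp_config(),
                            shap_samples = 512L, reference = NULL) {
  structure(list(k = as.integer(k), n_iter = as.integer(n_iter),
                 seed = as.integer(seed), normalization = normalization,
                 reversal_threshold = reversal_threshold,
                 n_permutations = as.integer(n_permutations), mlp = mlp,
                 shap_samples = as.integer(shap_samples),
                 reference = reference),
            class = "pipeline_config")
}

#' Run the full gait-phenotyping pipeline on a cohort
#'
#' Executes, in order: camera-frame angle extraction
#' (\code{\link{compute_angle_series}}), 101-point time normalization,
#' per-class k-means++ quality control with typical-cluster selection and
#' reversed-cluster correction, optional signature validation against a
#' reference, nearest-centroid phenotyping with ROM comparison, MLP
#' classification with held-out metrics, and Shapley time-window attribution
#' for a representative SCI cycle. Rerunning with the same cohort and
#' configuration reproduces the report exactly.
#'
#' @param cohort A list of trials (from \code{\link{generate_cohort}} or
#'   \code{\link{read_cohort}}).
#' @param config A \code{\link{pipeline_config}}.
#' @return A list of class \code{phenotype_report}; see the elements
#'   \code{subsets}, \code{qc}, \code{rom}, \code{centroid_metrics},
#'   \code{mlp_metrics}, \code{windows}, \code{validation},
#'   \code{flipped_trials}.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  labels_all <- vapply(cohort, function(t) t$label, character(1))
  classes <- sort(unique(labels_all))
  cycles <- lapply(cohort, function(trial) {
    ser <- compute_angle_series(trial$keypoints)
    normalize_time(ser, method = config$normalization)
  })
  qc <- list()
  subset1 <- list(); subset2 <- list()
  flipped <- character()
  for (cl in classes) {
    idx <- which(labels_all == cl)
    model <- cluster_cycles(cycles[idx], k = min(config$k, length(idx)),
                            n_iter = config$n_iter, seed = config$seed)
    orient <- resolve_orientation(model,
                                  threshold = config$reversal_threshold)
    typical <- orient$typical
    reversed <- orient$reversed
    subs <- build_subsets(model, cycles[idx], typical, reversed)
    qc[[cl]] <- list(model = model, typical_cluster = typical,
                     reversed_clusters = reversed)
    subset1[[cl]] <- subs$subset1
    subset2[[cl]] <- subs$subset2
    flipped <- c(flipped, subs$subset2$flipped_trials)
  }
  s2_cycles <- do.call(c, lapply(classes, function(cl) subset2[[cl]]$cycles))
  s2_labels <- do.call(c, lapply(classes, function(cl) {
    rep(cl, length(subset2[[cl]]$cycles))
  }))
  centroids <- fit_centroids(s2_cycles, s2_labels)
  centroid_metrics <- if (length(classes) >= 2L) {
    compute_metrics(s2_labels, classify_cycles(centroids, s2_cycles))
  }
  rom <- if (all(c("Healthy", "SCI") %in% classes)) {
    rom_comparison(centroids, "Healthy", "SCI")
  }
  validation <- if (!is.null(config$reference)) {
    ref_label <- if ("Healthy" %in% classes) "Healthy" else classes[1L]
    validate_signatures(centroids$centroids[[ref_label]], config$reference,
                        n_permutations = config$n_permutations,
                        seed = config$seed)
  }
  mlp <- NULL; mlp_metrics <- NULL; attribution <- NULL; windows <- NULL
  if (length(classes) == 2L) {
    mlp <- train_classifier(s2_cycles, s2_labels, config = config$mlp)
    mlp_metrics <- mlp$metrics
    if (config$shap_samples > 0L && "SCI" %in% classes) {
      sci_idx <- which(s2_labels == "SCI")[1L]
      background <- s2_cycles[s2_labels == "Healthy"]
      attribution <- shap_attribution(mlp, background, s2_cycles[[sci_idx]],
                                      n_samples = config$shap_samples,
                                      seed = config$seed)
      windows <- extract_windows(attribution)
    }
  }
  structure(list(
    n_trials = length(cohort), classes = classes,
    qc = qc,
    subsets = list(
      subset1 = lapply(subset1, function(s) s$kept_trials),
      subset2 = lapply(subset2, function(s) s$kept_trials)),
    flipped_trials = flipped,
    centroids = centroids, centroid_metrics = centroid_metrics, rom = rom,
    validation = validation, mlp = mlp, mlp_metrics = mlp_metrics,
    attribution = attribution, windows = windows,
    config = config),
    class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf("<phenotype_report> %d trials (%s)\n", x$n_trials,
              paste(x$classes, collapse = " vs ")))
  n1 <- sum(lengths(x$subsets$subset1)); n2 <- sum(lengths(x$subsets$subset2))
  cat(sprintf("  subsets: %d typical, %d after flip-correction (%d flipped)\n",
              n1, n2, length(x$flipped_trials)))
  if (!is.null(x$rom)) {
    cat("  ROM reduction (% of reference):",
        paste(sprintf("%s=%.1f", x$rom$joint, x$rom$reduction_pct),
              collapse = " "), "\n")
  }
  if (!is.null(x$centroid_metrics)) {
    cat(sprintf("  centroid classifier accuracy: %.3f\n",
                x$centroid_metrics$accuracy))
  }
  if (!is.null(x$mlp_metrics)) {
    cat(sprintf("  MLP held-out accuracy: %.3f\n", x$mlp_metrics$accuracy))
  }
  if (!is.null(x$windows) && nrow(x$windows) > 0L) {
    w <- x$windows[1L, ]
    cat(sprintf("  top attributed window: %s %d-%d%% (%s)\n",
                w$channel, w$start, w$end, w$sign))
  }
  invisible(x)
}
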