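# Phenotyping: per-class centroid ("k-means classifier") model, nearest
# centroid classification, cluster-centre ROM comparison, confusion metrics.

#' Fit per-class centroid signatures
#'
#' Each class centroid is the element-wise mean of that class's 101 x 4 cycle
#' matrices — the cluster-centre representation used for interpretable
#' nearest-centroid ("k-means classifier") phenotyping.
#'
#' @param cycles List of \code{\link{normalized_cycle}} objects (or 101 x 4
#'   matrices).
#' @param labels Class label per cycle (at least 2 classes for
#'   classification; one cycle per class suffices).
#' @return An object of class \code{centroid_classifier}: named list
#'   \code{centroids} of 101 x 4 matrices, \code{classes}, \code{n_per_class}.
#' @export
fit_centroids <- function(cycles, labels) {
  labels <- as.character(labels)
  if (length(cycles) != length(labels)) {
    stopf("`cycles` and `labels` must have equal length")
  }
  classes <- sort(unique(labels))
  centroids <- lapply(classes, function(cl) {
    mats <- lapply(cycles[labels == cl], cycle_matrix)
    Reduce(`+`, mats) / length(mats)
  })
  names(centroids) <- classes
  structure(list(centroids = centroids, classes = classes,
                 n_per_class = table(labels)),
            class = "centroid_classifier")
}

#' @export
print.centroid_classifier <- function(x, ...) {
  cat(sprintf("<centroid_classifier> classes: %s\n",
              paste(sprintf("%s (n=%d)", x$classes,
                            as.integer(x$n_per_class[x$classes])),
                    collapse = ", ")))
  invisible(x)
}

#' Classify cycles by nearest class centroid
#'
#' Euclidean distance on the flattened 4 x 101 matrices; exact ties break
#' deterministically to the first class in sorted label order.
#'
#' @param model A \code{\link{fit_centroids}} fit with at least 2 classes.
#' @param cycles A single cycle or a list of cycles.
#' @return Character vector of predicted labels.
#' @export
classify_cycles <- function(model, cycles) {
  stopifnot(inherits(model, "centroid_classifier"))
  if (length(model$classes) < 2L) stopf("need at least 2 fitted classes")
  if (inherits(cycles, "normalized_cycle") || is.matrix(cycles)) {
    cycles <- list(cycles)
  }
  C <- vapply(model$centroids, as.vector, numeric(404L))
  vapply(cycles, function(cy) {
    v <- flatten_cycle(cy)
    d <- colSums((C - v)^2)
    model$classes[which.min(d)]   # which.min keeps the first on ties
  }, character(1))
}

#' Range-of-motion comparison between two class centroids
#'
#' Per joint, the range of motion (ROM) is the max minus min of the centroid
#' time series; the reduction percentage is
#' \code{100 * (rom_reference - rom_case) / rom_reference}, and
#' \code{max_flexion_diff} is the reference peak flexion minus the case peak
#' flexion (degrees).
#'
#' @param model A \code{\link{fit_centroids}} fit.
#' @param reference_label,case_label Fitted class labels (e.g. Healthy as the
#'   reference and SCI as the case).
#' @return Data frame with one row per joint: \code{joint, rom_reference,
#'   rom_case, reduction_pct, max_flexion_diff}.
#' @export
rom_comparison <- function(model, reference_label = "Healthy",
                           case_label = "SCI") {
  stopifnot(inherits(model, "centroid_classifier"))
  for (lab in c(reference_label, case_label)) {
    if (!lab %in% model$classes) stopf("class `%s` is not fitted", lab)
  }
  ref <- model$centroids[[reference_label]]
  cas <- model$centroids[[case_label]]
  rom_ref <- channel_rom(ref)
  rom_cas <- channel_rom(cas)
  if (any(rom_ref <= 0)) {
    stopf("zero reference ROM in joint(s): %s",
          paste(gait_channels()[rom_ref <= 0], collapse = ", "))
  }
  data.frame(joint = gait_channels(),
             rom_reference = as.numeric(rom_ref),
             rom_case = as.numeric(rom_cas),
             reduction_pct = 100 * (rom_ref - rom_cas) / rom_ref,
             max_flexion_diff = apply(ref, 2L, max) - apply(cas, 2L, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Binary classification metrics from labels
#'
#' Computes the confusion counts and accuracy, precision, recall,
#' specificity and F1 with the SCI class as the positive class by default.
#' Ratios with zero denominators are reported as \code{NA}, not 0.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_label The positive class (default \code{"SCI"}).
#' @return List of class \code{classification_metrics}: \code{confusion}
#'   (TP, FP, TN, FN) and the five metrics.
#' @export
compute_metrics <- function(y_true, y_pred, positive_label = "SCI") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stopf("`y_true` and `y_pred` must be equal-length, non-empty")
  }
  tp <- sum(y_true == positive_label & y_pred == positive_label)
  fp <- sum(y_true != positive_label & y_pred == positive_label)
  tn <- sum(y_true != positive_label & y_pred != positive_label)
  fn <- sum(y_true == positive_label & y_pred != positive_label)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall,
                 specificity = ratio(tn, tn + fp), f1 = f1,
                 positive_label = positive_label),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "<classification_metrics> acc=%.3f prec=%.3f rec=%.3f spec=%.3f f1=%.3f (positive: %s)\n",
    x$accuracy, x$precision, x$recall, x$specificity, x$f1, x$positive_label))
  invisible(x)
}
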