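# Gait-cycle quality control: k-means++ clustering of normalized cycles,
# detection of direction-reversed clusters, flip correction, subset building.

cycles_to_matrix <- function(cycles) {
  if (inherits(cycles, "normalized_cycle")) cycles <- list(cycles)
  X <- t(vapply(cycles, flatten_cycle, numeric(404L)))
  ids <- vapply(seq_along(cycles), function(i) {
    cy <- cycles[[i]]
    id <- if (inherits(cy, "normalized_cycle")) cy$trial_id else NA_character_
    if (is.na(id)) sprintf("trial_%03d", i) else id
  }, character(1))
  rownames(X) <- make.unique(ids)
  X
}

#' Cluster normalized gait cycles with k-means++
#'
#' Plain Euclidean k-means on the flattened 4 x 101 cycle matrices, with
#' k-means++ seeding, at most \code{n_iter} Lloyd update rounds (or until
#' assignments stabilize) and farthest-point re-seeding of clusters that
#' empty out. Channels are not rescaled: all four share degree units.
#' Deterministic given \code{seed}.
#'
#' @param cycles List of \code{\link{normalized_cycle}} objects (at least
#'   \code{k}).
#' @param k Number of clusters (default 5, the empirical per-dataset choice
#'   for gait-cycle quality control).
#' @param n_iter Maximum Lloyd iterations (default 100).
#' @param seed Integer seed.
#' @return An object of class \code{cluster_model}: \code{k},
#'   \code{centroids} (k x 404 matrix), \code{assignments} (named integer
#'   vector of cluster ids 1..k), \code{inertia}, \code{inertia_trace} (one
#'   value per update round), \code{sizes}, \code{seed}, \code{n_iter_run}.
#' @export
cluster_cycles <- function(cycles, k = 5L, n_iter = 100L, seed = 1L) {
  X <- cycles_to_matrix(cycles)
  n <- nrow(X)
  if (n < k) stopf("need at least k = %d cycles, got %d", k, n)
  with_seed(seed, {
    centers <- kmeanspp_init(X, k)
    assign_old <- rep(0L, n)
    iter <- 0L
    inertia_trace <- numeric()
    repeat {
      iter <- iter + 1L
      d2 <- dist2_to_centers(X, centers)
      assign_new <- max.col(-d2, ties.method = "first")
      # Re-seed empty clusters from the globally farthest point.
      for (j in seq_len(k)) {
        if (!any(assign_new == j)) {
          far <- which.max(d2[cbind(seq_len(n), assign_new)])
          centers[j, ] <- X[far, ]
          assign_new[far] <- j
        }
      }
      for (j in seq_len(k)) {
        members <- which(assign_new == j)
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
      d2 <- dist2_to_centers(X, centers)
      inertia_trace <- c(inertia_trace,
                         sum(d2[cbind(seq_len(n), assign_new)]))
      if (identical(assign_new, assign_old) || iter >= n_iter) break
      assign_old <- assign_new
    }
    names(assign_new) <- rownames(X)
    structure(list(k = as.integer(k), centroids = centers,
                   assignments = assign_new,
                   inertia = inertia_trace[length(inertia_trace)],
                   inertia_trace = inertia_trace,
                   sizes = tabulate(assign_new, k), seed = as.integer(seed),
                   n_iter_run = iter),
              class = "cluster_model")
  })
}

# Squared Euclidean distances, n x k.
dist2_to_centers <- function(X, centers) {
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  pmax(outer(xx, cc, `+`) - 2 * X %*% t(centers), 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      pick <- if (sum(d2) <= 0) sample.int(n, 1L) else {
        sample.int(n, 1L, prob = d2 / sum(d2))
      }
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, %d cycles, inertia=%.1f, %d iteration(s)\n",
              x$k, length(x$assignments), x$inertia, x$n_iter_run))
  cat("  sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

# Centroid of cluster j as a 101 x 4 matrix.
centroid_cycle <- function(model, j) unflatten_cycle(model$centroids[j, ])

swap_lr_channels <- function(m) {
  out <- m[, c("RHip", "LHip", "RKnee", "LKnee"), drop = FALSE]
  colnames(out) <- gait_channels()
  out
}

#' Swap left/right channels of a cycle (reversed-trial correction)
#'
#' Direction-reversed recordings yield angle channels with left and right
#' exchanged; the correction swaps \code{LHip <-> RHip} and
#' \code{LKnee <-> RKnee}. The time axis is untouched by default; the
#' \code{"time_reverse"} mode additionally reverses the cycle in time, kept
#' behind a flag because the recording artifact it models is ambiguous.
#' Applying the swap twice is the identity.
#'
#' @param cycle A \code{\link{normalized_cycle}} or 101 x 4 matrix.
#' @param mode \code{"swap"} (default) or \code{"time_reverse"}.
#' @return Same type as the input.
#' @export
flip_trial <- function(cycle, mode = c("swap", "time_reverse")) {
  mode <- match.arg(mode)
  m <- cycle_matrix(cycle)
  out <- swap_lr_channels(m)
  if (mode == "time_reverse") out <- out[101:1, , drop = FALSE]
  if (inherits(cycle, "normalized_cycle")) {
    cycle$angles <- out
    cycle
  } else out
}

#' Detect clusters that are left/right-reversed copies of a reference
#'
#' A cluster is flagged as reversed when its centroid, after swapping the
#' left/right channels, correlates with the reference centroid above
#' \code{threshold} (Pearson, on the flattened matrices) and more strongly
#' than the unswapped centroid does.
#'
#' @param model A \code{\link{cluster_cycles}} fit.
#' @param reference_cluster Id of the typical (reference) cluster.
#' @param threshold Minimum swapped correlation (default 0.9).
#' @return Integer vector of reversed cluster ids (possibly empty).
#' @export
detect_reversed_clusters <- function(model, reference_cluster,
                                     threshold = 0.9) {
  stopifnot(inherits(model, "cluster_model"))
  if (!reference_cluster %in% seq_len(model$k)) {
    stopf("`reference_cluster` must be a cluster id in 1..%d", model$k)
  }
  ref <- as.vector(centroid_cycle(model, reference_cluster))
  out <- integer()
  for (j in setdiff(seq_len(model$k), reference_cluster)) {
    cen <- centroid_cycle(model, j)
    r_unswapped <- suppressWarnings(cor(as.vector(cen), ref))
    r_swapped <- suppressWarnings(cor(as.vector(swap_lr_channels(cen)), ref))
    if (!is.na(r_swapped) && r_swapped > threshold &&
        (is.na(r_unswapped) || r_swapped > r_unswapped)) {
      out <- c(out, j)
    }
  }
  out
}

#' Pick the cluster that best captures a clear gait signal
#'
#' The published selection of the representative cluster was empirical, so
#' this heuristic is a documented proxy with a mandatory manual override:
#' each cluster is scored by the summed channel range of motion of its
#' centroid multiplied by its membership size, favouring large clusters with
#' strong flexion excursions over flat/noisy ones.
#'
#' @param model A \code{\link{cluster_cycles}} fit.
#' @param override Explicit cluster id returned verbatim when given.
#' @return A cluster id.
#' @export
select_typical_cluster <- function(model, override = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (!is.null(override)) {
    if (!override %in% seq_len(model$k)) stopf("invalid override cluster id")
    return(as.integer(override))
  }
  score <- vapply(seq_len(model$k), function(j) {
    sum(channel_rom(centroid_cycle(model, j))) * model$sizes[j]
  }, numeric(1))
  which.max(score)
}

#' Anchor the typical cluster on the majority walking direction
#'
#' A mirrored (direction-reversed) cohort is internally symmetric: a reversed
#' cluster looks exactly like a typical one. This resolves the ambiguity by
#' majority: starting from a candidate typical cluster, the mirrored clusters
#' are detected; if they hold more trials than the clusters sharing the
#' candidate's orientation, the anchor is moved to the highest-scoring
#' mirrored cluster and detection is redone. With a minority of reversed
#' recordings (the realistic acquisition artifact) this keeps the reference
#' orientation that most trials share.
#'
#' @param model A \code{\link{cluster_cycles}} fit.
#' @param candidate Candidate typical cluster id (default
#'   \code{\link{select_typical_cluster}}).
#' @param threshold Passed to \code{\link{detect_reversed_clusters}}.
#' @return List with \code{typical} (cluster id) and \code{reversed}
#'   (integer vector of mirrored cluster ids).
#' @export
resolve_orientation <- function(model, candidate = NULL, threshold = 0.9) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(candidate)) candidate <- select_typical_cluster(model)
  reversed <- detect_reversed_clusters(model, candidate, threshold)
  if (length(reversed) > 0L) {
    aligned <- setdiff(seq_len(model$k), reversed)
    if (sum(model$sizes[reversed]) > sum(model$sizes[aligned])) {
      score <- vapply(reversed, function(j) {
        sum(channel_rom(centroid_cycle(model, j))) * model$sizes[j]
      }, numeric(1))
      candidate <- reversed[which.max(score)]
      reversed <- detect_reversed_clusters(model, candidate, threshold)
    }
  }
  list(typical = as.integer(candidate), reversed = as.integer(reversed))
}

#' Build the two refined analysis subsets from a cluster model
#'
#' Subset 1 keeps the trials of the typical cluster(s); Subset 2 additionally
#' merges the trials of the reversed cluster(s) after flip correction — the
#' larger, more comprehensive set used for downstream feature extraction.
#'
#' @param model A \code{\link{cluster_cycles}} fit.
#' @param cycles The list of \code{\link{normalized_cycle}} objects the model
#'   was fitted on (same order).
#' @param typical_clusters Integer ids of typical clusters.
#' @param reversed_clusters Integer ids of reversed clusters (disjoint from
#'   typical).
#' @param flip_mode Passed to \code{\link{flip_trial}}.
#' @return List with \code{subset1} and \code{subset2}, each of class
#'   \code{subset_definition}: \code{cycles} (flip-corrected where needed),
#'   \code{kept_trials}, \code{flipped_trials} (trial ids) and a
#'   \code{provenance} data frame (trial, cluster, action).
#' @export
build_subsets <- function(model, cycles, typical_clusters, reversed_clusters,
                          flip_mode = "swap") {
  stopifnot(inherits(model, "cluster_model"))
  if (length(intersect(typical_clusters, reversed_clusters)) > 0L) {
    stopf("typical and reversed cluster ids must be disjoint")
  }
  bad <- setdiff(c(typical_clusters, reversed_clusters), seq_len(model$k))
  if (length(bad) > 0L) stopf("invalid cluster id(s): %s",
                              paste(bad, collapse = ", "))
  ids <- names(model$assignments)
  typ_idx <- which(model$assignments %in% typical_clusters)
  rev_idx <- which(model$assignments %in% reversed_clusters)
  make_subset <- function(keep_idx, flip_idx) {
    out_cycles <- cycles[keep_idx]
    flip_pos <- match(flip_idx, keep_idx)
    for (p in flip_pos) out_cycles[[p]] <- flip_trial(out_cycles[[p]],
                                                      mode = flip_mode)
    prov <- data.frame(trial = ids[keep_idx],
                       cluster = as.integer(model$assignments[keep_idx]),
                       action = ifelse(keep_idx %in% flip_idx,
                                       "flipped", "kept"),
                       stringsAsFactors = FALSE)
    structure(list(cycles = out_cycles, kept_trials = ids[keep_idx],
                   flipped_trials = ids[flip_idx], provenance = prov),
              class = "subset_definition")
  }
  list(subset1 = make_subset(typ_idx, integer()),
       subset2 = make_subset(c(typ_idx, rev_idx), rev_idx))
}

#' @export
print.subset_definition <- function(x, ...) {
  cat(sprintf("<subset_definition> %d trials kept, %d flip-corrected\n",
              length(x$kept_trials), length(x$flipped_trials)))
  invisible(x)
}
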