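# Feature ranking and selection from a fitted weight matrix. A row of W is
# one ROI's weight across modalities, so features are scored by the
# Euclidean norm of their row; the top-k rows name the discriminative
# regions.

#' Rank features by row norm of the fitted weight matrix
#'
#' Score_j is the Euclidean norm of row j of W (the feature's weight across
#' all modalities). Ranking is by descending score; exact ties are broken
#' toward the smaller feature index so reports are reproducible. Per-modality
#' absolute weights are kept alongside for inspection.
#'
#' @param model An `fc2fs_model`.
#' @return An object of class `fc2fs_selection`: list with `scores`,
#'   `ranking` (permutation of 1..p), `selected` (initially the full
#'   ranking), `per_modality_weights` (p x m), `feature_labels`, `top_k`.
#' @export
rank_features <- function(model) {
  stopifnot(inherits(model, "fc2fs_model"))
  W <- model$W
  scores <- sqrt(rowSums(W^2))
  ranking <- order(-scores, seq_along(scores))
  structure(
    list(scores = unname(scores), ranking = ranking, selected = ranking,
         per_modality_weights = W, feature_labels = model$feature_labels,
         top_k = length(ranking)),
    class = "fc2fs_selection"
  )
}

#' Restrict a selection to its top-k features
#'
#' @param selection An `fc2fs_selection` from [rank_features()].
#' @param k Number of features to keep, `1 <= k <= p`.
#' @return The selection with `selected` set to the first
#'   `min(k, p)` entries of the ranking and `top_k = k`.
#' @export
select_top_k <- function(selection, k) {
  stopifnot(inherits(selection, "fc2fs_selection"))
  p <- length(selection$ranking)
  k <- as.integer(k)
  if (k < 1L || k > p) {
    stop(sprintf("k must lie in [1, %d], got %d", p, k), call. = FALSE)
  }
  selection$selected <- selection$ranking[seq_len(k)]
  selection$top_k <- k
  selection
}

#' @export
print.fc2fs_selection <- function(x, ...) {
  k <- length(x$selected)
  shown <- x$selected[seq_len(min(k, 10L))]
  cat(sprintf("<fc2fs_selection> top %d of %d features: %s%s\n",
              k, length(x$ranking),
              paste(x$feature_labels[shown], collapse = ", "),
              if (k > 10L) ", ..." else ""))
  invisible(x)
}

#' Build the fused feature matrix of the selected features
#'
#' With `mode = "blend"` (default) column j of the result is
#' `tau * X1[, sel_j] + (1 - tau) * X2[, sel_j]` — the same linear fusion
#' used for the feature graph — giving k columns. With `mode = "concat"` the
#' selected columns of every modality are placed side by side (m * k
#' columns, modality-major order).
#'
#' @param d An `fc2fs_dataset` (normalized to the same scale as the fit).
#' @param selection An `fc2fs_selection` with a non-empty `selected` set.
#' @param tau Fusion coefficient (two modalities; default the model's tau is
#'   supplied by the caller).
#' @param mode `"blend"` or `"concat"`.
#' @return Numeric N x d matrix (d = k or m * k) with informative column
#'   names.
#' @export
fuse_selected_features <- function(d, selection, tau = 0.3,
                                   mode = c("blend", "concat")) {
  mode <- match.arg(mode)
  stopifnot(inherits(selection, "fc2fs_selection"))
  validate_dataset(d)
  sel <- selection$selected
  if (length(sel) < 1L) stop("selection is empty", call. = FALSE)
  labs <- d$modalities[[1L]]$feature_labels[sel]
  if (mode == "blend") {
    Xf <- if (d$n_modalities == 1L) {
      d$modalities[[1L]]$values
    } else {
      fuse_feature_matrices(d$modalities, tau = tau)
    }
    out <- Xf[, sel, drop = FALSE]
    colnames(out) <- labs
  } else {
    cols <- lapply(d$modalities, function(mm) {
      x <- mm$values[, sel, drop = FALSE]
      colnames(x) <- paste(mm$modality, labs, sep = ".")
      x
    })
    out <- do.call(cbind, cols)
  }
  rownames(out) <- d$modalities[[1L]]$subject_ids
  out
}

#' Tabulate the selected features as a region report
#'
#' One row per selected feature in ranking order: rank, feature label, score,
#' the per-modality weights, and — when an ROI map is supplied — the
#' anatomical region name.
#'
#' @param selection An `fc2fs_selection`.
#' @param roi_map Optional named character vector mapping feature labels to
#'   anatomical names (see [read_roi_map()]). Labels missing from the map
#'   trigger a warning and get a blank name.
#' @return A `data.frame` with columns `rank`, `feature_label`, `score`,
#'   `weight_<modality>` (one per modality), `region_name`.
#' @export
region_report <- function(selection, roi_map = NULL) {
  stopifnot(inherits(selection, "fc2fs_selection"))
  sel <- selection$selected
  labs <- selection$feature_labels[sel]
  W <- selection$per_modality_weights[sel, , drop = FALSE]
  mods <- colnames(W)
  if (is.null(mods)) mods <- sprintf("modality%d", seq_len(ncol(W)))
  rep <- data.frame(rank = seq_along(sel), feature_label = labs,
                    score = selection$scores[sel],
                    stringsAsFactors = FALSE)
  for (j in seq_along(mods)) rep[[paste0("weight_", mods[j])]] <- W[, j]
  names_out <- rep("", length(sel))
  if (!is.null(roi_map)) {
    hit <- labs %in% names(roi_map)
    if (any(!hit)) {
      warning(sprintf("ROI map is missing %d selected label(s): %s",
                      sum(!hit), paste(labs[!hit], collapse = ", ")))
    }
    names_out[hit] <- unname(roi_map[labs[hit]])
  }
  rep$region_name <- names_out
  rownames(rep) <- NULL
  rep
}
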