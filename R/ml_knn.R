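# KNN triage workflow: training-set assembly, descriptor/PCA/KNN model with
# F-beta hyperparameter tuning, and prediction.

#' Assemble a binder/non-binder training set
#'
#' Positives are SPR-labelled binders plus (optionally) enriched round-4
#' variants; negatives are SPR-labelled non-binders plus a seeded random
#' sample of the initial library. A sequence appearing with conflicting
#' labels is resolved to binder; the number of conflicts is recorded in
#' \code{attr(, "n_conflicts")}.
#'
#' @param spr_labels Data frame with columns \code{aa} and \code{is_binder}
#'   (logical), emulating SPR kinetics calls.
#' @param round4_enriched Character vector of enriched round-4 sequences
#'   supplementing the positive class (may be empty).
#' @param library_sample Character vector of initial-library sequences from
#'   which negatives are drawn (may be empty).
#' @param neg_sample_size Number of library sequences to draw as negatives.
#' @param seed Integer seed for the negative draw.
#' @return A tibble with \code{aa}, \code{label} (\code{"binder"} /
#'   \code{"nonbinder"}), \code{provenance} (\code{"spr"},
#'   \code{"enriched_r4"}, or \code{"library_background"}).
#' @export
build_training_set <- function(spr_labels, round4_enriched = character(0),
                               library_sample = character(0),
                               neg_sample_size = length(library_sample),
                               seed = 1) {
  pos <- tibble::tibble(
    aa = c(spr_labels$aa[spr_labels$is_binder], round4_enriched),
    label = "binder",
    provenance = c(rep("spr", sum(spr_labels$is_binder)),
                   rep("enriched_r4", length(round4_enriched)))
  )
  neg_lib <- with_seed(seed, {
    if (length(library_sample) > 0 && neg_sample_size > 0) {
      sample(library_sample, min(neg_sample_size, length(library_sample)))
    } else {
      character(0)
    }
  })
  neg <- tibble::tibble(
    aa = c(spr_labels$aa[!spr_labels$is_binder], neg_lib),
    label = "nonbinder",
    provenance = c(rep("spr", sum(!spr_labels$is_binder)),
                   rep("library_background", length(neg_lib)))
  )
  conflicts <- intersect(pos$aa, neg$aa)
  neg <- neg[!neg$aa %in% conflicts, , drop = FALSE]
  out <- rbind(pos[!duplicated(pos$aa), ], neg[!duplicated(neg$aa), ])
  if (sum(out$label == "binder") == 0 || sum(out$label == "nonbinder") == 0) {
    stop("training set must contain both classes")
  }
  attr(out, "n_conflicts") <- length(conflicts)
  out
}

# Stratified cross-validation fold assignment.
#' @keywords internal
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(seq_len(k), function(f) {
    length(unique(y[fold == f])) < length(unique(y))
  }, logical(1)))) {
    stop("stratification error: a fold contains a single class")
  }
  fold
}

#' Tune and fit the PCA/KNN triage classifier
#'
#' For every grid point (number of PCA components x number of neighbours) the
#' mean stratified cross-validated F-beta is recorded; the selected point
#' maximizes it, with ties broken toward fewer components, then smaller k.
#' The final model is refit on all training data (descriptor normalization
#' and PCA are refit inside every fold, so validation scores are honest).
#'
#' @param training Training tibble from [build_training_set()].
#' @param grid List with numeric vectors \code{pca_components} and
#'   \code{k_neighbors} (k must be odd to avoid vote ties).
#' @param beta F-beta weight for the tuning objective.
#' @param cv_folds Number of stratified folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class \code{knn_triage} with the fitted
#'   normalization, PCA projection, training scores, selected
#'   hyperparameters, and the per-grid-point \code{tuning} record.
#' @export
tune_knn <- function(training,
                     grid = list(pca_components = c(2, 5, 10, 15),
                                 k_neighbors = c(3, 5, 7, 9)),
                     beta = 1, cv_folds = 5, seed = 1) {
  stopifnot(length(grid$pca_components) >= 1, length(grid$k_neighbors) >= 1,
            cv_folds >= 2)
  if (any(grid$k_neighbors %% 2 == 0)) {
    stop("k_neighbors must be odd (vote-tie avoidance)")
  }
  y <- training$label == "binder"
  feats <- featurize(training$aa)
  with_seed(seed, {
    fold <- stratified_folds(y, cv_folds)
    rank <- qr(normalize_features(feats)$x)$rank
    comps <- grid$pca_components[grid$pca_components <= rank]
    if (length(comps) == 0) stop("no grid point with pca_components <= rank")
    ks <- grid$k_neighbors[grid$k_neighbors < nrow(feats)]
    tuning <- expand.grid(pca_components = comps, k_neighbors = ks)
    tuning$fbeta <- NA_real_
    for (g in seq_len(nrow(tuning))) {
      scores <- numeric(cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        norm <- normalize_features(feats[tr, , drop = FALSE])
        pca <- fit_pca(norm$x, tuning$pca_components[g])
        tr_proj <- apply_pca(norm$x, pca)
        te_proj <- apply_pca(
          apply_normalization(feats[!tr, , drop = FALSE], norm), pca)
        pred <- class::knn(tr_proj, te_proj, factor(y[tr]),
                           k = tuning$k_neighbors[g])
        scores[f] <- fbeta_from_labels(y[!tr], pred == "TRUE", beta)
      }
      tuning$fbeta[g] <- mean(scores)
    }
    best <- tuning[order(-tuning$fbeta, tuning$pca_components,
                         tuning$k_neighbors), ][1, ]
    norm <- normalize_features(feats)
    pca <- fit_pca(norm$x, best$pca_components)
    structure(
      list(normalization = norm[c("center", "scale", "constant")],
           pca = pca,
           train_scores = apply_pca(norm$x, pca),
           train_labels = y,
           pca_components = best$pca_components,
           k_neighbors = best$k_neighbors,
           beta = beta,
           best_fbeta = best$fbeta,
           tuning = tibble::as_tibble(tuning)),
      class = "knn_triage"
    )
  })
}

#' Predict with a fitted KNN triage model
#'
#' @param object A \code{knn_triage} model.
#' @param sequences Character vector of amino-acid sequences.
#' @param type \code{"class"} for logical binder calls, \code{"prob"} for the
#'   neighbourhood binder vote fraction.
#' @param ... Unused.
#' @return Logical vector (\code{type = "class"}) or numeric probabilities.
#' @export
predict.knn_triage <- function(object, sequences, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  feats <- featurize(sequences)
  stats <- c(object$normalization, list())
  x <- sweep(sweep(feats, 2, stats$center), 2, stats$scale, "/")
  x[, stats$constant] <- 0
  proj <- apply_pca(x, object$pca)
  pred <- class::knn(object$train_scores, proj,
                     factor(object$train_labels),
                     k = object$k_neighbors, prob = TRUE)
  win_frac <- attr(pred, "prob")
  is_binder <- pred == "TRUE"
  if (type == "class") {
    is_binder
  } else {
    ifelse(is_binder, win_frac, 1 - win_frac)
  }
}

#' @export
print.knn_triage <- function(x, ...) {
  cat("<knn_triage> components =", x$pca_components,
      " k =", x$k_neighbors,
      sprintf(" (CV F%.2g = %.3f)\n", x$beta, x$best_fbeta))
  invisible(x)
}
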