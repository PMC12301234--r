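# Sequence descriptors, normalization, PCA, and the F-beta score shared by
# the triage classifiers.

#' Compute sequence-based descriptors
#'
#' Default descriptor set: the 20 amino-acid frequencies, sequence length,
#' mean Kyte-Doolittle hydropathy, net side-chain charge at pH 7 (Asp/Glu -1,
#' Lys/Arg +1, His +0.1), aromaticity (Phe/Trp/Tyr fraction), and - when a
#' CDR3 annotation is supplied - CDR3 length (25 columns; 24 without it).
#'
#' @param sequences Character vector of amino-acid sequences over the
#'   standard 20-letter alphabet.
#' @param cdr3 Optional character vector of CDR3 sequences (same length) used
#'   for the CDR3-length descriptor.
#' @return A numeric matrix, one row per sequence, with named columns.
#'   Sequences containing non-standard residues raise an error identifying
#'   the offending entries.
#' @export
#' @examples
#' featurize("AAAA")[, c("freq_A", "length")]
featurize <- function(sequences, cdr3 = NULL) {
  stopifnot(length(sequences) > 0)
  chars <- strsplit(sequences, "", fixed = TRUE)
  bad <- vapply(chars, function(x) any(!x %in% AA_STANDARD), logical(1))
  if (any(bad)) {
    stop("non-standard residues in sequence(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  n <- length(sequences)
  counts <- t(vapply(chars, function(x) {
    tabulate(factor(x, levels = AA_STANDARD), nbins = 20L)
  }, integer(20)))
  len <- nchar(sequences)
  freqs <- counts / len
  colnames(freqs) <- paste0("freq_", AA_STANDARD)
  hydro <- as.vector(freqs %*% KYTE_DOOLITTLE[AA_STANDARD])
  charge <- as.vector(counts[, match(names(AA_CHARGE), AA_STANDARD),
                             drop = FALSE] %*% AA_CHARGE)
  arom <- rowSums(freqs[, c("freq_F", "freq_W", "freq_Y"), drop = FALSE])
  out <- cbind(freqs, length = len, hydropathy = hydro,
               net_charge = charge, aromaticity = arom)
  if (!is.null(cdr3)) {
    stopifnot(length(cdr3) == n)
    out <- cbind(out, cdr3_length = nchar(cdr3))
  }
  rownames(out) <- NULL
  out
}

#' Z-score normalize a feature matrix
#'
#' Per-column centering and scaling by the population standard deviation
#' (division by n, not n - 1). Zero-variance columns are mapped to 0 and
#' flagged. The fitted statistics can be applied to new data with
#' [apply_normalization()].
#'
#' @param x Numeric matrix (>= 2 rows).
#' @return A list with \code{x} (normalized matrix), \code{center},
#'   \code{scale} (population sd, 1 for constant columns), and
#'   \code{constant} (logical flag per column).
#' @export
#' @examples
#' normalize_features(cbind(a = c(1, 3)))$x  # -1, 1
normalize_features <- function(x) {
  stopifnot(nrow(x) >= 2)
  center <- colMeans(x)
  centered <- sweep(x, 2, center)
  sd_pop <- sqrt(colMeans(centered^2))
  constant <- sd_pop == 0
  scale <- ifelse(constant, 1, sd_pop)
  list(x = sweep(centered, 2, scale, "/"), center = center, scale = scale,
       constant = constant)
}

#' Apply fitted normalization statistics to new data
#'
#' @param x Numeric matrix with the same columns as the fitting matrix.
#' @param stats Result of [normalize_features()].
#' @return Normalized matrix (constant training columns map to 0).
#' @export
apply_normalization <- function(x, stats) {
  stopifnot(identical(colnames(x), names(stats$center)))
  out <- sweep(sweep(x, 2, stats$center), 2, stats$scale, "/")
  out[, stats$constant] <- 0
  out
}

#' Fit a PCA projection
#'
#' Principal components ordered by decreasing explained variance, with a
#' deterministic sign convention: each component's largest-magnitude loading
#' is positive.
#'
#' @param x Numeric (normalized) matrix.
#' @param n_components Number of components, at most the matrix rank.
#' @return A list with \code{rotation} (loadings), \code{center},
#'   \code{explained_variance_ratio}.
#' @export
fit_pca <- function(x, n_components) {
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-9)
  if (n_components < 1 || n_components > rank) {
    stop("n_components must be between 1 and the matrix rank (", rank, ")")
  }
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  list(rotation = rot, center = pr$center,
       explained_variance_ratio = pr$sdev^2 / sum(pr$sdev^2))
}

#' Project data with a fitted PCA
#'
#' @param x Numeric matrix.
#' @param pca Result of [fit_pca()].
#' @return Score matrix (rows = observations, columns = components).
#' @export
apply_pca <- function(x, pca) {
  sweep(x, 2, pca$center) %*% pca$rotation
}

#' F-beta score
#'
#' \code{(1 + beta^2) * P * R / (beta^2 * P + R)}, defined as 0 when the
#' denominator is 0. \code{beta > 1} weights recall more heavily.
#'
#' @param precision,recall Values in [0, 1].
#' @param beta Positive weight.
#' @return The F-beta score.
#' @export
#' @examples
#' fbeta(0.5, 0.5, beta = 1)  # 0.5
fbeta <- function(precision, recall, beta = 1) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1), beta > 0)
  denom <- beta^2 * precision + recall
  ifelse(denom == 0, 0, (1 + beta^2) * precision * recall / denom)
}

# F-beta from predicted/true binary labels (positive class TRUE).
#' @keywords internal
fbeta_from_labels <- function(truth, pred, beta = 1) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  fbeta(p, r, beta)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity for binary labels.
#'
#' @param truth,pred Logical vectors (TRUE = positive class).
#' @return Balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(truth, pred) {
  sens <- if (sum(truth) == 0) NA_real_ else sum(pred & truth) / sum(truth)
  spec <- if (sum(!truth) == 0) NA_real_ else sum(!pred & !truth) / sum(!truth)
  mean(c(sens, spec))
}
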