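# Convolutional sequence classifier for binder triage.
#
# Architecture: one-hot 20-letter encoding (realised as integer lookups, so
# the convolution is a sum of per-position weight-row gathers), a single 1-D
# convolutional layer (n_filters motif detectors of width kernel_size),
# global max pooling, ReLU, one dense hidden layer with ReLU, and a sigmoid
# output. Trained full-batch with Adam on binary cross-entropy; the
# checkpoint maximizing validation F1 is returned. Right-padding uses a 21st
# "pad" symbol whose convolution weights are pinned at zero.

#' @keywords internal
encode_sequences <- function(sequences, min_len = 1L) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  L <- max(max(nchar(sequences)), min_len)
  S <- matrix(21L, nrow = length(sequences), ncol = L)
  for (i in seq_along(chars)) {
    idx <- match(chars[[i]], AA_STANDARD)
    if (anyNA(idx)) stop("non-standard residue in sequence ", i)
    S[i, seq_along(idx)] <- idx
  }
  S
}

#' @keywords internal
conv_init <- function(n_filters, kernel_size, hidden, seed_state_ok = TRUE) {
  Wc <- array(stats::rnorm(21 * kernel_size * n_filters, sd = 0.3),
              dim = c(21, kernel_size, n_filters))
  Wc[21, , ] <- 0
  list(
    Wc = Wc,
    bc = numeric(n_filters),
    W1 = matrix(stats::rnorm(n_filters * hidden, sd = sqrt(1 / n_filters)),
                n_filters, hidden),
    b1 = numeric(hidden),
    w2 = matrix(stats::rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1),
    b2 = 0
  )
}

# Forward pass; returns activations needed for backprop.
#' @keywords internal
conv_forward <- function(S, params) {
  n <- nrow(S)
  nf <- dim(params$Wc)[3]
  w <- dim(params$Wc)[2]
  P <- ncol(S) - w + 1L
  Z <- matrix(-Inf, n, nf)
  Pos <- matrix(1L, n, nf)
  bcr <- matrix(params$bc, n, nf, byrow = TRUE)
  for (p in seq_len(P)) {
    Cp <- bcr
    for (j in seq_len(w)) {
      Cp <- Cp + params$Wc[, j, ][S[, p + j - 1L], , drop = FALSE]
    }
    upd <- Cp > Z
    Z[upd] <- Cp[upd]
    Pos[upd] <- p
  }
  A <- pmax(Z, 0)
  H <- sweep(A %*% params$W1, 2, params$b1, "+")
  Hr <- pmax(H, 0)
  o <- as.vector(Hr %*% params$w2) + params$b2
  prob <- 1 / (1 + exp(-o))
  list(Z = Z, Pos = Pos, A = A, H = H, Hr = Hr, prob = prob)
}

#' @keywords internal
conv_backward <- function(S, y, params, fwd) {
  n <- nrow(S)
  nf <- dim(params$Wc)[3]
  w <- dim(params$Wc)[2]
  go <- (fwd$prob - y) / n
  gw2 <- t(fwd$Hr) %*% go
  gb2 <- sum(go)
  gH <- (go %*% t(params$w2)) * (fwd$H > 0)
  gW1 <- t(fwd$A) %*% gH
  gb1 <- colSums(gH)
  gZ <- (gH %*% t(params$W1)) * (fwd$Z > 0)
  gbc <- colSums(gZ)
  gWc <- array(0, dim = dim(params$Wc))
  row_idx <- rep.int(seq_len(n), nf)
  filt_off <- 21L * rep(seq_len(nf) - 1L, each = n)
  gz_vec <- as.vector(gZ)
  pos_vec <- as.vector(fwd$Pos)
  for (j in seq_len(w)) {
    aa_idx <- S[cbind(row_idx, pos_vec + j - 1L)]
    acc <- rowsum(gz_vec, aa_idx + filt_off)
    gvec <- numeric(21L * nf)
    gvec[as.integer(rownames(acc))] <- acc
    gWc[, j, ] <- matrix(gvec, 21L, nf)
  }
  gWc[21, , ] <- 0
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2)
}

#' Train the convolutional binder classifier
#'
#' Splits the training set into stratified train/validation parts, trains
#' full-batch with Adam, scores validation F1 after every epoch, and returns
#' the parameters of the best-scoring epoch (earliest epoch on ties, making
#' the selected checkpoint deterministic for a given seed).
#'
#' @param training Training tibble from [build_training_set()] (columns
#'   \code{aa}, \code{label}).
#' @param validation_fraction Fraction held out for checkpoint selection
#'   (must be > 0; both splits must contain both classes).
#' @param n_filters,kernel_size,hidden Architecture: number of convolutional
#'   motif detectors, their width (residues), and the dense hidden width.
#' @param epochs Training epochs (mini-batch passes over the data).
#' @param batch_size Mini-batch size; batches are reshuffled every epoch
#'   under the training seed.
#' @param learning_rate Adam step size.
#' @param seed Integer seed (initialization, split, batch order).
#' @return An object of class \code{conv_triage} with elements
#'   \code{params}, \code{best_epoch}, \code{val_f1}, and a per-epoch
#'   \code{history} tibble.
#' @export
train_conv_classifier <- function(training, validation_fraction = 0.2,
                                  n_filters = 16, kernel_size = 5,
                                  hidden = 32, epochs = 30, batch_size = 64,
                                  learning_rate = 0.02, seed = 1) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  y_all <- as.numeric(training$label == "binder")
  with_seed(seed, {
    n <- nrow(training)
    val <- logical(n)
    for (cls in c(0, 1)) {
      idx <- sample(which(y_all == cls))
      val[idx[seq_len(max(1L, round(validation_fraction * length(idx))))]] <- TRUE
    }
    if (length(unique(y_all[val])) < 2 || length(unique(y_all[!val])) < 2) {
      stop("degenerate split: a partition contains a single class")
    }
    S_tr <- encode_sequences(training$aa[!val], min_len = kernel_size)
    S_va <- encode_sequences(training$aa[val], min_len = kernel_size)
    y_tr <- y_all[!val]
    y_va <- y_all[val]

    params <- conv_init(n_filters, kernel_size, hidden)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2m <- 0.999; eps <- 1e-8
    best <- list(f1 = -1, epoch = 0L, params = params)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_f1 = numeric(0))
    step <- 0L
    n_tr <- nrow(S_tr)
    for (e in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        rows <- batches[[bi]]
        Sb <- S_tr[rows, , drop = FALSE]
        yb <- y_tr[rows]
        fwd <- conv_forward(Sb, params)
        pr <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
        losses[bi] <- -mean(yb * log(pr) + (1 - yb) * log(1 - pr))
        grads <- conv_backward(Sb, yb, params, fwd)
        step <- step + 1L
        for (nm in names(params)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grads[[nm]]
          v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v[[nm]] / (1 - b2m^step)
          params[[nm]] <- params[[nm]] -
            learning_rate * mhat / (sqrt(vhat) + eps)
        }
        params$Wc[21, , ] <- 0
      }
      val_prob <- conv_forward(S_va, params)$prob
      f1 <- fbeta_from_labels(y_va == 1, val_prob >= 0.5, beta = 1)
      history <- rbind(history, data.frame(epoch = e,
                                           train_loss = mean(losses),
                                           val_f1 = f1))
      if (f1 > best$f1) best <- list(f1 = f1, epoch = e, params = params)
    }
    structure(
      list(params = best$params, best_epoch = best$epoch, val_f1 = best$f1,
           n_filters = n_filters, kernel_size = kernel_size, hidden = hidden,
           history = tibble::as_tibble(history)),
      class = "conv_triage"
    )
  })
}

#' Predict binder probabilities with the convolutional classifier
#'
#' @param object A \code{conv_triage} model.
#' @param sequences Character vector of amino-acid sequences.
#' @param type \code{"prob"} (default) or \code{"class"} (probability >= 0.5).
#' @param ... Unused.
#' @return Numeric probabilities in [0, 1] or logical calls.
#' @export
predict.conv_triage <- function(object, sequences, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  S <- encode_sequences(sequences, min_len = object$kernel_size)
  prob <- conv_forward(S, object$params)$prob
  if (type == "prob") prob else prob >= 0.5
}

#' @export
print.conv_triage <- function(x, ...) {
  cat("<conv_triage>", x$n_filters, "filters x width", x$kernel_size,
      "| best epoch", x$best_epoch,
      sprintf("(validation F1 = %.3f)\n", x$val_f1))
  invisible(x)
}

#' Threshold predicted binders
#'
#' Keeps every sequence whose predicted binder probability is at least
#' \code{threshold}. Raising the threshold never adds members.
#'
#' @param model A fitted \code{conv_triage} or \code{knn_triage} model.
#' @param sequences Character vector of amino-acid sequences.
#' @param threshold Probability cutoff.
#' @return A tibble with \code{aa} and \code{probability} for the kept
#'   sequences.
#' @export
predict_binders <- function(model, sequences, threshold = 0.5) {
  prob <- as.numeric(predict(model, sequences, type = "prob"))
  keep <- prob >= threshold
  tibble::tibble(aa = sequences[keep], probability = prob[keep])
}

#' Diversify candidates by sequence clustering
#'
#' K-medoids (PAM) clustering on pairwise normalized edit distance
#' (Levenshtein distance divided by the longer sequence length) over the
#' full-length amino-acid sequences; the representative of each non-empty
#' cluster is its member with the highest predicted probability (ties broken
#' lexicographically). \code{n_clusters} larger than the number of distinct
#' sequences is clamped with a warning.
#'
#' @param candidates Tibble with columns \code{aa} and \code{probability}
#'   (e.g. from [predict_binders()]).
#' @param n_clusters Number of clusters requested.
#' @return A tibble of representatives with \code{aa}, \code{probability},
#'   \code{cluster_id}, ordered by cluster id.
#' @export
diversify <- function(candidates, n_clusters) {
  stopifnot(n_clusters >= 1)
  # collapse duplicates to their best probability
  best <- tapply(candidates$probability, candidates$aa, max)
  uniq <- tibble::tibble(aa = names(best), probability = as.numeric(best))
  uniq <- uniq[order(uniq$aa), ]
  n <- nrow(uniq)
  if (n_clusters > n) {
    warning("n_clusters clamped to the number of distinct sequences (", n, ")")
    n_clusters <- n
  }
  if (n_clusters == n) {
    cluster <- seq_len(n)
  } else if (n_clusters == 1) {
    cluster <- rep(1L, n)
  } else {
    d <- utils::adist(uniq$aa)
    norm <- outer(nchar(uniq$aa), nchar(uniq$aa), pmax)
    pam_fit <- cluster::pam(stats::as.dist(d / norm), k = n_clusters)
    cluster <- pam_fit$clustering
  }
  reps <- lapply(sort(unique(cluster)), function(cl) {
    members <- uniq[cluster == cl, , drop = FALSE]
    members <- members[order(-members$probability, members$aa), ]
    cbind(members[1, ], cluster_id = cl)
  })
  tibble::as_tibble(do.call(rbind, reps))
}
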