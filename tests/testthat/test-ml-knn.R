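test_that("descriptors match hand-computed values", {
  f <- featurize(c("AAAA", "KKKK", "AI"))
  expect_equal(f[1, "freq_A"], c(freq_A = 1))
  freq_cols <- startsWith(colnames(f), "freq_")
  expect_equal(unname(sum(f[1, freq_cols])), 1)  # all other frequencies 0
  expect_equal(unname(f[1, "length"]), 4)
  expect_equal(unname(f[2, "net_charge"]), 4)
  expect_equal(unname(f[3, "hydropathy"]), (1.8 + 4.5) / 2)  # Kyte-Doolittle
  expect_equal(unname(f[3, "aromaticity"]), 0)
  expect_error(featurize("AB*Z"), "non-standard")
  withcdr3 <- featurize("AAAA", cdr3 = "AA")
  expect_equal(unname(withcdr3[, "cdr3_length"]), 2)
  expect_equal(ncol(withcdr3), 25)
})

test_that("normalization is population z-scoring with constant-column flags", {
  res <- normalize_features(cbind(a = c(1, 3), b = c(2, 2)))
  expect_equal(unname(res$x[, "a"]), c(-1, 1))
  expect_equal(unname(res$x[, "b"]), c(0, 0))
  expect_true(res$constant[["b"]])
  big <- matrix(rnorm(200), 50)
  colnames(big) <- paste0("c", 1:4)
  z <- normalize_features(big)$x
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(z^2))), rep(1, 4), tolerance = 1e-12)
})

test_that("PCA orders components, bounds ratios, and captures lines", {
  withr::with_seed(8, {
    x <- matrix(rnorm(300), 100, 3)
    p <- fit_pca(x, 3)
    expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
    expect_lte(sum(p$explained_variance_ratio), 1 + 1e-9)
    # 2-D data on a line: first component captures essentially everything
    t <- rnorm(100)
    line <- cbind(t, 2 * t)
    pl <- fit_pca(line, 1)
    expect_gte(pl$explained_variance_ratio[1], 0.999)
    expect_error(fit_pca(line, 3), "rank")
  })
})

test_that("fbeta follows the weighted harmonic-mean formula", {
  expect_equal(fbeta(1, 1, 2), 1)
  expect_equal(fbeta(0.5, 0.5, 1), 0.5)
  expect_equal(fbeta(1, 0.5, 0.5), 1.25 * 0.5 / (0.25 + 0.5))
  expect_equal(fbeta(0, 0, 1), 0)
  # symmetric in P, R exactly when beta = 1
  expect_equal(fbeta(0.3, 0.8, 1), fbeta(0.8, 0.3, 1))
  expect_false(isTRUE(all.equal(fbeta(0.3, 0.8, 2), fbeta(0.8, 0.3, 2))))
  # increasing beta increases the weight on recall
  h <- 1e-6
  d1 <- (fbeta(0.6, 0.4 + h, 1) - fbeta(0.6, 0.4, 1)) / h
  d2 <- (fbeta(0.6, 0.4 + h, 3) - fbeta(0.6, 0.4, 3)) / h
  expect_gt(d2, d1)
})

test_that("training sets combine sources and resolve conflicts to binder", {
  spr <- tibble::tibble(aa = paste0("s", 1:20),
                        is_binder = rep(c(TRUE, FALSE), each = 10))
  ts <- build_training_set(spr)
  expect_equal(sum(ts$label == "binder"), 10)
  expect_equal(sum(ts$label == "nonbinder"), 10)

  conf <- build_training_set(spr, round4_enriched = "s11")
  expect_equal(attr(conf, "n_conflicts"), 1L)
  expect_identical(conf$label[conf$aa == "s11"], "binder")

  lib <- paste0("L", 1:1000)
  n1 <- build_training_set(spr, library_sample = lib, neg_sample_size = 100,
                           seed = 9)
  n2 <- build_training_set(spr, library_sample = lib, neg_sample_size = 100,
                           seed = 9)
  expect_identical(n1, n2)
  expect_equal(sum(n1$provenance == "library_background"), 100)

  expect_error(build_training_set(tibble::tibble(aa = "x", is_binder = TRUE)),
               "both classes")
})

## Two tight composition clusters (basic-residue-rich vs acidic-rich):
## linearly separable in descriptor space by construction.
cluster_training_set <- function(n_pos, n_neg, len = 30, seed = 1) {
  withr::with_seed(seed, {
    pos <- vapply(seq_len(n_pos), function(i) {
      paste(sample(c("K", "R", "A", "G"), len, replace = TRUE), collapse = "")
    }, character(1))
    neg <- vapply(seq_len(n_neg), function(i) {
      paste(sample(c("D", "E", "S", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    tibble::tibble(aa = c(pos, neg),
                   label = rep(c("binder", "nonbinder"), c(n_pos, n_neg)),
                   provenance = "spr")
  })
}

test_that("KNN tuning attains a perfect F-beta on separable data", {
  ts <- cluster_training_set(40, 40, seed = 3)
  model <- tune_knn(ts, grid = list(pca_components = c(2, 5),
                                    k_neighbors = c(3, 5)),
                    cv_folds = 5, seed = 1)
  expect_equal(model$best_fbeta, 1.0, tolerance = 1e-9)
  # grid of one point selects that point
  one <- tune_knn(ts, grid = list(pca_components = 4, k_neighbors = 7),
                  seed = 1)
  expect_equal(one$pca_components, 4)
  expect_equal(one$k_neighbors, 7)
  expect_error(tune_knn(ts, grid = list(pca_components = 2,
                                        k_neighbors = 4)),
               "odd")
})

test_that("KNN predictions generalize and expose vote probabilities", {
  ts <- cluster_training_set(50, 50, seed = 5)
  model <- tune_knn(ts, grid = list(pca_components = c(5, 10),
                                    k_neighbors = 5), seed = 2)
  fresh <- cluster_training_set(30, 30, seed = 99)
  pred <- predict(model, fresh$aa)
  expect_gte(balanced_accuracy(fresh$label == "binder", pred), 0.95)
  prob <- predict(model, fresh$aa, type = "prob")
  expect_true(all(prob >= 0 & prob <= 1))
  expect_identical(pred, prob >= 0.5)
})
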