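# Closed-form pooled-variance two-sample t, written independently of the
# implementation path.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

test_that("competition binarization thresholds relative responses", {
  m <- rbind(a = c(a = 0.10, b = 0.95), b = c(a = NA, b = 0.05))
  bl <- binarize_competition(m, 0.30)
  expect_true(bl["a", "a"])
  expect_false(bl["a", "b"])
  expect_true(is.na(bl["b", "a"]))
  expect_error(binarize_competition(-m, 0.3), "non-negative")
})

test_that("bin assignment groups identical blocking patterns", {
  # identity-only blocking: every antibody its own bin
  m <- diag(3) * 0.05 + (1 - diag(3)) * 0.9
  dimnames(m) <- list(letters[1:3], letters[1:3])
  bins <- assign_bins(binarize_competition(m))
  expect_equal(attr(bins, "n_bins"), 3)

  # two families with identical rows share bins
  fam <- competition_from_bins(list(c("x", "y"), c("p", "q", "r")))
  bins2 <- assign_bins(binarize_competition(fam))
  expect_equal(attr(bins2, "n_bins"), 2)
  expect_equal(unique(bins2$bin[bins2$antibody %in% c("p", "q", "r")]), 1)
  expect_equal(unique(bins2$bin[bins2$antibody %in% c("x", "y")]), 2)
})

test_that("bin assignment is invariant to row/column permutation", {
  fam <- competition_from_bins(list(c("a", "b", "c"), c("d", "e")))
  perm <- sample(rownames(fam))
  b1 <- assign_bins(binarize_competition(fam))
  b2 <- assign_bins(binarize_competition(fam[perm, perm]))
  expect_identical(b1[order(b1$antibody), ], b2[order(b2$antibody), ])
})

test_that("modification fraction is modified over total XIC area", {
  expect_equal(modification_fraction(25, 100), 0.25)
  expect_equal(modification_fraction(80, 80), 1)
  expect_equal(modification_fraction(0, 50), 0)
  expect_error(modification_fraction(10, 0), "positive")
  expect_error(modification_fraction(60, 50), "xic_modified")
})

test_that("footprint test matches the pooled-variance t oracle", {
  bound <- c(0.10, 0.11, 0.09, 0.10)
  unbound <- c(0.20, 0.21, 0.19, 0.20)
  res <- footprint_test(bound, unbound)
  o <- pooled_t_oracle(bound, unbound)
  expect_equal(res$t, o$t, tolerance = 1e-12)
  expect_equal(res$df, o$df)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  expect_equal(res$percent_fc, -50, tolerance = 1e-9)
  expect_identical(res$call, "protected")

  # identical samples: no change
  same <- footprint_test(c(0.1, 0.2, 0.15), c(0.2, 0.1, 0.15))
  expect_equal(same$percent_fc, 0)
  expect_identical(same$call, "unchanged")

  # increased modification upon binding: deprotection
  dep <- footprint_test(unbound, bound)
  expect_identical(dep$call, "deprotected")
  # swapping states preserves p and flips the direction
  expect_equal(dep$p, res$p, tolerance = 1e-12)
  expect_equal(sign(dep$percent_fc), -sign(res$percent_fc))

  expect_error(footprint_test(c(0.1, 0.2), c(0, 0)), "unbound mean")
})

test_that("footprint tables support optional BH adjustment", {
  pep <- expand.grid(peptide_id = c("p1", "p2"),
                     state = c("bound", "unbound"),
                     replicate = 1:4, stringsAsFactors = FALSE)
  withr::with_seed(12, {
    pep$xic_total <- 100
    pep$xic_modified <- ifelse(
      pep$peptide_id == "p1" & pep$state == "bound",
      rnorm(nrow(pep), 10, 0.5), rnorm(nrow(pep), 20, 0.5))
  })
  tab <- footprint_table(pep)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$call[tab$peptide_id == "p1"], "protected")
  tab_bh <- footprint_table(pep, p_adjust = "BH")
  expect_true(all(tab_bh$p_adj >= tab_bh$p))
})

test_that("TGI reproduces its defining formula and invariances", {
  expect_equal(compute_tgi(100, 100, 100, 1000), 100)      # no treated growth
  expect_equal(compute_tgi(100, 550, 100, 550), 0)         # equal growth
  expect_equal(compute_tgi(100, 550, 100, 1000), 50)
  # affine invariance under common rescaling
  expect_equal(compute_tgi(100, 550, 100, 1000),
               compute_tgi(250, 1375, 250, 2500))
  expect_error(compute_tgi(100, 200, 300, 300), "undefined")
})
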