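test_that("single-combination library assembles deterministically", {
  d <- vhh_library_design(pool_sizes = c(1, 1, 1), seed = 5)
  camp <- generate_library(d, 1)
  expected_nt <- paste0(d$anchor, d$frameworks_nt[["FR1"]],
                        d$cdr_pools_nt[[1]][1], d$frameworks_nt[["FR2"]],
                        d$cdr_pools_nt[[2]][1], d$frameworks_nt[["FR3"]],
                        d$cdr_pools_nt[[3]][1], d$frameworks_nt[["FR4"]])
  expect_identical(camp$clones$nt[1], expected_nt)
  expected_aa <- paste0(d$frameworks_aa[["FR1"]], d$cdr_pools_aa[[1]][1],
                        d$frameworks_aa[["FR2"]], d$cdr_pools_aa[[2]][1],
                        d$frameworks_aa[["FR3"]], d$cdr_pools_aa[[3]][1],
                        d$frameworks_aa[["FR4"]])
  expect_identical(camp$clones$aa[1], expected_aa)
})

test_that("design invariants hold: clean in-frame pools and frameworks", {
  d <- tiny_design(seed = 11)
  expect_false(any(grepl("\\*", vapply(d$frameworks_nt, function(nt) {
    translate_region(nt)$aa
  }, character(1)))))
  for (pool in d$cdr_pools_nt) expect_true(all(nchar(pool) %% 3 == 0))
  expect_identical(d$anchor, default_anchor())
})

test_that("liability planting matches ground truth exactly", {
  d <- vhh_library_design(pool_sizes = c(10, 10, 20),
                          liability_fraction = 0.2, seed = 3)
  camp <- generate_library(d, 100)
  planted <- camp$clones$planted_liability
  expect_equal(sum(!is.na(planted)), 20)
  # zero-rate case
  d0 <- tiny_design(seed = 4)
  camp0 <- generate_library(d0, 30)
  expect_true(all(is.na(camp0$clones$planted_liability)))
  # every planted clone is flagged with its planted label, clean clones not
  res <- filter_library(camp$clones)
  expect_setequal(res$removed$clone_id,
                  camp$clones$clone_id[!is.na(planted)])
})

test_that("binder-motif planting preserves liability ground truth", {
  d <- vhh_library_design(pool_sizes = c(10, 10, 20),
                          liability_fraction = 0.2, seed = 41)
  camp <- generate_library(d, 100)
  camp <- assign_affinities(camp, binder_fraction = 0.3,
                            binder_motif = "WGWG", seed = 43)
  res <- filter_library(camp$clones)
  expect_setequal(res$removed$clone_id,
                  camp$clones$clone_id[!is.na(camp$clones$planted_liability)])
})

test_that("identical seeds give byte-identical campaigns", {
  c1 <- generate_library(tiny_design(seed = 9), 40)
  c2 <- generate_library(tiny_design(seed = 9), 40)
  expect_identical(c1$clones, c2$clones)
})

test_that("affinity assignment respects class ranges and fractions", {
  camp <- generate_library(tiny_design(seed = 2), 50)
  all_b <- assign_affinities(camp, binder_fraction = 1, seed = 1)
  expect_true(all(all_b$clones$is_binder))
  expect_true(all(all_b$clones$kd <= 1e-7))

  mix <- assign_affinities(camp, binder_fraction = 0.5, seed = 1)
  kb <- mix$clones$kd[mix$clones$is_binder]
  kn <- mix$clones$kd[!mix$clones$is_binder]
  expect_true(max(kb) < min(kn))

  expect_error(assign_affinities(camp, kd_binder_range = c(1e-8, 1e-5),
                                 kd_nonbinder_range = c(1e-6, 1e-4)),
               "strictly below")
})

test_that("binder count lands in the binomial 99% interval", {
  d <- vhh_library_design(pool_sizes = c(15, 15, 25), seed = 21)
  camp <- generate_library(d, 1000)
  camp <- assign_affinities(camp, binder_fraction = 0.1, seed = 77)
  n_b <- sum(camp$clones$is_binder)
  bounds <- stats::qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_b, bounds[1])
  expect_lte(n_b, bounds[2])
})

test_that("selection round matches the closed-form Langmuir expectation", {
  # one binder (1 nM) vs one equal-count non-binder (10 uM) at C = 100 nM
  C <- 100e-9
  kd <- c(1e-9, 1e-5)
  w <- 1 * (C / (C + kd) + 0.001)
  expected_freq <- w[1] / sum(w)
  expect_equal(expected_freq, 0.989, tolerance = 1e-3)
  out <- simulate_round(c(1e6, 1e6), kd, C, 0.001, 1e6, seed = 42)
  expect_equal(out[1] / 1e6, expected_freq, tolerance = 5e-3)

  # symmetry: identical K_D leaves expected frequencies unchanged
  eq <- simulate_round(c(5e5, 5e5), c(1e-9, 1e-9), C, 0.001, 1e6, seed = 1)
  expect_equal(eq[1] / 1e6, 0.5, tolerance = 5e-3)

  # saturation: C >> K_D makes weights proportional to counts only
  sat <- simulate_round(c(9e5, 1e5), c(1e-12, 1e-4), 1e3, 0.001, 1e6,
                        seed = 2)
  expect_equal(sat[1] / 1e6, 0.9, tolerance = 5e-3)

  expect_error(simulate_round(c(0, 0), kd, C, 0.001, 100), "degenerate")
})

test_that("per-round frequencies sum to one and totals are conserved", {
  camp <- tiny_campaign(seed = 31)
  freqs <- compute_frequencies(camp$counts)
  expect_equal(unname(colSums(freqs)), rep(1, ncol(freqs)), tolerance = 1e-9)
  expect_true(all(colSums(camp$counts) == camp$config$reads_per_round))
})

test_that("the best binder enriches monotonically in most campaigns", {
  hits <- vapply(1:20, function(s) {
    camp <- tiny_campaign(seed = 100 + s, n_clones = 200, reads = 20000)
    best <- which.min(camp$clones$kd)
    freq <- camp$counts[best, ] / colSums(camp$counts)
    all(diff(freq) >= 0)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fastq emission conserves reads and models errors correctly", {
  camp <- tiny_campaign(seed = 51, n_clones = 50, reads = 500)
  f <- withr::local_tempfile(fileext = ".fastq")
  n <- emit_fastq(camp, 4, f, error_rate = 0, seed = 1)
  expect_equal(n, sum(camp$counts[, "R4"]))
  reads <- Biostrings::readDNAStringSet(f, format = "fastq")
  expect_equal(length(reads), n)
  ids <- sub(":.*", "", names(reads))
  expect_identical(as.character(unname(reads)),
                   camp$clones$nt[match(ids, camp$clones$clone_id)])

  # substitution-error expectation: ~ error_rate * length mismatches/read
  f2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(camp, 4, f2, error_rate = 0.01, seed = 7)
  noisy <- as.character(Biostrings::readDNAStringSet(f2, format = "fastq"))
  clean <- camp$clones$nt[match(ids, camp$clones$clone_id)]
  mism <- mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, noisy, clean)
  L <- nchar(clean[1])
  expect_equal(mean(mism), 0.01 * L, tolerance = 0.15)
})

test_that("fastq emission is byte-identical under a fixed seed", {
  camp <- tiny_campaign(seed = 61, n_clones = 40, reads = 400)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(camp, 4, f1, error_rate = 0.01, spike_fraction = 0.05, seed = 3)
  emit_fastq(camp, 4, f2, error_rate = 0.01, spike_fraction = 0.05, seed = 3)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
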