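# Oracle used below: plain regex matching over the default registry patterns,
# applied independently of the scanner's interval bookkeeping.
regex_oracle <- function(pattern, x) {
  m <- gregexpr(paste0("(?=", pattern, ")"), x, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

test_that("NGT in a CDR yields deamidation and sequon findings", {
  aa <- paste0(strrep("A", 10), "NGT", strrep("A", 10))
  rec <- make_record(aa, list(c(5, 8), c(10, 13), c(16, 20)))
  rep <- scan_liabilities(rec, liability_registry())
  labs <- rep$label[rep$category == "PTM"]
  expect_setequal(labs, c("deamidation_NG", "nglyc_sequon"))
  # positions agree with the regex oracle
  expect_equal(rep$start[rep$label == "deamidation_NG"],
               regex_oracle("N[GST]", aa))
  expect_equal(rep$start[rep$label == "nglyc_sequon"],
               regex_oracle("N[^P][ST]", aa))
})

test_that("NPS is not a glycosylation sequon", {
  aa <- paste0(strrep("A", 10), "NPS", strrep("A", 10))
  rec <- make_record(aa, list(c(5, 8), c(10, 13), c(16, 20)))
  rep <- scan_liabilities(rec, liability_registry())
  expect_false("nglyc_sequon" %in% rep$label)
})

test_that("SfiI wildcard site is found at oracle positions in nucleotide", {
  nt <- paste0("ATGATG", "GGCCAAAAAGGCC", "ATGATG")
  rec <- list(clone_id = "x", nt = nt, aa = strrep("A", 8),
              regions = NULL, aa_offset_nt = NA_integer_)
  rep <- scan_liabilities(rec, liability_registry()[
    liability_registry()$level == "nucleotide", ], cdr_only = FALSE)
  sfii <- rep[rep$label == "SfiI", ]
  expect_equal(nrow(sfii), 1)
  expect_equal(sfii$start, regex_oracle("GGCC[ACGT]{5}GGCC", nt))
  # round-trip: the reported slice matches the pattern
  slice <- substr(nt, sfii$start + 1, sfii$end)
  expect_true(grepl("^GGCC[ACGT]{5}GGCC$", slice))
})

test_that("scanning is position-complete across concatenation junctions", {
  left <- "AAAAN"
  right <- "GAAAA"
  rec <- list(clone_id = "j", nt = NA_character_,
              aa = paste0(left, right), regions = NULL,
              aa_offset_nt = NA_integer_)
  rep <- scan_liabilities(rec, liability_registry(), cdr_only = FALSE)
  expect_true("deamidation_NG" %in% rep$label)
  expect_equal(rep$start[rep$label == "deamidation_NG"], 4L)
})

test_that("report positions round-trip on generated libraries", {
  d <- vhh_library_design(pool_sizes = c(10, 10, 20),
                          liability_fraction = 0.3, seed = 19)
  camp <- generate_library(d, 60)
  res <- filter_library(camp$clones)
  prot <- res$report[res$report$level == "protein", ]
  for (i in seq_len(nrow(prot))) {
    aa <- camp$clones$aa[camp$clones$clone_id == prot$clone_id[i]]
    slice <- substr(aa, prot$start[i] + 1, prot$end[i])
    pat <- liability_registry()$pattern[
      liability_registry()$label == prot$label[i]]
    if (pat == "<unpaired_cys>") pat <- "C"
    pat <- sub("^\\^", "", pat)
    expect_true(grepl(paste0("^(", pat, ")$"), slice, perl = TRUE))
  }
})

test_that("policy semantics: only disqualifying categories remove clones", {
  d <- vhh_library_design(pool_sizes = c(10, 10, 20),
                          liability_fraction = 0.3, seed = 23)
  camp <- generate_library(d, 60)
  res_restr <- filter_library(camp$clones, policy = "restriction")
  planted <- camp$clones$planted_liability
  restr_ids <- camp$clones$clone_id[!is.na(planted) & planted == "SfiI"]
  expect_setequal(res_restr$removed$clone_id, restr_ids)
  # PTM-bearing clones are kept under a restriction-only policy
  ptm_ids <- camp$clones$clone_id[!is.na(planted) &
                                    planted == "deamidation_NG"]
  expect_true(all(ptm_ids %in% res_restr$kept$clone_id))
})

test_that("liability-free libraries pass untouched; pyroGlu is flag-only", {
  camp <- generate_library(tiny_design(seed = 29), 40)
  res <- filter_library(camp$clones)
  expect_equal(nrow(res$removed), 0)
  # frameworks start with E: the pyroglutamate precursor must be reported
  # on every clone yet never disqualify
  expect_true(all(camp$clones$clone_id %in%
                    res$report$clone_id[res$report$label == "pyroglutamate"]))
  expect_true(nrow(res$kept) == 40)
})

test_that("kept and removed partition the input", {
  d <- vhh_library_design(pool_sizes = c(10, 10, 20),
                          liability_fraction = 0.25, seed = 31)
  camp <- generate_library(d, 80)
  res <- filter_library(camp$clones)
  expect_equal(nrow(res$kept) + nrow(res$removed), 80)
  expect_length(intersect(res$kept$clone_id, res$removed$clone_id), 0)
})

test_that("cdr_only scanning of unannotated records is a scope error", {
  rec <- list(clone_id = "u", nt = NA_character_, aa = "AAANGTAAA",
              regions = NULL, aa_offset_nt = NA_integer_)
  expect_error(scan_liabilities(rec, liability_registry(), cdr_only = TRUE),
               "annotated")
})
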