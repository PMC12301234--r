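test_that("anchor location finds the payload on either strand", {
  anchor <- default_anchor()
  payload <- "ATGGCCAAAGGG"
  off <- locate_vhh(paste0(anchor, payload), anchor)
  expect_equal(as.integer(off), nchar(anchor))
  expect_identical(attr(off, "strand"), "+")

  expect_true(is.na(locate_vhh("ACGTACGTACGT", anchor)))

  # reverse-complement recovery, checked against a brute-force two-strand
  # oracle built directly in the test
  read_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(anchor, payload))))
  oracle <- local({
    hit <- regexpr(anchor, read_rc, fixed = TRUE)
    if (hit == -1L) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read_rc)))
      substr(rc, regexpr(anchor, rc, fixed = TRUE) + nchar(anchor), nchar(rc))
    } else {
      substr(read_rc, hit + nchar(anchor), nchar(read_rc))
    }
  })
  expect_identical(extract_vhh(read_rc, anchor), oracle)
  expect_identical(oracle, payload)
})

test_that("translation flags frame, stop and ambiguity conditions", {
  expect_identical(translate_region("ATGGCC"),
                   list(aa = "MA", flags = character(0)))
  expect_true("internal-stop" %in% translate_region("ATGTAAGGG")$flags)
  expect_true("frame-remainder" %in% translate_region("ATGGC")$flags)
  expect_true("ambiguous-base" %in% translate_region("ATGNCC")$flags)
})

test_that("region annotation recovers planted CDRs and tiles the sequence", {
  d <- tiny_design(seed = 13)
  camp <- generate_library(d, 20)
  for (i in c(1, 7, 20)) {
    ann <- annotate_regions(camp$clones$aa[i])
    expect_false(is.null(ann$regions))
    r <- ann$regions
    expect_identical(substr(camp$clones$aa[i], r["CDR3", "start"] + 1,
                            r["CDR3", "end"]),
                     camp$clones$cdr3[i])
    # contiguous tiling in order
    expect_equal(unname(r[-1, "start"]), unname(r[-nrow(r), "end"]))
    expect_equal(r["FR1", "start"], c(start = 0L), ignore_attr = TRUE)
    expect_equal(unname(r["FR4", "end"]), nchar(camp$clones$aa[i]))
  }
})

test_that("fuzzy framework matching tolerates two substitutions", {
  d <- tiny_design(seed = 14)
  camp <- generate_library(d, 5)
  aa <- camp$clones$aa[1]
  r <- camp$clones$regions[[1]]
  mutated <- aa
  p1 <- r["FR3", "start"] + 3L
  p2 <- r["FR3", "start"] + 10L
  substr(mutated, p1 + 1L, p1 + 1L) <- "W"
  substr(mutated, p2 + 1L, p2 + 1L) <- "W"
  ann <- annotate_regions(mutated)
  expect_false(is.null(ann$regions))
  expect_identical(substr(mutated, ann$regions["CDR3", "start"] + 1,
                          ann$regions["CDR3", "end"]),
                   camp$clones$cdr3[1])
})

test_that("annotation failures are kept and flagged", {
  fr <- vhh_frameworks()
  no_fr4 <- paste0(fr["FR1"], "GGSAAAG", fr["FR2"], "TTTTTT",
                   fr["FR3"], "AAAAGGGG")
  ann <- annotate_regions(no_fr4)
  expect_null(ann$regions)
  expect_true(any(grepl("missing-FR4", ann$flags)))

  adjacent <- paste0(fr["FR1"], fr["FR2"], "TTTTTT", fr["FR3"],
                     "AAAAGGGG", fr["FR4"])
  ann2 <- annotate_regions(adjacent)
  expect_null(ann2$regions)
  expect_true("empty-cdr" %in% ann2$flags)
})

test_that("every read is accounted for across annotation outcomes", {
  camp <- tiny_campaign(seed = 71, n_clones = 60, reads = 800)
  f <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(camp, 4, f, error_rate = 0.005, spike_fraction = 0.05, seed = 5)
  ann <- annotate_reads(f)
  acc <- attr(ann, "accounting")
  expect_equal(acc[["total"]],
               acc[["annotated"]] + acc[["flagged"]] + acc[["anchorless"]])
  expect_gt(acc[["anchorless"]], 0)  # spikes present
})

test_that("ELISA hit rule is an inclusive three-fold-over-background call", {
  wells <- data.frame(
    clone_id = c("at", "below", "blank"),
    signal = c(0.90, 0.89, 0.20),
    background = c(0.30, 0.30, 0)
  )
  expect_setequal(call_elisa_hits(wells), c("at", "blank"))
  expect_error(call_elisa_hits(data.frame(clone_id = "x", signal = -1,
                                          background = 0.1)),
               "negative")
})

test_that("dereplication orders by count then lexicographically", {
  out <- dereplicate(c("A", "A", "B"))
  expect_equal(out$aa, c("A", "B"))
  expect_equal(out$count, c(2L, 1L))
  tied <- dereplicate(c("B", "A"))
  expect_equal(tied$aa, c("A", "B"))
  expect_equal(nrow(dereplicate(character(0))), 0)
})
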