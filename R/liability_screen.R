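# Sequence-liability screening: motif registry, scanner, and library filter.
#
# The registry mirrors the developability screen applied to synthetic-library
# CDR diversities before synthesis: post-translational-modification motifs,
# cryptic splice-site consensus sequences, and restriction sites used in
# cloning. Patterns are regular expressions; protein-level patterns are
# scanned on the amino-acid sequence (restricted to CDRs by default),
# nucleotide-level patterns on the full nucleotide sequence.

#' Default liability-motif registry
#'
#' Returns the default registry of manufacturability liabilities:
#' \itemize{
#'   \item PTM motifs (protein level, CDR-restricted by default): deamidation
#'     \code{N[GST]}, isomerization \code{D[GST]}, N-glycosylation sequon
#'     \code{N[^P][ST]}, unpaired cysteine (an odd number of Cys across the
#'     CDRs flags every CDR cysteine).
#'   \item N-terminal pyroglutamate precursor (E/Q at position 1), category
#'     \code{"flag"}: reported but never disqualifying under the default
#'     policy, and always scanned at the N terminus.
#'   \item Cryptic splice sites (nucleotide level): donor consensus
#'     \code{GGT[AG]AG} and acceptor poly-pyrimidine tract \code{[CT]{6}.CAG}.
#'   \item Restriction sites (nucleotide level): SfiI
#'     \code{GGCC.....GGCC} (the cloning enzyme). EcoRI \code{GAATTC} and NotI
#'     \code{GCGGCCGC} are included only when \code{extras = TRUE}.
#' }
#'
#' @param extras Include the optional EcoRI/NotI restriction sites.
#' @return A tibble with columns \code{label}, \code{level}
#'   (\code{"protein"}/\code{"nucleotide"}), \code{pattern} (regex, or the
#'   special token \code{"<unpaired_cys>"}), and \code{category}
#'   (\code{"PTM"}, \code{"splice"}, \code{"restriction"}, \code{"flag"}).
#' @export
#' @examples
#' liability_registry()
liability_registry <- function(extras = FALSE) {
  reg <- tibble::tibble(
    label = c("deamidation_NG", "isomerization_DG", "nglyc_sequon",
              "unpaired_cys", "pyroglutamate",
              "splice_donor", "splice_acceptor", "SfiI"),
    level = c("protein", "protein", "protein", "protein", "protein",
              "nucleotide", "nucleotide", "nucleotide"),
    pattern = c("N[GST]", "D[GST]", "N[^P][ST]", "<unpaired_cys>", "^[EQ]",
                "GGT[AG]AG", "[CT]{6}[ACGT]CAG", "GGCC[ACGT]{5}GGCC"),
    category = c("PTM", "PTM", "PTM", "PTM", "flag",
                 "splice", "splice", "restriction")
  )
  if (extras) {
    reg <- rbind(reg, tibble::tibble(
      label = c("EcoRI", "NotI"),
      level = "nucleotide",
      pattern = c("GAATTC", "GCGGCCGC"),
      category = "restriction"
    ))
  }
  reg
}

#' Read a liability registry from YAML
#'
#' The YAML file holds a list of entries with fields \code{label},
#' \code{level}, \code{pattern} and \code{category}.
#'
#' @param path Path to the YAML file.
#' @return A registry tibble as in [liability_registry()].
#' @export
read_liability_registry <- function(path) {
  entries <- yaml::read_yaml(path)
  tibble::tibble(
    label = vapply(entries, `[[`, character(1), "label"),
    level = vapply(entries, `[[`, character(1), "level"),
    pattern = vapply(entries, `[[`, character(1), "pattern"),
    category = vapply(entries, `[[`, character(1), "category")
  )
}

# Scan one string with one regex, returning all (possibly overlapping) match
# intervals as 0-based half-open [start, end).
#' @keywords internal
scan_pattern <- function(pattern, x) {
  starts <- regex_starts(pattern, x)
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  lens <- vapply(starts, function(s) {
    m <- regexpr(paste0("^(", pattern, ")"), substr(x, s, nchar(x)), perl = TRUE)
    attr(m, "match.length")
  }, integer(1))
  data.frame(start = starts - 1L, end = starts - 1L + lens)
}

# Name of the annotated region fully containing [start, end) (aa coords);
# "junction" if it straddles a boundary, NA if no annotation.
#' @keywords internal
containing_region <- function(regions, start, end) {
  if (is.null(regions)) return(NA_character_)
  hit <- rownames(regions)[regions[, "start"] <= start & regions[, "end"] >= end]
  if (length(hit) >= 1) hit[1] else "junction"
}

#' Scan a sequence record for liability motifs
#'
#' Protein-level motifs are scanned on the amino-acid sequence (restricted to
#' CDR intervals when \code{cdr_only = TRUE}, the default, matching a screen
#' applied to CDR diversities); nucleotide-level motifs are always scanned on
#' the full nucleotide sequence. The unpaired-cysteine rule flags every CDR
#' cysteine when their total count across the CDRs is odd. N-terminal
#' anchored patterns (pyroglutamate precursor) are scanned on the full
#' amino-acid sequence regardless of \code{cdr_only}.
#'
#' @param record A list or one-row data frame with fields \code{clone_id},
#'   \code{nt} (nucleotide sequence, may be \code{NA}), \code{aa} (amino-acid
#'   sequence), and \code{regions} (a matrix with rows FR1..FR4/CDR1..CDR3 and
#'   columns \code{start}, \code{end}, 0-based half-open amino-acid
#'   coordinates; may be \code{NULL} when unannotated).
#' @param registry Registry tibble as returned by [liability_registry()].
#' @param cdr_only Restrict protein-level scanning to CDR intervals.
#' @return A tibble of findings with columns \code{clone_id}, \code{label},
#'   \code{category}, \code{level}, \code{start}, \code{end} (0-based
#'   half-open; amino-acid coordinates for protein motifs, nucleotide
#'   coordinates for nucleotide motifs), and \code{region}.
#' @export
#' @examples
#' rec <- list(clone_id = "c1", nt = NA, aa = "AANGTAA",
#'             regions = cbind(start = c(0, 2, 5), end = c(2, 5, 7)) |>
#'               `rownames<-`(c("FR1", "CDR1", "FR2")))
#' scan_liabilities(rec, liability_registry())
scan_liabilities <- function(record, registry, cdr_only = TRUE) {
  stopifnot(nrow(registry) > 0)
  if (is.data.frame(record)) record <- as.list(record[1, ])
  if (is.list(record$regions) && !is.matrix(record$regions)) {
    record$regions <- record$regions[[1]]
  }
  regions <- record$regions
  aa <- record$aa
  nt <- record$nt
  cdr_rows <- if (!is.null(regions)) {
    intersect(c("CDR1", "CDR2", "CDR3"), rownames(regions))
  } else {
    character(0)
  }
  if (cdr_only && is.null(regions) && any(registry$level == "protein")) {
    stop("cdr_only scanning requires an annotated record (regions missing)")
  }

  out <- list()
  add <- function(label, category, level, start, end, region) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      clone_id = record$clone_id %||% NA_character_,
      label = label, category = category, level = level,
      start = as.integer(start), end = as.integer(end), region = region
    )
  }

  for (i in seq_len(nrow(registry))) {
    lab <- registry$label[i]
    pat <- registry$pattern[i]
    lev <- registry$level[i]
    cat_ <- registry$category[i]

    if (lev == "protein" && pat == "<unpaired_cys>") {
      if (length(cdr_rows) == 0) next
      pos <- integer(0)
      for (r in cdr_rows) {
        s <- regions[r, "start"]; e <- regions[r, "end"]
        sub <- substr(aa, s + 1, e)
        hits <- which(strsplit(sub, "", fixed = TRUE)[[1]] == "C")
        pos <- c(pos, s + hits - 1L)
      }
      if (length(pos) %% 2 == 1) {
        for (p in pos) add(lab, cat_, lev, p, p + 1L,
                           containing_region(regions, p, p + 1L))
      }
    } else if (lev == "protein" && startsWith(pat, "^")) {
      m <- scan_pattern(pat, aa)
      if (nrow(m) > 0) {
        add(lab, cat_, lev, m$start, m$end,
            containing_region(regions, m$start[1], m$end[1]))
      }
    } else if (lev == "protein") {
      if (cdr_only) {
        for (r in cdr_rows) {
          s <- regions[r, "start"]; e <- regions[r, "end"]
          m <- scan_pattern(pat, substr(aa, s + 1, e))
          for (k in seq_len(nrow(m))) {
            add(lab, cat_, lev, m$start[k] + s, m$end[k] + s, r)
          }
        }
      } else {
        m <- scan_pattern(pat, aa)
        for (k in seq_len(nrow(m))) {
          add(lab, cat_, lev, m$start[k], m$end[k],
              containing_region(regions, m$start[k], m$end[k]))
        }
      }
    } else { # nucleotide
      if (is.null(nt) || is.na(nt)) next
      m <- scan_pattern(pat, nt)
      for (k in seq_len(nrow(m))) {
        region <- NA_character_
        if (!is.null(regions) && !is.null(record$aa_offset_nt) &&
            !is.na(record$aa_offset_nt)) {
          aa_s <- (m$start[k] - record$aa_offset_nt) %/% 3
          aa_e <- (m$end[k] - 1L - record$aa_offset_nt) %/% 3 + 1L
          if (aa_s >= 0) region <- containing_region(regions, aa_s, aa_e)
        }
        add(lab, cat_, lev, m$start[k], m$end[k], region)
      }
    }
  }

  if (length(out) == 0) {
    tibble::tibble(clone_id = character(0), label = character(0),
                   category = character(0), level = character(0),
                   start = integer(0), end = integer(0), region = character(0))
  } else {
    do.call(rbind, out)
  }
}

#' Filter a library on liability findings
#'
#' Scans every record and removes those with at least one finding in a
#' disqualifying category. Kept and removed sets are disjoint and together
#' equal the input.
#'
#' @param records A tibble of records with columns \code{clone_id}, \code{nt},
#'   \code{aa}, and a \code{regions} list-column (as produced by
#'   [generate_library()] or [annotate_reads()]).
#' @param registry Registry tibble; defaults to [liability_registry()].
#' @param policy Character vector of disqualifying categories.
#' @param cdr_only Passed to [scan_liabilities()].
#' @return A list with elements \code{kept}, \code{removed} (tibbles of
#'   records) and \code{report} (the concatenated findings tibble).
#' @export
filter_library <- function(records,
                           registry = liability_registry(),
                           policy = c("PTM", "splice", "restriction"),
                           cdr_only = TRUE) {
  reports <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- list(
      clone_id = records$clone_id[i],
      nt = if ("nt" %in% names(records)) records$nt[i] else NA_character_,
      aa = records$aa[i],
      regions = if ("regions" %in% names(records)) records$regions[[i]] else NULL,
      aa_offset_nt = if ("aa_offset_nt" %in% names(records)) {
        records$aa_offset_nt[i]
      } else {
        NA_integer_
      }
    )
    reports[[i]] <- scan_liabilities(rec, registry, cdr_only = cdr_only)
  }
  report <- do.call(rbind, reports)
  bad_ids <- unique(report$clone_id[report$category %in% policy])
  removed <- records[records$clone_id %in% bad_ids, , drop = FALSE]
  kept <- records[!records$clone_id %in% bad_ids, , drop = FALSE]
  list(kept = kept, removed = removed, report = report)
}
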