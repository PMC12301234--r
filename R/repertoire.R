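# Repertoire processing: turn raw reads into annotated VHH records.

#' Locate the amplicon anchor in a read
#'
#' Searches the forward strand for the first exact anchor occurrence, then the
#' reverse complement. Returns the 0-based offset of the first base after the
#' anchor (on the matching strand), with attribute \code{strand} set to
#' \code{"+"} or \code{"-"}; \code{NA} when the anchor is absent from both
#' strands.
#'
#' @param read Nucleotide string.
#' @param anchor Nucleotide anchor string (non-empty).
#' @return Integer offset (0-based) or \code{NA_integer_}.
#' @export
#' @examples
#' locate_vhh(paste0(default_anchor(), "ATGGCC"), default_anchor())  # 30
locate_vhh <- function(read, anchor) {
  stopifnot(nchar(anchor) > 0)
  m <- regexpr(anchor, read, fixed = TRUE)
  if (m[1] != -1L) {
    return(structure(as.integer(m[1] - 1L + nchar(anchor)), strand = "+"))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  m <- regexpr(anchor, rc, fixed = TRUE)
  if (m[1] != -1L) {
    return(structure(as.integer(m[1] - 1L + nchar(anchor)), strand = "-"))
  }
  structure(NA_integer_, strand = NA_character_)
}

#' Extract the VHH payload downstream of the anchor
#'
#' @param read Nucleotide string.
#' @param anchor Nucleotide anchor string.
#' @return The payload (anchor-downstream sequence on the matching strand) or
#'   \code{NA_character_} if the anchor is not found.
#' @export
extract_vhh <- function(read, anchor) {
  off <- locate_vhh(read, anchor)
  if (is.na(off)) return(NA_character_)
  s <- if (attr(off, "strand") == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  } else {
    read
  }
  substr(s, off + 1L, nchar(s))
}

#' Translate a nucleotide region in frame 0
#'
#' Standard genetic code; quality flags are attached rather than raising
#' errors: \code{"frame-remainder"} when the length is not a multiple of 3
#' (trailing bases dropped), \code{"ambiguous-base"} when non-ACGT letters are
#' present (fuzzy codons translate to \code{X}), \code{"internal-stop"} when a
#' stop codon occurs before the last position.
#'
#' @param nt Nucleotide string.
#' @return A list with \code{aa} (amino-acid string) and \code{flags}
#'   (character vector, possibly empty).
#' @export
#' @examples
#' translate_region("ATGGCC")$aa   # "MA"
translate_region <- function(nt) {
  flags <- character(0)
  if (nchar(nt) %% 3 != 0) {
    flags <- c(flags, "frame-remainder")
    nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
  }
  if (grepl("[^ACGT]", nt)) flags <- c(flags, "ambiguous-base")
  if (nchar(nt) == 0) return(list(aa = "", flags = flags))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  stops <- regex_starts("\\*", aa)
  if (length(stops) > 0 && any(stops < nchar(aa))) {
    flags <- c(flags, "internal-stop")
  }
  list(aa = aa, flags = flags)
}

# Best match of `pattern` in `subject` (AA strings): minimal-mismatch
# position up to max_mismatch substitutions (exact matches dominate by
# construction). Returns 0-based start or NA; attribute "ambiguous" when
# multiple best matches exist. Vectorized sliding mismatch count - patterns
# are short framework segments, so this stays cheap.
#' @keywords internal
best_fr_match <- function(pattern, subject, max_mismatch = 2) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] != -1L) {
    return(structure(as.integer(m[1] - 1L), ambiguous = length(m) > 1))
  }
  if (max_mismatch > 0) {
    sv <- utf8ToInt(subject)
    pv <- utf8ToInt(pattern)
    np <- length(sv) - length(pv) + 1L
    if (np >= 1) {
      mm <- integer(np)
      for (j in seq_along(pv)) {
        mm <- mm + (sv[j:(j + np - 1L)] != pv[j])
      }
      best <- min(mm)
      if (best <= max_mismatch) {
        hits <- which(mm == best)
        return(structure(hits[1] - 1L, ambiguous = length(hits) > 1))
      }
    }
  }
  structure(NA_integer_, ambiguous = FALSE)
}

#' Annotate framework and CDR regions of a VHH amino-acid sequence
#'
#' Locates the four framework segments in order (exact match first, then
#' fuzzy matching tolerating up to \code{max_mismatch} substitutions, which
#' absorbs translated sequencing errors); the CDRs are the inter-framework
#' gaps. Annotation fails (with a flag, not an error) when a framework is
#' missing or ambiguous, when frameworks appear out of order, when a CDR gap
#' is empty, or when FR1/FR4 do not reach the sequence ends (the regions must
#' tile the sequence).
#'
#' @param aa Amino-acid string.
#' @param scheme Named character vector with elements FR1..FR4 (amino-acid
#'   framework sequences); defaults to [vhh_frameworks()].
#' @param max_mismatch Maximum substitutions per framework in fuzzy matching.
#' @return A list with \code{regions} (matrix rows FR1..FR4/CDR1..3, columns
#'   \code{start}, \code{end}, 0-based half-open; \code{NULL} on failure) and
#'   \code{flags} (character vector).
#' @export
#' @examples
#' fr <- vhh_frameworks()
#' aa <- paste0(fr["FR1"], "GGSAAAG", fr["FR2"], "TTTTTT",
#'              fr["FR3"], "AAAAGGGGSSSS", fr["FR4"])
#' annotate_regions(aa)$regions["CDR3", ]
annotate_regions <- function(aa, scheme = vhh_frameworks(), max_mismatch = 2) {
  stopifnot(all(c("FR1", "FR2", "FR3", "FR4") %in% names(scheme)))
  flags <- character(0)
  starts <- integer(4)
  cursor <- 0L
  for (i in 1:4) {
    fr <- scheme[[paste0("FR", i)]]
    rest <- substr(aa, cursor + 1L, nchar(aa))
    hit <- best_fr_match(fr, rest, max_mismatch)
    if (is.na(hit)) {
      return(list(regions = NULL,
                  flags = c(flags, paste0("missing-FR", i))))
    }
    if (attr(hit, "ambiguous")) {
      return(list(regions = NULL,
                  flags = c(flags, paste0("ambiguous-FR", i))))
    }
    starts[i] <- cursor + hit
    cursor <- starts[i] + nchar(fr)
  }
  fr_len <- nchar(scheme[c("FR1", "FR2", "FR3", "FR4")])
  fr_end <- starts + fr_len
  if (starts[1] != 0L || fr_end[4] != nchar(aa)) {
    return(list(regions = NULL, flags = c(flags, "incomplete-tiling")))
  }
  cdr_start <- fr_end[1:3]
  cdr_end <- starts[2:4]
  if (any(cdr_end <= cdr_start)) {
    return(list(regions = NULL, flags = c(flags, "empty-cdr")))
  }
  m <- cbind(
    start = as.integer(c(starts[1], cdr_start[1], starts[2], cdr_start[2],
                         starts[3], cdr_start[3], starts[4])),
    end = as.integer(c(fr_end[1], cdr_end[1], fr_end[2], cdr_end[2],
                       fr_end[3], cdr_end[3], fr_end[4]))
  )
  rownames(m) <- REGION_NAMES
  list(regions = m, flags = flags)
}

#' Read, orient, translate and annotate reads from FASTQ/FASTA
#'
#' Locates the anchor on either strand, translates the downstream payload,
#' and annotates framework/CDR regions. Identical payloads are processed once
#' and the annotation is broadcast back, so error-free amplicon data is
#' handled at dereplicated cost. Every input read is accounted for:
#' \code{annotated + flagged + anchorless} equals the number of input reads
#' (see the \code{accounting} attribute of the result).
#'
#' @param path FASTQ or FASTA file of nucleotide reads.
#' @param anchor Anchor sequence; defaults to [default_anchor()].
#' @param scheme Framework scheme for [annotate_regions()].
#' @param format \code{"fastq"} or \code{"fasta"}.
#' @param max_mismatch Fuzzy-matching tolerance per framework.
#' @return A tibble with columns \code{read_id}, \code{nt} (payload on the
#'   anchor strand), \code{aa}, \code{cdr1}, \code{cdr2}, \code{cdr3},
#'   \code{annotated} (logical), \code{qc_flags} (list-column), and a
#'   \code{regions} list-column; anchor-less reads are excluded but counted
#'   in \code{attr(, "accounting")}.
#' @export
annotate_reads <- function(path, anchor = default_anchor(),
                           scheme = vhh_frameworks(), format = "fastq",
                           max_mismatch = 2) {
  raw <- Biostrings::readDNAStringSet(path, format = format)
  ids <- names(raw)
  reads <- as.character(raw)
  total <- length(reads)

  # orient and trim to payload
  has_fwd <- regexpr(anchor, reads, fixed = TRUE)
  payload <- rep(NA_character_, total)
  fwd <- has_fwd != -1L
  payload[fwd] <- substr(reads[fwd],
                         as.integer(has_fwd[fwd]) + nchar(anchor),
                         nchar(reads[fwd]))
  if (any(!fwd)) {
    rc <- as.character(Biostrings::reverseComplement(raw[!fwd]))
    has_rev <- regexpr(anchor, rc, fixed = TRUE)
    rev_hit <- has_rev != -1L
    payload[!fwd][rev_hit] <- substr(rc[rev_hit],
                                     as.integer(has_rev[rev_hit]) + nchar(anchor),
                                     nchar(rc[rev_hit]))
  }
  anchorless <- sum(is.na(payload))
  keep <- !is.na(payload)
  ids <- ids[keep]
  payload <- payload[keep]

  uniq <- unique(payload)
  # batch translation of the unique payloads (one vectorized call)
  rem <- nchar(uniq) %% 3L
  trimmed <- substr(uniq, 1L, nchar(uniq) - rem)
  aa_u <- character(length(uniq))
  nonempty <- nchar(trimmed) > 0
  if (any(nonempty)) {
    aa_u[nonempty] <- as.character(
      Biostrings::translate(Biostrings::DNAStringSet(trimmed[nonempty]),
                            if.fuzzy.codon = "X"))
  }
  ambig <- grepl("[^ACGT]", trimmed)
  stop_pos <- regexpr("*", aa_u, fixed = TRUE)
  internal_stop <- stop_pos != -1L & stop_pos < nchar(aa_u)
  ann <- lapply(seq_along(uniq), function(i) {
    tflags <- c(if (rem[i] > 0) "frame-remainder",
                if (ambig[i]) "ambiguous-base",
                if (internal_stop[i]) "internal-stop")
    an <- annotate_regions(aa_u[i], scheme, max_mismatch)
    list(aa = aa_u[i], flags = c(tflags, an$flags), regions = an$regions)
  })
  idx <- match(payload, uniq)

  aa <- vapply(ann, `[[`, character(1), "aa")[idx]
  regions <- lapply(ann, `[[`, "regions")[idx]
  qc <- lapply(ann, `[[`, "flags")[idx]
  annotated <- !vapply(regions, is.null, logical(1))
  get_cdr <- function(name) {
    vapply(seq_along(regions), function(i) {
      r <- regions[[i]]
      if (is.null(r)) return(NA_character_)
      substr(aa[i], r[name, "start"] + 1L, r[name, "end"])
    }, character(1))
  }
  out <- tibble::tibble(
    read_id = ids, nt = payload, aa = aa,
    cdr1 = get_cdr("CDR1"), cdr2 = get_cdr("CDR2"), cdr3 = get_cdr("CDR3"),
    annotated = annotated, qc_flags = qc, regions = regions
  )
  attr(out, "accounting") <- c(total = total, anchorless = anchorless,
                               annotated = sum(annotated),
                               flagged = sum(!annotated))
  out
}

#' Call ELISA hits by fold-over-background
#'
#' A well is a hit when \code{signal / max(background, background_floor)} is
#' at least \code{fold} (the at-least-three-fold-over-background rule; the
#' boundary is inclusive). The floor guards against division blow-up on blank
#' background wells.
#'
#' @param wells Data frame with columns \code{clone_id}, \code{signal},
#'   \code{background} (absorbance, arbitrary units, non-negative).
#' @param fold Fold threshold (> 0), default 3.
#' @param background_floor Minimum background used in the ratio.
#' @return Character vector of hit \code{clone_id}s.
#' @export
#' @examples
#' wells <- data.frame(clone_id = c("a", "b"),
#'                     signal = c(0.90, 0.89), background = 0.30)
#' call_elisa_hits(wells)  # "a"
call_elisa_hits <- function(wells, fold = 3, background_floor = 0.05) {
  stopifnot(fold > 0, background_floor > 0)
  if (any(wells$signal < 0) || any(wells$background < 0)) {
    stop("negative absorbance values")
  }
  ratio <- wells$signal / pmax(wells$background, background_floor)
  wells$clone_id[ratio >= fold]
}

#' Dereplicate sequences into unique variants with counts
#'
#' @param sequences Character vector (typically amino-acid sequences).
#' @return A tibble with columns \code{aa} and \code{count}, ordered by count
#'   descending then sequence lexicographically.
#' @export
#' @examples
#' dereplicate(c("A", "A", "B"))
dereplicate <- function(sequences) {
  if (length(sequences) == 0) {
    return(tibble::tibble(aa = character(0), count = integer(0)))
  }
  tab <- table(sequences)
  out <- tibble::tibble(aa = names(tab), count = as.integer(tab))
  out[order(-out$count, out$aa), ]
}
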