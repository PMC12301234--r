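# Synthetic phage-display campaigns with known ground truth.
#
# A campaign is built from a fixed-framework VHH library whose CDRs are drawn
# from liability-free pools (mirroring a screened synthetic-library design),
# optionally with planted liability motifs and a planted binder motif, then
# panned in silico under a Langmuir selection model.

#' Default VHH framework amino-acid sequences
#'
#' A humanized single-domain framework with a camelid FR2 (the hallmark
#' solubilizing framework-2 of heavy-chain-only antibodies). CDR1/2/3 are the
#' inter-framework gaps.
#'
#' @return Named character vector with elements FR1, FR2, FR3, FR4.
#' @export
vhh_frameworks <- function() {
  c(FR1 = "EVQLVESGGGLVQPGGSLRLSCAAS",
    FR2 = "WFRQAPGKEREFVA",
    FR3 = "RFTISRDNAKNTVYLQMNSLRAEDTAVYYCAA",
    FR4 = "WGQGTLVTVSS")
}

# Does a nucleotide string contain any nucleotide-level registry motif?
#' @keywords internal
nt_has_motif <- function(nt, registry) {
  nuc <- registry[registry$level == "nucleotide", , drop = FALSE]
  for (i in seq_len(nrow(nuc))) {
    if (length(regex_starts(nuc$pattern[i], nt)) > 0) return(TRUE)
  }
  FALSE
}

#' Build a VHH library design
#'
#' Generates liability-free CDR pools over a fixed framework. Each CDR variant
#' is drawn from an alphabet excluding Asn, Asp, Cys and Trp (so random CDRs
#' carry no PTM motifs by construction), back-translated with randomly chosen
#' synonymous codons, and rejected if its nucleotide sequence - in the context
#' of its flanking frameworks - contains any nucleotide-level liability motif.
#' Clones assembled from such pools are therefore liability-free unless a
#' motif is planted explicitly.
#'
#' @param pool_sizes Integer vector of length 3: number of CDR1/2/3 variants.
#' @param cdr_lengths Integer vector of length 3: amino-acid length of each CDR.
#' @param anchor Nucleotide anchor prepended upstream of FR1.
#' @param liability_fraction Proportion of clones that receive exactly one
#'   planted liability motif in [generate_library()].
#' @param seed Integer seed; the design is reproducible byte-for-byte.
#' @param registry Liability registry used for the cleanliness screen.
#' @return An object of class \code{library_design}.
#' @export
#' @examples
#' d <- vhh_library_design(pool_sizes = c(4, 4, 4), seed = 1)
#' lengths(d$cdr_pools_aa)
vhh_library_design <- function(pool_sizes = c(30, 30, 60),
                               cdr_lengths = c(7, 6, 12),
                               anchor = default_anchor(),
                               liability_fraction = 0,
                               seed = 1,
                               registry = liability_registry()) {
  stopifnot(length(pool_sizes) == 3, all(pool_sizes >= 1),
            length(cdr_lengths) == 3, all(cdr_lengths >= 1),
            nchar(anchor) > 0,
            liability_fraction >= 0, liability_fraction <= 1)
  fr_aa <- vhh_frameworks()
  with_seed(seed, {
    fr_nt <- vapply(fr_aa, function(aa) {
      for (try in 1:100) {
        nt <- reverse_translate(aa)
        if (!nt_has_motif(nt, registry)) return(nt)
      }
      stop("could not back-translate a liability-free framework")
    }, character(1))
    if (nt_has_motif(paste0(anchor, fr_nt[["FR1"]]), registry)) {
      stop("anchor/FR1 junction contains a liability motif")
    }
    flank_l <- c(fr_nt[["FR1"]], fr_nt[["FR2"]], fr_nt[["FR3"]])
    flank_r <- c(fr_nt[["FR2"]], fr_nt[["FR3"]], fr_nt[["FR4"]])
    pools_aa <- vector("list", 3)
    pools_nt <- vector("list", 3)
    for (cdr in 1:3) {
      aa_set <- character(0)
      nt_set <- character(0)
      guard <- 0L
      while (length(aa_set) < pool_sizes[cdr]) {
        guard <- guard + 1L
        if (guard > 1000L * pool_sizes[cdr]) {
          stop("CDR pool generation did not converge")
        }
        aa <- paste(sample(AA_CDR_SAFE, cdr_lengths[cdr], replace = TRUE),
                    collapse = "")
        if (aa %in% aa_set) next
        nt <- reverse_translate(aa)
        if (nt_has_motif(paste0(flank_l[cdr], nt, flank_r[cdr]), registry)) next
        aa_set <- c(aa_set, aa)
        nt_set <- c(nt_set, nt)
      }
      pools_aa[[cdr]] <- aa_set
      pools_nt[[cdr]] <- nt_set
    }
    structure(
      list(frameworks_aa = fr_aa, frameworks_nt = fr_nt,
           cdr_pools_aa = pools_aa, cdr_pools_nt = pools_nt,
           cdr_lengths = cdr_lengths, anchor = anchor,
           liability_fraction = liability_fraction,
           registry = registry, seed = seed),
      class = "library_design"
    )
  })
}

# Region coordinate matrix (0-based half-open aa coords) for a design.
#' @keywords internal
design_regions <- function(design) {
  lens <- c(nchar(design$frameworks_aa[["FR1"]]), design$cdr_lengths[1],
            nchar(design$frameworks_aa[["FR2"]]), design$cdr_lengths[2],
            nchar(design$frameworks_aa[["FR3"]]), design$cdr_lengths[3],
            nchar(design$frameworks_aa[["FR4"]]))
  ends <- cumsum(lens)
  starts <- ends - lens
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  rownames(m) <- REGION_NAMES
  m
}

# Liability motifs available for planting. Each entry gives the aa (or nt)
# payload and the registry label expected to be the sole disqualifying
# finding after planting.
#' @keywords internal
PLANT_SET <- list(
  list(label = "deamidation_NG",   level = "protein",    payload = "NGA"),
  list(label = "isomerization_DG", level = "protein",    payload = "DGA"),
  list(label = "nglyc_sequon",     level = "protein",    payload = "NAS"),
  list(label = "unpaired_cys",     level = "protein",    payload = "C"),
  list(label = "SfiI",             level = "nucleotide", payload = "GGCCAAAAAGGCCAA"),
  list(label = "splice_donor",     level = "nucleotide", payload = "GGTAAG")
)

# Disqualifying findings for one assembled clone.
#' @keywords internal
clone_findings <- function(clone, registry,
                           policy = c("PTM", "splice", "restriction")) {
  rep <- scan_liabilities(clone, registry, cdr_only = TRUE)
  rep[rep$category %in% policy, , drop = FALSE]
}

# Plant one liability motif into a clone; returns the modified clone or NULL
# if no clean placement was found.
#' @keywords internal
plant_liability <- function(clone, plant, design, regions) {
  anchor_len <- nchar(design$anchor)
  cdr_rows <- c("CDR1", "CDR2", "CDR3")
  for (try in 1:20) {
    cl <- clone
    if (plant$level == "protein") {
      len <- nchar(plant$payload)
      ok <- cdr_rows[design$cdr_lengths >= len + 2]
      r <- ok[sample.int(length(ok), 1L)]
      s <- regions[r, "start"]; e <- regions[r, "end"]
      width <- e - s
      off <- sample.int(width - len - 1L, 1L)        # interior placement
      aa_start <- s + off                            # 0-based
      substr(cl$aa, aa_start + 1L, aa_start + len) <- plant$payload
      nt_start <- anchor_len + 3L * aa_start
      substr(cl$nt, nt_start + 1L, nt_start + 3L * len) <-
        reverse_translate(plant$payload)
    } else {
      len_nt <- nchar(plant$payload)
      len_aa <- len_nt %/% 3L
      s <- regions["CDR3", "start"]
      aa_start <- s + 3L                             # codon-aligned, interior
      nt_start <- anchor_len + 3L * aa_start
      substr(cl$nt, nt_start + 1L, nt_start + len_nt) <- plant$payload
      aa_new <- as.character(Biostrings::translate(Biostrings::DNAString(
        substr(cl$nt, nt_start + 1L, nt_start + len_nt))))
      substr(cl$aa, aa_start + 1L, aa_start + len_aa) <- aa_new
    }
    f <- clone_findings(cl, design$registry)
    if (nrow(f) > 0 && all(f$label == plant$label)) return(cl)
  }
  NULL
}

#' Generate a combinatorial VHH library with ground truth
#'
#' Assembles \code{n_clones} unique clones by sampling CDR combinations from
#' the design pools (nucleotide layout: anchor + FR1 + CDR1 + FR2 + CDR2 +
#' FR3 + CDR3 + FR4). Approximately \code{design$liability_fraction} of the
#' clones (exactly \code{round(fraction * n_clones)}) receive one planted
#' liability motif inside a CDR; all other clones are liability-free under the
#' design registry, so the planted set is the exact ground truth for
#' [filter_library()].
#'
#' @param design A \code{library_design} from [vhh_library_design()].
#' @param n_clones Number of unique clones (must not exceed the combinatorial
#'   space of the pools).
#' @param seed Integer seed; defaults to the design seed.
#' @return An object of class \code{panning_campaign}: a list with
#'   \code{design}, \code{clones} (tibble with clone_id, nt, aa, per-CDR aa,
#'   regions list-column, aa_offset_nt, kd, is_binder, planted_liability) and
#'   \code{counts} (\code{NULL} until [simulate_panning()]).
#' @export
#' @examples
#' d <- vhh_library_design(pool_sizes = c(3, 3, 3), seed = 7)
#' camp <- generate_library(d, n_clones = 5)
#' camp$clones$aa[1]
generate_library <- function(design, n_clones, seed = design$seed) {
  stopifnot(inherits(design, "library_design"), n_clones >= 1)
  sizes <- lengths(design$cdr_pools_aa)
  if (any(sizes == 0)) stop("empty CDR pool")
  total <- prod(sizes)
  if (n_clones > total) {
    stop("n_clones exceeds the combinatorial space of the CDR pools")
  }
  regions <- design_regions(design)
  anchor_len <- nchar(design$anchor)
  fr_nt <- design$frameworks_nt
  fr_aa <- design$frameworks_aa

  with_seed(seed, {
    idx <- sample.int(total, n_clones)          # unique combinations
    i1 <- (idx - 1L) %% sizes[1] + 1L
    i2 <- ((idx - 1L) %/% sizes[1]) %% sizes[2] + 1L
    i3 <- (idx - 1L) %/% (sizes[1] * sizes[2]) + 1L
    nt <- paste0(design$anchor, fr_nt[["FR1"]], design$cdr_pools_nt[[1]][i1],
                 fr_nt[["FR2"]], design$cdr_pools_nt[[2]][i2],
                 fr_nt[["FR3"]], design$cdr_pools_nt[[3]][i3],
                 fr_nt[["FR4"]])
    aa <- paste0(fr_aa[["FR1"]], design$cdr_pools_aa[[1]][i1],
                 fr_aa[["FR2"]], design$cdr_pools_aa[[2]][i2],
                 fr_aa[["FR3"]], design$cdr_pools_aa[[3]][i3],
                 fr_aa[["FR4"]])
    clone_id <- sprintf("clone%05d", seq_len(n_clones))
    planted <- rep(NA_character_, n_clones)

    n_liab <- round(design$liability_fraction * n_clones)
    if (n_liab > 0) {
      which_liab <- sample.int(n_clones, n_liab)
      plant_idx <- rep_len(seq_along(PLANT_SET), n_liab)
      for (k in seq_len(n_liab)) {
        i <- which_liab[k]
        plant <- PLANT_SET[[plant_idx[k]]]
        cl <- plant_liability(
          list(clone_id = clone_id[i], nt = nt[i], aa = aa[i],
               regions = regions, aa_offset_nt = anchor_len),
          plant, design, regions
        )
        if (is.null(cl)) stop("could not plant liability motif cleanly")
        nt[i] <- cl$nt
        aa[i] <- cl$aa
        planted[i] <- plant$label
      }
    }
    if (anyDuplicated(aa)) stop("duplicate clones after assembly; enlarge pools")

    clones <- tibble::tibble(
      clone_id = clone_id,
      nt = nt,
      aa = aa,
      cdr1 = substr(aa, regions["CDR1", "start"] + 1L, regions["CDR1", "end"]),
      cdr2 = substr(aa, regions["CDR2", "start"] + 1L, regions["CDR2", "end"]),
      cdr3 = substr(aa, regions["CDR3", "start"] + 1L, regions["CDR3", "end"]),
      regions = replicate(n_clones, regions, simplify = FALSE),
      aa_offset_nt = anchor_len,
      kd = NA_real_,
      is_binder = NA,
      planted_liability = planted
    )
    structure(list(design = design, clones = clones,
                   counts = NULL, config = NULL),
              class = "panning_campaign")
  })
}

#' Assign dissociation constants and binder labels
#'
#' Each clone is independently a binder with probability
#' \code{binder_fraction}; its K_D is drawn log-uniformly from the class
#' range. \code{is_binder} is consistent with \code{kd <= binder_cutoff} by
#' the disjoint-range precondition. Optionally a binder motif is planted into
#' the CDR3 of every binder (at a random interior position), giving binder
#' labels a sequence signature that descriptor- and motif-based classifiers
#' can recover - the in-silico analogue of binding being determined by
#' sequence.
#'
#' @param campaign A \code{panning_campaign}.
#' @param binder_fraction Probability that a clone is a binder.
#' @param kd_binder_range,kd_nonbinder_range K_D ranges in molar; the binder
#'   range must lie strictly below the non-binder range and bracket the
#'   cutoff correctly.
#' @param binder_cutoff K_D at or below which a clone is a binder (default
#'   100 nM).
#' @param binder_motif Optional amino-acid motif planted in binder CDR3s.
#' @param seed Integer seed.
#' @return The campaign with \code{kd}, \code{is_binder} (and modified
#'   sequences if \code{binder_motif} is set).
#' @export
assign_affinities <- function(campaign,
                              binder_fraction = 0.1,
                              kd_binder_range = c(1e-10, 1e-8),
                              kd_nonbinder_range = c(1e-6, 1e-4),
                              binder_cutoff = 1e-7,
                              binder_motif = NULL,
                              seed = NULL) {
  stopifnot(inherits(campaign, "panning_campaign"),
            binder_fraction >= 0, binder_fraction <= 1,
            all(kd_binder_range > 0), all(kd_nonbinder_range > 0))
  if (max(kd_binder_range) >= min(kd_nonbinder_range)) {
    stop("binder K_D range must lie strictly below the non-binder range")
  }
  if (max(kd_binder_range) > binder_cutoff ||
      min(kd_nonbinder_range) <= binder_cutoff) {
    stop("binder_cutoff must separate the two K_D ranges")
  }
  cl <- campaign$clones
  n <- nrow(cl)
  regions <- cl$regions[[1]]
  with_seed(seed, {
    is_binder <- stats::runif(n) < binder_fraction
    kd <- ifelse(
      is_binder,
      10^stats::runif(n, log10(kd_binder_range[1]), log10(kd_binder_range[2])),
      10^stats::runif(n, log10(kd_nonbinder_range[1]), log10(kd_nonbinder_range[2]))
    )
    cl$kd <- kd
    cl$is_binder <- is_binder
    if (!is.null(binder_motif) && any(is_binder)) {
      len <- nchar(binder_motif)
      s <- regions["CDR3", "start"]
      width <- regions["CDR3", "end"] - s
      if (width < len + 2) stop("CDR3 too short for the binder motif")
      registry <- campaign$design$registry
      for (i in which(is_binder)) {
        # keep the clone's liability ground truth intact: accept only
        # placements that preserve its disqualifying-finding label set
        expected <- cl$planted_liability[i]
        rec <- list(clone_id = cl$clone_id[i], nt = cl$nt[i], aa = cl$aa[i],
                    regions = regions, aa_offset_nt = cl$aa_offset_nt[i])
        for (off in sample(seq_len(width - len - 1L))) {
          cand <- rec
          aa_start <- s + off
          substr(cand$aa, aa_start + 1L, aa_start + len) <- binder_motif
          nt_start <- cand$aa_offset_nt + 3L * aa_start
          substr(cand$nt, nt_start + 1L, nt_start + 3L * len) <-
            reverse_translate(binder_motif)
          f <- clone_findings(cand, registry)
          ok <- if (is.na(expected)) {
            nrow(f) == 0
          } else {
            nrow(f) > 0 && all(f$label == expected)
          }
          if (ok) {
            cl$aa[i] <- cand$aa
            cl$nt[i] <- cand$nt
            break
          }
        }
        # no admissible placement (e.g. a CDR3-spanning planted site):
        # the binder keeps its label but carries no motif
      }
      cl$cdr3 <- substr(cl$aa, regions["CDR3", "start"] + 1L,
                        regions["CDR3", "end"])
    }
    campaign$clones <- cl
    campaign
  })
}

#' Panning round configuration
#'
#' @param n_rounds Number of selection rounds.
#' @param antigen_conc Molar antigen concentration per round, strictly
#'   decreasing (stringency rises as antigen is reduced).
#' @param wash_retention Per-round non-specific retention probability,
#'   strictly decreasing (stringency rises as washes are added).
#' @param reads_per_round Sequencing depth per round.
#' @param seed Integer seed.
#' @return A \code{panning_config} list.
#' @export
panning_config <- function(n_rounds = 4,
                           antigen_conc = c(100, 50, 25, 10) * 1e-9,
                           wash_retention = 10^seq(-2, -4, length.out = n_rounds),
                           reads_per_round = 50000,
                           seed = 1) {
  stopifnot(length(antigen_conc) == n_rounds,
            length(wash_retention) == n_rounds,
            all(antigen_conc > 0),
            all(diff(antigen_conc) < 0),
            all(wash_retention > 0), all(wash_retention <= 1),
            all(diff(wash_retention) < 0),
            reads_per_round >= 1)
  structure(list(n_rounds = n_rounds, antigen_conc = antigen_conc,
                 wash_retention = wash_retention,
                 reads_per_round = reads_per_round, seed = seed),
            class = "panning_config")
}

#' Simulate one round of affinity selection
#'
#' Each clone's selection weight is
#' \code{count * (C / (C + K_D) + wash_retention)}: Langmuir fractional
#' occupancy at antigen concentration \code{C} plus an additive non-specific
#' wash-survival term. Next-round counts are drawn multinomially with
#' probabilities proportional to the weights.
#'
#' @param counts Integer vector of current clone counts.
#' @param kd Dissociation constants (molar), same length.
#' @param antigen_conc Antigen concentration (molar), positive scalar.
#' @param wash_retention Non-specific retention probability in (0, 1].
#' @param reads_out Total output count.
#' @param seed Optional integer seed.
#' @return Integer vector of next-round counts summing to \code{reads_out}.
#' @export
#' @examples
#' simulate_round(c(100, 100), c(1e-9, 1e-5), 100e-9, 0.001, 1000, seed = 1)
simulate_round <- function(counts, kd, antigen_conc, wash_retention,
                           reads_out, seed = NULL) {
  stopifnot(length(counts) == length(kd), antigen_conc > 0,
            wash_retention > 0, wash_retention <= 1, reads_out >= 1)
  w <- counts * (antigen_conc / (antigen_conc + kd) + wash_retention)
  if (all(w == 0)) stop("degenerate round: all selection weights are zero")
  with_seed(seed, as.vector(stats::rmultinom(1, reads_out, w / sum(w))))
}

#' Simulate a full panning campaign
#'
#' Draws round-0 counts uniformly (library sampling), then applies
#' [simulate_round()] for each configured round. The counts matrix has one
#' column per round (\code{R0} .. \code{Rn}); each column sums to
#' \code{reads_per_round}.
#'
#' @param campaign A campaign with affinities assigned.
#' @param config A [panning_config()].
#' @return The campaign with \code{counts} and \code{config} filled in.
#' @export
simulate_panning <- function(campaign, config = panning_config()) {
  stopifnot(inherits(campaign, "panning_campaign"),
            inherits(config, "panning_config"))
  if (anyNA(campaign$clones$kd)) {
    stop("assign_affinities() must be called before simulate_panning()")
  }
  n <- nrow(campaign$clones)
  with_seed(config$seed, {
    counts <- matrix(0L, nrow = n, ncol = config$n_rounds + 1L,
                     dimnames = list(campaign$clones$clone_id,
                                     paste0("R", 0:config$n_rounds)))
    counts[, 1] <- as.vector(stats::rmultinom(1, config$reads_per_round,
                                              rep(1 / n, n)))
    for (r in seq_len(config$n_rounds)) {
      counts[, r + 1L] <- simulate_round(
        counts[, r], campaign$clones$kd,
        config$antigen_conc[r], config$wash_retention[r],
        config$reads_per_round
      )
    }
    campaign$counts <- counts
    campaign$config <- config
    campaign
  })
}

#' Write simulated reads for one round as FASTQ
#'
#' Emits one read per sampled clone copy with substitution errors at
#' \code{error_rate} per base and a constant Phred+33 quality string. Read
#' identifiers encode the clone of origin (\code{cloneXXXXX:copy}) so
#' downstream stages can be validated against ground truth. When
#' \code{spike_fraction > 0}, additional anchor-less random reads
#' (\code{spike:i}) are appended - a stand-in for sequencing-diversity
#' spike-in material that exercises anchor filtering; at the default of 0 the
#' number of reads equals the round total.
#'
#' @param campaign A campaign with simulated counts.
#' @param round Round index (0 = input library).
#' @param path Output FASTQ path.
#' @param error_rate Per-base substitution probability.
#' @param spike_fraction Fraction (of the round total) of extra anchor-less
#'   reads to append.
#' @param seed Optional integer seed.
#' @return Invisibly, the number of reads written.
#' @export
emit_fastq <- function(campaign, round, path, error_rate = 0.001,
                       spike_fraction = 0, seed = NULL) {
  stopifnot(inherits(campaign, "panning_campaign"), !is.null(campaign$counts))
  col <- paste0("R", round)
  if (!col %in% colnames(campaign$counts)) stop("round not simulated: ", round)
  counts <- campaign$counts[, col]
  keep <- counts > 0
  reads <- rep(campaign$clones$nt[keep], counts[keep])
  ids <- paste0(rep(campaign$clones$clone_id[keep], counts[keep]), ":",
                unlist(lapply(counts[keep], seq_len)))
  with_seed(seed, {
    if (error_rate > 0 && length(reads) > 0) {
      widths <- nchar(reads)
      n_err <- stats::rbinom(length(reads), widths, error_rate)
      bases <- c("A", "C", "G", "T")
      for (i in which(n_err > 0)) {
        pos <- sample.int(widths[i], n_err[i])
        for (p in pos) {
          cur <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
        }
      }
    }
    n_spike <- round(spike_fraction * sum(counts))
    if (n_spike > 0) {
      w <- nchar(campaign$clones$nt[1])
      anchor <- campaign$design$anchor
      spikes <- character(n_spike)
      for (i in seq_len(n_spike)) {
        repeat {
          s <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                     collapse = "")
          if (length(regex_starts(anchor, s)) == 0) break
        }
        spikes[i] <- s
      }
      reads <- c(reads, spikes)
      ids <- c(ids, paste0("spike:", seq_len(n_spike)))
    }
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- ids
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals)
    invisible(length(reads))
  })
}

#' Write campaign ground truth as JSON
#'
#' @param campaign A \code{panning_campaign}.
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_campaign_truth <- function(campaign, path) {
  cl <- campaign$clones
  truth <- list(
    clones = data.frame(clone_id = cl$clone_id, aa = cl$aa, kd = cl$kd,
                        is_binder = cl$is_binder,
                        planted_liability = cl$planted_liability),
    counts = if (!is.null(campaign$counts)) {
      cbind(data.frame(clone_id = rownames(campaign$counts)),
            as.data.frame(campaign$counts))
    }
  )
  jsonlite::write_json(truth, path, dataframe = "columns", na = "null",
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.panning_campaign <- function(x, ...) {
  cat("<panning_campaign>", nrow(x$clones), "clones")
  if (!is.null(x$counts)) {
    cat(";", ncol(x$counts) - 1L, "rounds simulated at depth",
        x$config$reads_per_round)
  }
  cat("\n")
  if (!anyNA(x$clones$is_binder)) {
    cat("  binders:", sum(x$clones$is_binder), "\n")
  }
  n_liab <- sum(!is.na(x$clones$planted_liability))
  if (n_liab > 0) cat("  planted liabilities:", n_liab, "\n")
  invisible(x)
}
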