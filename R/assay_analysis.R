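# Assay analyses: SPR cross-competition epitope binning, hydroxyl-radical
# footprinting protection calls, and tumor growth inhibition.

#' Binarize an SPR competition matrix
#'
#' A ligand/analyte pair is blocked (competitive) when the relative binding
#' response - the analyte response over the immobilized ligand as a fraction
#' of the no-competitor control - falls below \code{threshold}. Missing cells
#' stay \code{NA} and are excluded from similarity comparisons downstream.
#'
#' @param matrix Numeric matrix, rows = immobilized ligands, columns =
#'   injected analytes, values = relative binding response (>= 0).
#' @param threshold Blocking cutoff in (0, 1); default 0.30 of the control
#'   response.
#' @return Logical matrix of the same shape (\code{TRUE} = blocked).
#' @export
#' @examples
#' binarize_competition(rbind(a = c(a = 0.1, b = 0.95)), 0.3)
binarize_competition <- function(matrix, threshold = 0.30) {
  stopifnot(threshold > 0, threshold < 1)
  if (any(matrix < 0, na.rm = TRUE)) stop("responses must be non-negative")
  matrix < threshold
}

# Rows i and j match on their mutually observed entries, up to max_mismatch
# disagreements.
#' @keywords internal
rows_match <- function(a, b, max_mismatch = 0) {
  obs <- !is.na(a) & !is.na(b)
  sum(a[obs] != b[obs]) <= max_mismatch
}

#' Group antibodies into epitope bins
#'
#' Works on the common ligand/analyte antibody set. The blocked matrix is
#' symmetrized by logical OR of the (ligand, analyte) and (analyte, ligand)
#' cells - competition observed in either orientation counts. Antibodies
#' whose symmetrized blocking-pattern rows are identical (or, with
#' \code{max_mismatch > 0}, within that Hamming distance on mutually observed
#' entries) share a bin. Bins are numbered by size descending, ties by the
#' lexicographically smallest member, and the assignment is invariant to
#' row/column permutations of the input.
#'
#' @param blocked Logical blocking matrix from [binarize_competition()].
#' @param max_mismatch Allowed disagreements for near-identical grouping
#'   (default 0 = exact row identity).
#' @return A tibble with columns \code{antibody} and \code{bin}; the number
#'   of bins is in \code{attr(, "n_bins")}.
#' @export
assign_bins <- function(blocked, max_mismatch = 0) {
  common <- intersect(rownames(blocked), colnames(blocked))
  if (length(common) == 0) stop("no common ligand/analyte antibody set")
  b <- blocked[common, common, drop = FALSE]
  sym <- b | t(b)                       # NA when both orientations missing
  n <- length(common)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (rows_match(sym[i, ], sym[j, ], max_mismatch)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(common, root)
  sizes <- lengths(groups)
  first <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-sizes, first)
  out <- do.call(rbind, lapply(seq_along(ord), function(k) {
    tibble::tibble(antibody = sort(groups[[ord[k]]]), bin = k)
  }))
  attr(out, "n_bins") <- length(groups)
  out
}

#' Modification fraction of a peptide
#'
#' Relative XIC peak area of modified versus total (modified + unmodified)
#' peptide signal.
#'
#' @param xic_modified,xic_total Peak areas (arbitrary units);
#'   \code{0 <= xic_modified <= xic_total}, \code{xic_total > 0}.
#' @return Fraction in [0, 1].
#' @export
#' @examples
#' modification_fraction(25, 100)  # 0.25
modification_fraction <- function(xic_modified, xic_total) {
  if (any(xic_total <= 0)) stop("xic_total must be positive")
  if (any(xic_modified < 0) || any(xic_modified > xic_total)) {
    stop("xic_modified must lie in [0, xic_total]")
  }
  xic_modified / xic_total
}

#' Protection/deprotection test for one peptide
#'
#' Compares per-replicate modification fractions between the antibody-bound
#' and unbound states. The percent fold-change is the signed difference over
#' baseline, \code{100 * (mean_bound - mean_unbound) / mean_unbound}
#' (\code{method = "ratio"} gives \code{100 * mean_bound / mean_unbound}
#' instead); significance is a two-sided two-sample Student's t test with
#' pooled (equal) variance. The call is \code{"protected"} for a significant
#' decrease in modification upon binding, \code{"deprotected"} for a
#' significant increase, otherwise \code{"unchanged"}.
#'
#' @param bound,unbound Numeric vectors of replicate modification fractions
#'   (>= 2 replicates each).
#' @param alpha Significance level.
#' @param method Percent fold-change convention (see above).
#' @return A one-row tibble: \code{mean_bound}, \code{mean_unbound},
#'   \code{log2_fc}, \code{percent_fc}, \code{t}, \code{df}, \code{p},
#'   \code{call}.
#' @export
#' @examples
#' footprint_test(c(0.10, 0.11, 0.09, 0.10), c(0.20, 0.21, 0.19, 0.20))
footprint_test <- function(bound, unbound, alpha = 0.05,
                           method = c("difference", "ratio")) {
  method <- match.arg(method)
  stopifnot(length(bound) >= 2, length(unbound) >= 2)
  mb <- mean(bound)
  mu <- mean(unbound)
  if (mu == 0) stop("undefined fold-change: unbound mean is zero")
  pct <- if (method == "difference") 100 * (mb - mu) / mu else 100 * mb / mu
  tt <- stats::t.test(bound, unbound, var.equal = TRUE)
  delta <- mb - mu
  call <- if (tt$p.value < alpha && delta < 0) {
    "protected"
  } else if (tt$p.value < alpha && delta > 0) {
    "deprotected"
  } else {
    "unchanged"
  }
  tibble::tibble(
    mean_bound = mb, mean_unbound = mu,
    log2_fc = log2(mb / mu), percent_fc = pct,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, call = call
  )
}

#' Footprinting analysis over a peptide table
#'
#' Applies [footprint_test()] per peptide to a long-format replicate table.
#' No multiple-testing correction is applied by default;
#' \code{p_adjust = "BH"} switches the calls to Benjamini-Hochberg adjusted
#' p values.
#'
#' @param peptides Data frame with columns \code{peptide_id}, \code{state}
#'   (\code{"bound"}/\code{"unbound"}), \code{replicate},
#'   \code{xic_modified}, \code{xic_total}.
#' @param alpha Significance level.
#' @param p_adjust \code{"none"} or \code{"BH"}.
#' @param method Passed to [footprint_test()].
#' @return A tibble with one row per peptide.
#' @export
footprint_table <- function(peptides, alpha = 0.05,
                            p_adjust = c("none", "BH"),
                            method = "difference") {
  p_adjust <- match.arg(p_adjust)
  frac <- modification_fraction(peptides$xic_modified, peptides$xic_total)
  ids <- unique(peptides$peptide_id)
  rows <- lapply(ids, function(id) {
    sel <- peptides$peptide_id == id
    res <- footprint_test(frac[sel & peptides$state == "bound"],
                          frac[sel & peptides$state == "unbound"],
                          alpha = alpha, method = method)
    cbind(tibble::tibble(peptide_id = id), res)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  if (p_adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    delta <- out$mean_bound - out$mean_unbound
    out$call <- ifelse(out$p_adj < alpha & delta < 0, "protected",
                       ifelse(out$p_adj < alpha & delta > 0, "deprotected",
                              "unchanged"))
  }
  out
}

#' Tumor growth inhibition
#'
#' \code{TGI (\%) = (1 - (Tt - T0) / (Ct - C0)) * 100}, comparing the mean
#' tumor-volume gain of the treated group with that of the control group.
#'
#' @param t0,tt Treated-group mean tumor volume at baseline and time t (mm3).
#' @param c0,ct Control-group means at the same times (mm3); \code{ct}
#'   must differ from \code{c0}.
#' @return TGI in percent.
#' @export
#' @examples
#' compute_tgi(100, 550, 100, 1000)  # 50
compute_tgi <- function(t0, tt, c0, ct) {
  stopifnot(all(c(t0, tt, c0, ct) > 0))
  if (any(ct == c0)) stop("TGI undefined: control group did not change")
  (1 - (tt - t0) / (ct - c0)) * 100
}
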