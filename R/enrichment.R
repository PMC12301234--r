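# Clonotype assignment, per-round frequencies, round-to-round enrichment, and
# the enrichment-workflow candidate selection.

#' Assign clonotypes by exact CDR3 identity
#'
#' Partitions variants into clonotypes keyed on the exact CDR3 amino-acid
#' sequence (a single fixed framework leaves no V-gene component to the key).
#' Clonotype identifiers are deterministic: ordered by total count descending,
#' ties broken by CDR3 lexicographically.
#'
#' @param variants A tibble with columns \code{aa}, \code{cdr3}, and one or
#'   more count columns (e.g. \code{count_r3}, \code{count_r4}). Rows with
#'   \code{NA} CDR3 are excluded (their number is reported in
#'   \code{attr(, "n_excluded")}).
#' @param count_cols Names of the count columns used for the total-count
#'   ordering; defaults to every column starting with \code{"count"}.
#' @return A list with \code{clonotypes} (tibble: \code{clonotype_id},
#'   \code{cdr3}, \code{n_variants}, summed count columns) and
#'   \code{variants} (the input rows with a \code{clonotype_id} column).
#' @export
assign_clonotypes <- function(variants, count_cols = NULL) {
  stopifnot("cdr3" %in% names(variants))
  if (is.null(count_cols)) {
    count_cols <- grep("^count", names(variants), value = TRUE)
  }
  stopifnot(length(count_cols) >= 1)
  n_excluded <- sum(is.na(variants$cdr3))
  if (n_excluded > 0) {
    warning(n_excluded, " variant(s) lacking CDR3 excluded from clonotyping")
    variants <- variants[!is.na(variants$cdr3), , drop = FALSE]
  }
  totals <- rowsum(rowSums(as.matrix(variants[, count_cols, drop = FALSE])),
                   variants$cdr3)
  keys <- rownames(totals)
  ord <- order(-totals[, 1], keys)
  keys <- keys[ord]
  ids <- sprintf("CT%05d", seq_along(keys))
  names(ids) <- keys
  variants$clonotype_id <- unname(ids[variants$cdr3])

  sums <- lapply(count_cols, function(cc) {
    s <- rowsum(variants[[cc]], variants$cdr3)
    s[keys, 1]
  })
  names(sums) <- count_cols
  clonotypes <- tibble::tibble(
    clonotype_id = ids,
    cdr3 = keys,
    n_variants = as.integer(table(variants$cdr3)[keys]),
    !!!sums
  )
  out <- list(clonotypes = clonotypes, variants = variants)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-round relative frequencies
#'
#' @param counts Numeric matrix or data frame of counts (rows = clones or
#'   clonotypes, columns = rounds). Every column must have a positive total.
#' @return Matrix of frequencies; each column sums to 1.
#' @export
#' @examples
#' compute_frequencies(cbind(r = c(3, 1)))
compute_frequencies <- function(counts) {
  m <- as.matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) stop("empty round: zero total count")
  sweep(m, 2, totals, "/")
}

#' Round-to-round enrichment score
#'
#' The log2 ratio of pseudocount-regularized frequencies,
#' \code{log2((f4 + p4) / (f3 + p3))}, with per-round pseudocount frequencies
#' \code{p_r = pseudocount / total_r}. The score is finite for clonotypes
#' absent from one round and antisymmetric under swapping rounds (with the
#' pseudocount pair swapped accordingly).
#'
#' @param freq_r3,freq_r4 Frequencies in the earlier and later round.
#' @param pseudocount Pseudocount in read units (> 0).
#' @param total_r3,total_r4 Round totals used to convert the pseudocount to
#'   the frequency scale.
#' @return Numeric vector of enrichment scores.
#' @export
#' @examples
#' compute_enrichment(0.01, 0.10, pseudocount = 1e-6, 1, 1)  # ~ log2(10)
compute_enrichment <- function(freq_r3, freq_r4, pseudocount = 0.5,
                               total_r3 = 1, total_r4 = total_r3) {
  stopifnot(pseudocount > 0, total_r3 > 0, total_r4 > 0)
  p3 <- pseudocount / total_r3
  p4 <- pseudocount / total_r4
  log2((freq_r4 + p4) / (freq_r3 + p3))
}

#' Build a clonotype enrichment table between two rounds
#'
#' @param clonotypes Clonotype tibble from [assign_clonotypes()] containing
#'   the two count columns.
#' @param r3_col,r4_col Names of the earlier/later round count columns.
#' @param pseudocount Pseudocount in read units.
#' @return A tibble with \code{clonotype_id}, \code{cdr3}, \code{freq_r3},
#'   \code{freq_r4}, \code{enrichment}, sorted by enrichment descending
#'   (ties: higher \code{freq_r4}, then CDR3 lexicographic).
#' @export
enrichment_table <- function(clonotypes, r3_col = "count_r3",
                             r4_col = "count_r4", pseudocount = 0.5) {
  t3 <- sum(clonotypes[[r3_col]])
  t4 <- sum(clonotypes[[r4_col]])
  if (t3 <= 0 || t4 <= 0) stop("empty round: zero total count")
  f3 <- clonotypes[[r3_col]] / t3
  f4 <- clonotypes[[r4_col]] / t4
  out <- tibble::tibble(
    clonotype_id = clonotypes$clonotype_id,
    cdr3 = clonotypes$cdr3,
    freq_r3 = f3,
    freq_r4 = f4,
    enrichment = compute_enrichment(f3, f4, pseudocount, t3, t4)
  )
  out[order(-out$enrichment, -out$freq_r4, out$cdr3), ]
}

#' Select candidates from top enriched clonotypes
#'
#' Takes the \code{n_top_clonotypes} highest-scoring clonotypes (ties broken
#' by higher round-4 frequency, then CDR3 lexicographically) and, within each,
#' up to \code{variants_per_clonotype} variants by round-4 count descending
#' (ties lexicographic on the full sequence). The result is invariant to the
#' input row order.
#'
#' @param table Enrichment table from [enrichment_table()].
#' @param variants Variant tibble with \code{clonotype_id}, \code{aa} and the
#'   round-4 count column.
#' @param n_top_clonotypes Number of clonotypes to take.
#' @param variants_per_clonotype Variants kept per clonotype (default 3, the
#'   top-three-most-abundant rule).
#' @param r4_col Round-4 count column in \code{variants}.
#' @return A tibble with \code{aa}, \code{clonotype_id}, \code{count_r4},
#'   \code{rank_in_clonotype}.
#' @export
select_enrichment_candidates <- function(table, variants,
                                         n_top_clonotypes = 20,
                                         variants_per_clonotype = 3,
                                         r4_col = "count_r4") {
  stopifnot(n_top_clonotypes >= 1)
  ordered <- table[order(-table$enrichment, -table$freq_r4, table$cdr3), ]
  top <- utils::head(ordered$clonotype_id, n_top_clonotypes)
  out <- list()
  for (ct in top) {
    v <- variants[variants$clonotype_id == ct, , drop = FALSE]
    v <- v[order(-v[[r4_col]], v$aa), , drop = FALSE]
    v <- utils::head(v, variants_per_clonotype)
    if (nrow(v) > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        aa = v$aa, clonotype_id = ct, count_r4 = v[[r4_col]],
        rank_in_clonotype = seq_len(nrow(v))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(aa = character(0), clonotype_id = character(0),
                          count_r4 = numeric(0), rank_in_clonotype = integer(0)))
  }
  do.call(rbind, out)
}

#' Aggregate candidate lists from multiple workflows
#'
#' Union by exact amino-acid identity with provenance labels retained per
#' candidate. Output order is deterministic (sequence lexicographic).
#'
#' @param ... Named character vectors (or tibbles with an \code{aa} column)
#'   of candidate sequences; the argument names are the provenance labels.
#' @return A tibble with \code{aa} and a \code{provenance} list-column.
#' @export
#' @examples
#' aggregate_candidates(enrichment = c("A", "B"), knn = c("B", "C"))
aggregate_candidates <- function(...) {
  lists <- list(...)
  if (is.null(names(lists)) || any(names(lists) == "")) {
    stop("all candidate lists must be named (provenance labels)")
  }
  seqs <- lapply(lists, function(x) {
    if (is.data.frame(x)) unique(x$aa) else unique(as.character(x))
  })
  all_aa <- sort(unique(unlist(seqs)))
  prov <- lapply(all_aa, function(a) {
    names(seqs)[vapply(seqs, function(s) a %in% s, logical(1))]
  })
  tibble::tibble(aa = all_aa, provenance = prov)
}
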