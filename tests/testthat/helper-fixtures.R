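# Shared fixtures, all built in code.

# Small design with enough combinatorial space for a few hundred clones.
tiny_design <- function(seed = 1, liability_fraction = 0,
                        pool_sizes = c(8, 8, 12)) {
  vhh_library_design(pool_sizes = pool_sizes, seed = seed,
                     liability_fraction = liability_fraction)
}

# A fully simulated small campaign.
tiny_campaign <- function(seed = 1, n_clones = 150, reads = 4000,
                          binder_motif = NULL, liability_fraction = 0) {
  d <- vhh_library_design(pool_sizes = c(15, 15, 25), seed = seed,
                          liability_fraction = liability_fraction)
  camp <- generate_library(d, n_clones, seed = seed + 1)
  camp <- assign_affinities(camp, binder_fraction = 0.1,
                            binder_motif = binder_motif, seed = seed + 2)
  simulate_panning(camp, panning_config(reads_per_round = reads,
                                        seed = seed + 3))
}

# Hand-built annotated record for the liability scanner.
make_record <- function(aa, cdr_bounds, nt = NA_character_,
                        clone_id = "rec1") {
  # cdr_bounds: list of c(start, end) for CDR1..CDR3 (0-based half-open);
  # frameworks fill the gaps.
  stopifnot(length(cdr_bounds) == 3)
  b <- do.call(rbind, cdr_bounds)
  m <- rbind(
    FR1 = c(0, b[1, 1]),
    CDR1 = b[1, ],
    FR2 = c(b[1, 2], b[2, 1]),
    CDR2 = b[2, ],
    FR3 = c(b[2, 2], b[3, 1]),
    CDR3 = b[3, ],
    FR4 = c(b[3, 2], nchar(aa))
  )
  colnames(m) <- c("start", "end")
  list(clone_id = clone_id, nt = nt, aa = aa, regions = m,
       aa_offset_nt = 0L)
}

# Motif-separable training set: positives carry a planted 4-mer at a random
# position, negatives do not (background alphabet excludes W).
motif_training_set <- function(n_pos, n_neg, len = 30, motif = "WGWG",
                               seed = 1) {
  bg <- setdiff(c("A", "E", "F", "G", "H", "I", "K", "L", "M", "P", "Q",
                  "R", "S", "T", "V", "Y"), strsplit(motif, "")[[1]][1])
  withr::with_seed(seed, {
    rand_seq <- function() paste(sample(bg, len, replace = TRUE), collapse = "")
    pos <- vapply(seq_len(n_pos), function(i) {
      s <- rand_seq()
      at <- sample.int(len - nchar(motif) + 1L, 1L)
      substr(s, at, at + nchar(motif) - 1L) <- motif
      s
    }, character(1))
    neg <- vapply(seq_len(n_neg), function(i) rand_seq(), character(1))
    tibble::tibble(aa = c(pos, neg),
                   label = rep(c("binder", "nonbinder"), c(n_pos, n_neg)),
                   provenance = "spr")
  })
}

# Competition matrix from bin memberships: members of the same bin block
# each other (and themselves); cross-bin pairs do not compete.
competition_from_bins <- function(bins, blocked_response = 0.05,
                                  open_response = 0.95) {
  abs <- unlist(bins)
  m <- matrix(open_response, length(abs), length(abs),
              dimnames = list(abs, abs))
  for (b in bins) m[b, b] <- blocked_response
  m
}
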