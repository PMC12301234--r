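# Small internal helpers shared across modules.

# Deterministic per-stage seed derived from a master seed and a stage name.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
#' @keywords internal
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) + h * 100003) %% 2147483647)
}

# Run code under a temporary RNG state so library functions with a `seed`
# argument do not clobber the caller's stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Reverse-translate an amino-acid string into nucleotides, sampling synonymous
# codons from CODON_CHOICES under the current RNG state.
#' @keywords internal
reverse_translate <- function(aa) {
  letters <- strsplit(aa, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(CODON_CHOICES))
  if (length(bad) > 0) {
    stop("cannot back-translate residue(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(vapply(letters, function(a) {
    ch <- CODON_CHOICES[[a]]
    if (length(ch) == 1L) ch else ch[sample.int(length(ch), 1L)]
  }, character(1)), collapse = "")
}

# All match start positions (1-based) of a regex, including overlapping ones.
#' @keywords internal
regex_starts <- function(pattern, x, match_length_pattern = NULL) {
  m <- gregexpr(paste0("(?=", pattern, ")"), x, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
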