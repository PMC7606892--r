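# Internal helpers shared across modules.

# Derive an independent 31-bit substream seed from a master seed and a stage
# label, so adding a stage never perturbs the random stream of earlier stages.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stage) == 1)
  codes <- utf8ToInt(as.character(stage))
  h <- as.double(seed) %% 2147483647
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Reverse complement of a plain character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGT characters (first offender: %s)",
                  what, x[which(bad)[1]]))
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
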