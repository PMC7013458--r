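#' Round half away from zero
#'
#' Rounding convention used for all reported metrics: ties are rounded away
#' from zero (so 1.55 -> 1.6 and 69.5 -> 70), unlike base [round()] which
#' rounds half to even.
#'
#' @param x numeric vector
#' @param digits number of decimal places (default 0)
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a per-stage child seed from a global seed
#'
#' Each simulation stage draws from its own seeded RNG stream so stages are
#' independently reproducible: the child seed is a fixed deterministic
#' function of the global seed and the stage label.
#'
#' @param seed global integer seed
#' @param stage character stage label (e.g. "genome", "methylome")
#' @return integer seed in \[0, 2^31 - 2\]
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  stopifnot(is.character(stage), length(stage) == 1L)
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 2000000011 * 31 + 97 * h) %% 2147483647)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rev_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
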