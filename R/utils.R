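## Small internal helpers shared across modules.

frobNorm <- function(M) sqrt(sum(M * M))

clip01 <- function(M) {
  M[M < 0] <- 0
  M[M > 1] <- 1
  M
}

## Symmetry measured as the largest absolute entry of M - t(M).
maxAsymmetry <- function(M) max(abs(M - t(M)))

## All messages go through here so verbosity is controlled in one place
## (options(bnnrmda.verbose = FALSE) silences pipeline narration).
mdaLog <- function(fmt, ...) {
  if (isTRUE(getOption("bnnrmda.verbose", TRUE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

## Deterministic per-repeat seed derived from a master seed; kept well below
## .Machine$integer.max so set.seed() always accepts it.
deriveSeed <- function(masterSeed, index) {
  as.integer((as.numeric(masterSeed) %% 1000003L + 104729 * index) %% 2147483629)
}

stopIfNotScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
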