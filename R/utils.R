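# internal helpers shared across modules

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that generators take explicit
#' seeds without leaking into the caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) without overflow; -Inf-safe
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# strand-ambiguous allele pair (A/T or C/G)
isAmbiguousPair <- function(ref, alt) {
  p <- paste0(toupper(ref), toupper(alt))
  p %in% c("AT", "TA", "CG", "GC")
}

# column call rate (fraction observed)
callRate <- function(x) colMeans(!is.na(x))

stopifnotScalarProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a probability in [0, 1]", name))
  }
}
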