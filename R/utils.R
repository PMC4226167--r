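## Internal helpers shared across modules.

#' @importFrom methods new validObject is slot show
#' @importFrom stats runif rnorm dpois ppois qpois
#' @importFrom utils read.csv write.csv
#' @importClassesFrom Matrix Matrix
#' @importMethodsFrom Matrix t
NULL

# Deterministic 31-bit mix for deriving independent child seeds from a run
# seed plus stage/entity keys. Keeps derived seeds < 2^31.
childSeed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) {
    h <- (h * 69069 + as.numeric(k) + 13) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Half-up rounding (0.5 -> 1), the convention used when converting soma
# densities to integer counts.
roundHalfUp <- function(x) floor(x + 0.5)

vecNorm <- function(v) sqrt(sum(v * v))

stopifnot3 <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)))
    stop(what, " must be a finite numeric vector of length 3", call. = FALSE)
  invisible(as.numeric(p))
}

asPointMatrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    p
  } else {
    matrix(stopifnot3(p), nrow = 1L)
  }
}
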