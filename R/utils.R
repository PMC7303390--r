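#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats cor cov pt qt sd rnorm runif var p.adjust setNames
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `expr` under a local Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards. No global RNG state leaks.
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

stopIfNot <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

isCount <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}

isProb <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x < 1
}

# Symmetry check used by readers and constructors.
maxAsymmetry <- function(m) {
  if (nrow(m) != ncol(m)) return(Inf)
  max(abs(m - t(m)))
}

fmtNum <- function(x) sprintf("%.17g", x)
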