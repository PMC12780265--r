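#' Derive a stage seed from the run seed
#'
#' All randomness in the package flows from a single integer seed. Each
#' stochastic stage draws its own seed through this rule so that stages are
#' reproducible independently of how many random numbers earlier stages
#' consumed.
#'
#' @param seed integer run seed.
#' @param offset small nonnegative integer identifying the stage (each
#'   caller uses a fixed, documented offset).
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(offset), length(offset) == 1L, offset >= 0)
  # affine hash in double precision, reduced mod a Mersenne prime
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% 97561) * 21001 + as.numeric(offset) * 7919 + 1
  as.integer(s %% (m - 1) + 1)
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
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
  expr
}

stop_prostir <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_prob_vector <- function(p, name = "probabilities", tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_prostir("%s must be finite and nonnegative", name)
  }
  if (abs(sum(p) - 1) > tol) {
    stop_prostir("%s must sum to 1 (got %.6f)", name, sum(p))
  }
  invisible(p)
}

check_binary <- function(y, name = "labels") {
  if (length(y) == 0L || any(!y %in% c(0, 1))) {
    stop_prostir("%s must be a nonempty vector of 0/1 values", name)
  }
  if (length(unique(y)) < 2L) {
    stop_prostir("%s must contain both outcome classes", name)
  }
  invisible(as.integer(y))
}

# keep probabilities strictly inside (0, 1)
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# softmax with max-shift for numerical stability
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
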