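# Internal numeric / RNG helpers.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Evaluate expr under a private RNG stream without disturbing the caller's
# .Random.seed. Returns the value of expr.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# A resumable private RNG stream: rng(function() ...) runs the drawing
# function under the stream's state and saves the advanced state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- with_seed(seed, get(".Random.seed", globalenv()))
  function(f) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
}

# Kaiming-style uniform fan-in initialization: U(-b, b), b = sqrt(6 / fan_in).
init_mat <- function(nr, nc, rng, fan_in = nc) {
  b <- sqrt(6 / fan_in)
  rng(function() matrix(stats::runif(nr * nc, -b, b), nr, nc))
}

# Derive a well-spread 31-bit child seed from (seed, index) without RNG use.
child_seed <- function(seed, index) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(x %% 2147483647) + 1L
}

# Add a row-vector bias to every row of a matrix.
addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

# Multiply each column c of M by v[c] (row-vector broadcast).
scale_cols <- function(M, v) M * matrix(v, nrow(M), length(v), byrow = TRUE)

check_finite <- function(x, layer) {
  if (!all(is.finite(x)))
    stop("non-finite values produced in layer: ", layer)
  invisible(x)
}
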