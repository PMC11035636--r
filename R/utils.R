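# internal helpers shared across modules

# mass of neutral NH3 (monoisotopic); separates [M+H]+ and [M+NH4]+ ions
NH3_MASS <- 17.02655

`%||%` <- rlang::`%||%`

abort_stage <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "lipidnet_error"), ...)
}

stop_validation <- function(message, ...) {
  abort_stage(message, class = "lipidnet_validation_error", ...)
}

# x: numeric matrix, columns closed to sum 1; all-zero columns left at zero
close_columns <- function(x) {
  totals <- colSums(x)
  nz <- totals > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, totals[nz], "/")
  x
}

# Shannon term with the 0 * log2(0) := 0 convention
xlog2x <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}

# A seeded random stream isolated from the caller's RNG state. Draws advance
# an internal copy of .Random.seed and restore the caller's on exit, so the
# same seed gives bit-identical output no matter what ran before.
new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  prev <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = genv)
  if (is.null(prev)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", prev, envir = genv)
  }
  draw <- function(fn) {
    outer_state <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      get(".Random.seed", envir = genv)
    } else {
      NULL
    }
    assign(".Random.seed", env$state, envir = genv)
    on.exit({
      env$state <- get(".Random.seed", envir = genv)
      if (is.null(outer_state)) {
        rm(".Random.seed", envir = genv)
      } else {
        assign(".Random.seed", outer_state, envir = genv)
      }
    })
    fn()
  }
  list(
    sample_int = function(n, size, replace = FALSE) {
      draw(function() sample.int(n, size, replace = replace))
    },
    runif = function(n, min = 0, max = 1) {
      draw(function() stats::runif(n, min, max))
    },
    rnorm = function(n, mean = 0, sd = 1) {
      draw(function() stats::rnorm(n, mean, sd))
    },
    rlnorm = function(n, meanlog = 0, sdlog = 1) {
      draw(function() stats::rlnorm(n, meanlog, sdlog))
    }
  )
}
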