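#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor plogis predict rnbinom rnorm runif setNames var
#' @importFrom utils read.csv write.csv head
NULL

# Run `code` under `seed`, restoring the caller's RNG state afterwards.
# All randomness in the package flows through this so that fits are
# reproducible without clobbering the user's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
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
  set.seed(as.integer(seed))
  force(code)
}

stop_cv <- function(...) stop(..., call. = FALSE)

# Label reserved for rejected cells; reference labels may not use it.
UNASSIGNED <- "unassigned"
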