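#' plaquebox: weak-label amyloid pathology detection and scoring
#'
#' See the package README and the methods vignette for the scientific
#' background and a worked example.
#'
#' @keywords internal
"_PACKAGE"

# Run expr under a local RNG seed, restoring any pre-existing global
# .Random.seed afterwards. All stochastic generators in the package route
# their randomness through this so no call mutates global random state.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot() with a formatted message
assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
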