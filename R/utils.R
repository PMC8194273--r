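#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the RNG seeded at \code{seed}, restoring the
#' caller's RNG state afterwards so seeded helpers do not perturb the
#' global random stream. A \code{NULL} seed evaluates the code as-is.
#'
#' @param seed integer seed or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# derive a reproducible 32-bit sub-seed from a base seed and a stream index
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 10007 + stream * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
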