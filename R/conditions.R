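#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., petfloc_no_exponential_phase = ...) instead of grepping
# messages.
stop_petfloc <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("petfloc_", class), "petfloc_error")))
}

warn_petfloc <- function(class, msg) {
  warning(warningCondition(msg, class = c(paste0("petfloc_", class), "petfloc_warning")))
}

# Deterministic RNG scope: runs `expr` under `seed` (when non-NULL) and
# restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round-half-up (base round() is round-half-even; printed copy-number
# tables use conventional rounding)
round_half_up <- function(x) floor(x + 0.5)
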