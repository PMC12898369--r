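# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes programmatically.
stop_canalregen <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "canalregen_error", "error"),
                      call = call))
}

stop_format   <- function(msg) stop_canalregen(msg, "canalregen_format_error")
stop_metadata <- function(msg) stop_canalregen(msg, "canalregen_metadata_error")
stop_io       <- function(msg) stop_canalregen(msg, "canalregen_io_error")
stop_geometry <- function(msg) stop_canalregen(msg, "canalregen_geometry_error")
stop_spec     <- function(msg) stop_canalregen(msg, "canalregen_spec_error")
stop_input    <- function(msg) stop_canalregen(msg, "canalregen_input_error")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Euclidean norm / distance for length-3 vectors.
vnorm <- function(x) sqrt(sum(x * x))

vdist <- function(a, b) vnorm(a - b)

as_point3 <- function(x, what = "point") {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 3L || anyNA(x) || any(!is.finite(x)))
    stop_input(sprintf("%s must be a finite numeric vector of length 3", what))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
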