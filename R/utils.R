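# internal helpers: classed conditions and seeded evaluation

fog_error <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "fog_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_schema <- function(msg) fog_error("fog_schema_error", msg)
stop_format <- function(msg) fog_error("fog_format_error", msg)
stop_alignment <- function(msg) fog_error("fog_alignment_error", msg)
stop_undefined_metric <- function(msg) fog_error("fog_undefined_metric", msg)
stop_validation <- function(msg) fog_error("fog_validation_error", msg)
stop_argument <- function(msg) fog_error("fog_argument_error", msg)
stop_insufficient <- function(msg) fog_error("fog_insufficient_data_error", msg)

# run expr under a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# derive a reproducible 31-bit substream seed from a base seed and string keys
substream_seed <- function(seed, ...) {
  keys <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(keys)) h <- (h * 31 + code) %% 1982627
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binaryish <- function(x) {
  is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))
}
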