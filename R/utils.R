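# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream; seed = NULL leaves the stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# derive a stream-specific child seed from a master seed, staying inside
# 32-bit integer range
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sf <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "seedfate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_sf(sprintf("%s must lie in [0, 1]", what), "seedfate_validation_error")
  }
  invisible(x)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_sf(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")),
            "seedfate_schema_error")
  }
  invisible(df)
}
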