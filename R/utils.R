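#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a stream-specific 31-bit sub-seed so that independent generator calls
# driven by one master seed do not share RNG streams.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (tok in c(...)) {
    for (ch in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_invalid("`%s` must be a %s finite scalar, got %s",
                 name, if (strict) "positive" else "non-negative",
                 paste(format(x), collapse = ", "))
  }
  invisible(x)
}

# FNV-1a over the serialized object; used for content-addressed file names.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
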