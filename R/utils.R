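# internal helpers shared across modules

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so generation is a pure function of (spec, seed).
with_local_seed <- function(seed, expr) {
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
  force(expr)
}

# Canonical (sorted-key, fixed-precision) JSON used for config hashing.
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, sort_keys = TRUE,
                   null = "null")
}

# md5 of an in-memory string via a temp file (tools::md5sum is file-based)
md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

stopf <- function(fmt, ..., class = "conceptkg_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
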