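# Shared helpers: quantile conventions, local RNG scoping, file hashing.

# All medians/quartiles in the package use linearly interpolated order
# statistics (stats::quantile type 7), for random-error maps and for
# across-joint MDE summaries alike.
.QUANTILE_TYPE <- 7L

five_number <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to summarize", call. = FALSE)
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = .QUANTILE_TYPE)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Stable hash of a config for provenance: canonical JSON -> md5.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
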