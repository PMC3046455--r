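# Internal helpers: substream seeding, assertions, formatting.

#' Derive a reproducible substream seed from a master seed and a label path
#'
#' A polynomial rolling hash (base 31, modulus 2^31 - 1) over the master seed
#' and the label path. All randomness in the package flows through substreams
#' so that, e.g., adding a study to a simulation never perturbs the draws of
#' existing studies, and bootstrap replicate `b` is reproducible in isolation.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
#' @noRd
substream_seed <- function(master, ...) {
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(key)
  m <- 2147483647
  h <- 2166136261 %% m
  for (b in bytes) {
    # 31 * h + b stays well below 2^53, so the arithmetic is exact
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# run expr under a local RNG state seeded by a substream, restoring the
# caller's state afterwards
with_substream <- function(master, ..., expr) {
  seed <- substream_seed(master, ...)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_gxe <- function(class, ..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c(class, "gxe_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")
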