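# Internal helpers shared across modules.

#' Derive a reproducible child seed from a top-level seed
#'
#' Composite analyses (simulate a tree, overlay marks, apply dropout, ...)
#' each consume their own random stream. Deriving per-component seeds from a
#' single top-level seed keeps whole pipelines bit-reproducible while letting
#' components be re-run in isolation.
#'
#' @param seed Integer top-level seed.
#' @param label Character tag naming the component ("tree", "marks", ...).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h + 1)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(code, "edittrace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
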