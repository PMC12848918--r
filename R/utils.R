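# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the ambient RNG stream" (no reseeding).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a master seed, a stream
# label and an index, so pipeline stages draw from independent streams.
derive_seed <- function(seed, stream, index = 0L) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 1009 + index * 7919) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fs <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fluxseason_error")))
}

assert_scalar_num <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_fs(sprintf("`%s` must be a finite numeric scalar", name),
             "fs_argument_error")
  invisible(x)
}

significance_star <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}
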