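# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators behave as pure
# functions of their arguments.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_ovtr <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ovtr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# FNV-1a 32-bit hash of a character scalar; used for config provenance.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %% 4294967296) - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so intermediates stay exactly representable in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
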