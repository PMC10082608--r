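#' @useDynLib grnsemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rnorm runif sd var
#' @importFrom utils head
NULL

# Deterministic 31-bit hash of a master seed plus arbitrary string tags.
# Used to derive independent, order-free RNG streams (per target gene,
# per subsample iteration) from a single user-facing seed.
hash_seed <- function(master, ...) {
  parts <- paste(c(as.character(master),
                   vapply(list(...), as.character, character(1))),
                 collapse = "\x1f")
  h <- 0
  for (cp in utf8ToInt(parts)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_rng <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Minimal leveled logger; level set via options(grnsemble.log_level = ...).
log_levels <- c(debug = 10L, info = 20L, warning = 30L, quiet = 90L)

log_msg <- function(level, ...) {
  threshold <- getOption("grnsemble.log_level", "warning")
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
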