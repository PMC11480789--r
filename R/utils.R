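# Internal helpers shared across modules.

# Symbol-shaped token: a letter followed by 1-9 letters/digits/hyphens.
SYMBOL_PATTERN <- "[A-Za-z][A-Za-z0-9-]{1,9}"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the RNG, evaluates `expr`, and
#' restores the previous state so deterministic routines do not perturb the
#' global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Stable across R sessions; used to derive per-call seeds and to bucket
# tokens in the bag-of-words embedder.
string_hash <- function(x, modulus = 2147483647) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% modulus
  }
  as.integer(h)
}

# Combine a base seed with string context into a reproducible sub-seed.
derive_seed <- function(seed, ...) {
  ctx <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
    collapse = "\x1f"
  )
  string_hash(ctx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
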