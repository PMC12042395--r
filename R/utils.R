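# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Round half away from zero at `digits`; base round() is round-half-even.
# Used only at presentation time (currency display).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 32-bit string hash (FNV-1a), for content-addressed seeding
# and config fingerprints. Returns a double in [0, 2^31).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  h
}

# Fast vectorised polynomial hash for per-note seeding: deterministic,
# order-sensitive, cheap on long strings (first 512 chars suffice).
string_seed <- function(x, salt = 0L) {
  x <- substr(x, 1L, 512L)
  b <- utf8ToInt(enc2utf8(x))
  if (length(b) == 0L) b <- 0L
  h <- sum(b * (seq_along(b) %% 97 + 1)) + nchar(x) + salt
  as.integer(h %% 2147483647)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(is.na(x)) ||
      any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "notepheno_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %s.", name, min),
          class = "notepheno_config_error")
  }
  invisible(x)
}

assert_choice <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices) {
    abort(sprintf("`%s` must be one of: %s.", name,
                  paste(choices, collapse = ", ")),
          class = "notepheno_config_error")
  }
  invisible(x)
}

# Sample one element of `x` (safe for length-1 vectors, unlike sample()).
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Whitespace-delimited token count; empty strings count zero words.
count_words <- function(text) {
  stringr::str_count(text, "\\S+")
}
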