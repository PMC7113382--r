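# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive per-unit child seeds from a master seed; values stay < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply by FNV prime 16777619 modulo 2^32 without integer overflow
    lo <- (h %% 2^16) * 16777619
    hi <- ((h %/% 2^16) * 16777619) %% 2^16
    h <- (lo + hi * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
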