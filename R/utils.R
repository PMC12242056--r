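# small internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# derive a child seed from a parent seed and a stream label, staying < 2^31
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483647)
}

unit_rows <- function(m, eps = 1e-12) {
  m / (sqrt(rowSums(m^2)) + eps)
}

stop_arg <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_arg(what, " contains non-finite values")
}

# sinusoidal encoding of integer positions into `dim` features
sinusoid_encoding <- function(positions, dim, base = 10000) {
  half <- ceiling(dim / 2)
  freq <- base^(-(seq_len(half) - 1L) / half)
  ang <- outer(positions, freq)
  out <- cbind(sin(ang), cos(ang))
  out[, seq_len(dim), drop = FALSE]
}
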