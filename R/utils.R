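#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (round(0.5) in base R goes to
#' even). Used for patient counts and integer QAR reporting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded with ties away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 200.55), 0)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# FNV-1a 32-bit hash of a string, returned as 8 hex chars. Enough to tag a
# result with the spec it came from; not cryptographic.
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (the rest of h is untouched by a byte xor)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles
    # split to stay inside the 2^53 exact-integer range
    h <- (h %% 65536 * 16777619 + h %/% 65536 * 16777619 %% 65536 * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bia <- function(msg, class = "bimpact_error") {
  rlang::abort(msg, class = class)
}
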