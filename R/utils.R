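# Small shared helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero to a given number of digits
#'
#' Printed percentage shares in compiled-database reports use commercial
#' (half-up) rounding, not the IEEE round-half-to-even that [base::round()]
#' applies, so 14.5 rounds to 15, never 14.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.5, 3.5, 13.51))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# 32-bit FNV-1a over a character scalar; used only to stamp fixture manifests
# with a config fingerprint (no cryptographic intent).
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h a double to stay
    # within 2^53 during the modular multiply
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  # h can exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_fct <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "fctforge_error")))
}
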