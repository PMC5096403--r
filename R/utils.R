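DNA_BASES_ <- c("A", "C", "G", "T")

# integer codes 1..4 for A,C,G,T; 0 for anything else (N, ambiguity)
baseToInt <- function(s) {
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(s)]
}

intToBase <- function(v) paste(DNA_BASES_[v], collapse = "")

reverseComplement_ <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE))
}

#' Derive a reproducible sub-seed
#'
#' Modules draw from independent RNG streams derived from one global seed by
#' fixed offsets, so each stage is reproducible in isolation.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset.
#' @return integer seed below 2^31.
#' @export
deriveSeed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 7919) %%
               2147483647)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' reporting divergence times, as opposed to R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}
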