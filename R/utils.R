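# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count1 <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
}

is_fraction1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

is_number1 <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x) &&
    (!positive || x > 0)
}

# categories a feature interval may carry
FEATURE_CATEGORIES <- c("promoter", "enhancer", "exon", "intron", "repeat")
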