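# internal helpers

# round-half-up, matching how the printed clinical tables round (base round()
# rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lower-case, trimmed, de-duplicated medication names; drug identity is
# case-insensitive throughout
normalize_meds <- function(meds) {
  meds <- tolower(trimws(as.character(meds)))
  meds <- meds[nzchar(meds)]
  unique(meds)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
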