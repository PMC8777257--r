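## Locale-independent decimal formatting that round-trips doubles exactly:
## shortest of %.15g / %.17g that re-reads to the same value. Integers are
## printed without exponent or trailing zeros.
fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, "")
}

parse_num <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (anyNA(v)) stop("non-numeric attribute value: '", s, "'", call. = FALSE)
  v
}
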