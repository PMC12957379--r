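# Unit conversions at the interface boundary. User-facing arguments are
# uL/min (flows), um or mm (lengths), mPa.s (viscosity), cm^2/s (diffusivity);
# internal arithmetic uses um and s throughout (1 uL = 1e9 um^3).

uL_min_to_um3_s <- function(q) q * 1e9 / 60

cm2_s_to_um2_s <- function(d) d * 1e8

check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (bad) {
    abort(sprintf(
      "`%s` must be %s and finite (got %s).",
      name, if (strict) "> 0" else ">= 0", paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}
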