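# Shared test utilities.

# random network codes from the 12- or 15-slot space
random_codes <- function(n, include_x = FALSE) {
  top <- if (include_x) 3^15 else 3^12
  sample.int(top, n) - 1
}

all_defaults <- function() {
  lapply(0:7, function(d)
    c(Kr = d %% 2L, pdm = (d %/% 2L) %% 2L, cas = (d %/% 4L) %% 2L))
}

# the exhaustive screens are expensive; run each at most once per test run
scan_cache <- new.env(parent = emptyenv())

cached_scan_with_x <- function(polarity = "on_off") {
  key <- paste0("x_", polarity)
  if (is.null(scan_cache[[key]]))
    scan_cache[[key]] <- scan_with_x(polarity, t_end = 10)
  scan_cache[[key]]
}

cached_scan_known <- function() {
  if (is.null(scan_cache$known))
    scan_cache$known <- scan_known_factors(t_end = 10, keep_flags = TRUE)
  scan_cache$known
}
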