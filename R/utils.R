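#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
NULL

# half-open sample window [floor(start*fs), floor(end*fs)) as 1-based
# indices; the epsilon guards floor() against products like 0.6*1000 landing
# one ulp below the integer
window_indices <- function(start_s, end_s, sample_rate, n_samples) {
  i0 <- floor(start_s * sample_rate + 1e-9)   # 0-based, inclusive
  i1 <- floor(end_s * sample_rate + 1e-9)     # 0-based, exclusive
  if (i1 <= i0)
    stop("window [", start_s, ", ", end_s, ") is empty after discretization",
         call. = FALSE)
  if (i0 < 0 || i1 > n_samples)
    stop("window [", start_s, ", ", end_s, ") lies outside the trace",
         call. = FALSE)
  seq.int(i0 + 1L, i1)
}

rms <- function(x) sqrt(mean(x^2))

# deterministic 31-bit polynomial hash of a UTF-8 string (Horner form, exact
# in double precision); used for the run-manifest parameter hash
param_hash <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
generics::tidy

#' @export
generics::glance
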