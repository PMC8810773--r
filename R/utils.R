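# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop2(...)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# round to n significant figures, guarding zero
signif0 <- function(x, digits = 2) ifelse(x == 0, 0, signif(x, digits))

# decimal precision (unit in the last printed place) of a number as printed;
# used by the fixture audit to bound rounding error of transcribed values
printed_ulp <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v == 0) return(1)
    s <- format(abs(v), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
    if (grepl("\\.", s)) {
      dec <- nchar(sub("^[^.]*\\.", "", s))
      10^(-dec)
    } else {
      # trailing zeros of an integer are not significant in the printed tables
      core <- sub("0+$", "", s)
      10^(nchar(s) - nchar(core))
    }
  }, numeric(1))
}

# deterministic child seeds below 2^31 derived from a master seed
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483647
}
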