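# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix naming the offending field
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# phase unwrapping (adds multiples of 2*pi so successive jumps are < pi)
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  jumps <- -2 * pi * cumsum(round(d / (2 * pi)))
  phi + c(0, jumps)
}

# deterministic child seeds below 2^31, derived from a parent seed
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(index) %% 2147480000L
}

# full-precision numeric formatting for text round-trips
fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# sniff "," vs "\t" from the first line of a delimited file
sniff_delim <- function(path) {
  line1 <- readLines(path, n = 1L)
  if (lengths(regmatches(line1, gregexpr("\t", line1))) >
      lengths(regmatches(line1, gregexpr(",", line1)))) "\t" else ","
}

polyline_arclength <- function(x, y) {
  sum(sqrt(diff(x)^2 + diff(y)^2))
}
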