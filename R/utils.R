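# low-level sequence and rounding helpers shared across modules

#' Reverse complement of a DNA string
#'
#' @param x A single DNA sequence (character).
#' @return The reverse complement, as a plain character string.
#' @export
revcomp <- function(x) {
  if (length(x) != 1L || !is.character(x)) {
    stop("`x` must be a single character string", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# longest common prefix length of two strings (byte-wise)
lcp_length <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d)) d[1] - 1L else n
}

# longest common suffix length of two strings
lcs_length <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d)) d[1] - 1L else n
}

# round half away from zero (printed tables use half-up rounding, unlike
# base round()'s round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# random DNA string at a given GC fraction
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# all occurrences of a fixed pattern in a string (integer positions)
find_all_fixed <- function(pattern, x) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}
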