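#' @importFrom rlang .data abort warn %||%
#' @importFrom stats pt pnorm sd setNames
#' @importFrom utils combn head tail
NULL

# Reverse complement of an A/C/G/T/N character string.
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Split a string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 0-based half-open substring of a sequence string.
seq_slice <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

gc_percent <- function(x) {
  ch <- seq_chars(toupper(x))
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(ch) == 0L) return(NA_real_)
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

at_percent <- function(x) {
  ch <- seq_chars(toupper(x))
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(ch) == 0L) return(NA_real_)
  100 * sum(ch %in% c("A", "T")) / length(ch)
}

random_dna <- function(n, at = 0.62) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Maximal runs of TRUE in a logical vector: tibble(start, end) 0-based half-open.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}
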