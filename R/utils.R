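# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named operation from one global seed.
# Keeps independent simulator stages stable when calls are reordered.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 131) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

# Random DNA with a given GC content.
random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Interval coverage helpers (0-based half-open tibbles with start/end).
iranges_of <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end) # to 1-based closed
}

# Fraction of [start, end) covered by the union of intervals in `by`
# (tibble with start, end), all 0-based half-open.
covered_fraction <- function(start, end, by_start, by_end) {
  if (length(by_start) == 0 || end <= start) return(0)
  q <- iranges_of(start, end)
  s <- IRanges::reduce(iranges_of(by_start, by_end))
  ov <- IRanges::intersect(IRanges::IRanges(IRanges::start(q), IRanges::end(q)), s)
  sum(IRanges::width(ov)) / (end - start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
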