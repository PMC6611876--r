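# Kimura two-parameter divergence and LTR insertion-time dating, with
# divergence-landscape binning of transposable-element copies against
# their family consensus.

TRANSITIONS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

#' Kimura two-parameter distance between two aligned sequences
#'
#' `K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with `P` and `Q` the transition
#' and transversion proportions over counted columns; columns containing a
#' gap or `N` are excluded from the denominator.  Saturated pairs
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) return `K = NA` with
#' `saturated = TRUE`.
#'
#' @param seq_a,seq_b aligned DNA strings of equal length (gaps `-`).
#' @return tibble: `P`, `Q`, `K`, `n_sites`, `saturated`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("aligned sequences differ in length")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) return(tibble(P = NA_real_, Q = NA_real_, K = NA_real_,
                            n_sites = 0L, saturated = NA))
  diff <- a != b
  ts <- diff & !is.na(TRANSITIONS[paste0(a, b)])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  K <- if (saturated) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  tibble(P = P, Q = Q, K = K, n_sites = n, saturated = saturated)
}

#' LTR insertion time from K2P distance
#'
#' `t = K / (2 r)` with `r` the substitution rate per site per year
#' (default `7e-9`, the rate conventionally used for cotton).
#'
#' @param K K2P distance (substitutions/site, finite, >= 0).
#' @param r substitution rate per site per year.
#' @return age in years.
#' @export
insertion_time <- function(K, r = 7e-9) {
  if (any(!is.finite(K)) || any(K < 0)) abort("K must be finite and >= 0")
  K / (2 * r)
}

#' Divergence landscape of TE copies against their consensus
#'
#' Each copy is globally aligned to its family consensus, its K2P distance
#' computed, and genome bp binned by divergence.  Both length-weighted
#' (bp per bin, the reported landscape) and copy-count histograms are
#' returned; saturated copies fall into an overflow bin.
#'
#' @param copies tibble: `element_id`, `seq`, `consensus`.
#' @param bin_width histogram bin width in K units (default 0.01).
#' @param r substitution rate for the age axis.
#' @return list: `records` (per-copy `element_id`, `P`, `Q`, `K`, `age`,
#'   `length`), `histogram` (`bin_low`, `bin_high`, `bp`, `percent`,
#'   `n_copies`; last row is the saturation overflow bin when present).
#' @export
divergence_landscape <- function(copies, bin_width = 0.01, r = 7e-9) {
  recs <- purrr::map(seq_len(nrow(copies)), function(i) {
    s <- copies$seq[i]; cons <- copies$consensus[i]
    if (nchar(s) == nchar(cons)) {
      pa <- s; sa <- cons
    } else {
      aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(s),
                                           Biostrings::DNAString(cons),
                                           type = "global")
      pa <- as.character(Biostrings::alignedPattern(aln))
      sa <- as.character(Biostrings::alignedSubject(aln))
    }
    k <- k2p_distance(pa, sa)
    tibble(element_id = copies$element_id[i], P = k$P, Q = k$Q, K = k$K,
           age = ifelse(is.na(k$K), NA_real_, k$K / (2 * r)),
           length = nchar(s), saturated = k$saturated)
  }) %>% bind_rows()
  ok <- !recs$saturated & !is.na(recs$K)
  kmax <- if (any(ok)) max(recs$K[ok]) else 0
  breaks <- seq(0, max(bin_width, ceiling(kmax / bin_width) * bin_width),
                by = bin_width)
  if (max(breaks) <= kmax) breaks <- c(breaks, max(breaks) + bin_width)
  idx <- findInterval(recs$K[ok], breaks, rightmost.closed = FALSE)
  hist <- tibble(bin_low = breaks[-length(breaks)], bin_high = breaks[-1]) %>%
    mutate(bp = vapply(row_number(), function(b)
      sum(recs$length[ok][idx == b]), 0),
      n_copies = vapply(row_number(), function(b) sum(idx == b), 0))
  if (any(!ok)) {
    hist <- bind_rows(hist, tibble(
      bin_low = Inf, bin_high = Inf, bp = sum(recs$length[!ok]),
      n_copies = sum(!ok)))
  }
  hist$percent <- 100 * hist$bp / sum(recs$length)
  list(records = recs %>% select(-"saturated"), histogram = hist)
}
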