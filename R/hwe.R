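#' Exact test of Hardy-Weinberg equilibrium
#'
#' Computes the exact two-sided p-value for deviation from Hardy-Weinberg
#' proportions from biallelic genotype counts, by summing the conditional
#' probabilities (given allele counts) of all heterozygote counts whose
#' probability does not exceed that of the observed count. The distribution
#' is evaluated by the stable outward recurrence from the modal heterozygote
#' count, the approach genotype-QC pipelines use; it remains well defined at
#' low minor allele frequency where the chi-square approximation fails.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom reference, het, hom alternate).
#' @return the exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no genotype calls", call. = FALSE)
  rare <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (rare == 0) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # modal heterozygote count under HWE, matched to allele-count parity
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  mid <- min(max(mid, rare %% 2L), rare)
  probs <- numeric(length(hets))
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # downward: P(h-2)/P(h) = h(h-1) / (4 (hom_r+1)(hom_c+1))
  h <- mid
  i <- i_mid
  while (h >= 2) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    h <- h - 2L; i <- i - 1L
  }
  # upward: P(h+2)/P(h) = 4 hom_r hom_c / ((h+2)(h+1))
  h <- mid
  i <- i_mid
  while (h <= rare - 2) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    h <- h + 2L; i <- i + 1L
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}
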