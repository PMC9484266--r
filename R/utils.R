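## Shared statistical helpers.

## Two-sided Wilcoxon rank-sum p-value: exact distribution when the
## combined sample is small (n <= 25) and tie-free, normal approximation
## with continuity correction otherwise. Degenerate all-tied input
## yields p = 1.
wilcox_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty")
  comb <- c(a, b)
  if (length(unique(comb)) == 1) return(1)
  use_exact <- length(comb) <= 25 && !any(duplicated(comb))
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value)
  if (is.na(p)) 1 else min(p, 1)
}
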