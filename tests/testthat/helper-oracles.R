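# independent oracles used across test files

# brute-force Mann-Whitney U for group1: pairs won (+0.5 per tie)
brute_force_u <- function(g1, g2) {
  u <- 0
  for (a in g1) for (b in g2) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# plain CLSI rank percentile, written out longhand (independent of
# stats::quantile and of the package's C++ path)
rank_percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  r <- min(max(p * (n + 1), 1), n)
  i <- floor(r)
  if (i >= n) return(s[n])
  s[i] + (r - i) * (s[i + 1] - s[i])
}

# a clean single-sex cohort spec with no contamination
clean_spec <- function(n = 2000, seed = 1, ...) {
  cohort_spec(n_subjects = n, healthy_fraction = 1,
              pathological_components = list(), seed = seed, ...)
}

# the default contaminated study conditions at a chosen size
contaminated_spec <- function(n = 20000, seed = 1, ...) {
  cohort_spec(n_subjects = n, seed = seed, ...)
}
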