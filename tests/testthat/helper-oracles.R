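# Independent oracles and small utilities used across tests.

# Build full-model parameters realizing a given reduced (alpha, beta, m)
# triple, with r_null = 1 and an even growth/stress split.
params_from_reduced <- function(alpha, beta, m, K = 1e7, phi = 0.5) {
  omega <- beta * log(2) / phi
  D <- if (m > 0) -log(1 - m) / ((1 - phi) * omega) else 0
  competition_params(r_wt = alpha, r_null = 1, carrying_capacity = K,
                     stress_period = omega, growth_fraction = phi,
                     death_rate = D)
}

# Brute-force non-overlapping motif count: enumerate every match interval on
# both strands, then take a maximum independent set on the interval path by
# the classic earliest-end greedy (provably optimal for intervals).
brute_motif_count <- function(sequence, motif) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
             H = "ACT", V = "ACG", N = "ACGT")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(sequence), "")[[1L]]
  find_all <- function(mot) {
    mc <- strsplit(mot, "")[[1L]]
    n <- length(chars); L <- length(mc)
    if (L > n) return(integer(0))
    hits <- integer(0)
    for (s in seq_len(n - L + 1L)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!chars[s + j - 1L] %in% strsplit(iupac[[mc[j]]], "")[[1L]]) {
          ok <- FALSE; break
        }
      }
      if (ok) hits <- c(hits, s)
    }
    hits
  }
  rc <- paste(rev(comp[strsplit(toupper(motif), "")[[1L]]]), collapse = "")
  starts <- sort(unique(c(find_all(toupper(motif)), find_all(rc))))
  if (!length(starts)) return(0L)
  ends <- starts + nchar(motif) - 1L
  ord <- order(ends)
  count <- 0L; last_end <- 0L
  for (i in ord) {
    if (starts[i] > last_end) {
      count <- count + 1L
      last_end <- ends[i]
    }
  }
  count
}

# Exact hypergeometric upper tail via factorial combinatorics (universes
# small enough for choose() to stay exact).
exact_hyper_upper <- function(overlap, set_size, cluster_size, universe) {
  ks <- overlap:min(set_size, cluster_size)
  sum(choose(set_size, ks) * choose(universe - set_size, cluster_size - ks)) /
    choose(universe, cluster_size)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}
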