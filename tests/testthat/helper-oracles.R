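# Independent oracles, deliberately naive: plain per-read / per-table
# loops with no shared code with the package internals.

# per-read enumeration of start counts and overlap coverage
naive_profile <- function(reads, lengths) {
  out <- list()
  for (mol in names(lengths)) {
    len <- lengths[[mol]]
    starts <- integer(len)
    overlap <- integer(len)
    sel <- which(reads$molecule == mol)
    for (i in sel) {
      s <- reads$start[i]
      e <- min(reads$end[i], len)
      starts[s] <- starts[s] + 1L
      for (p in s:e) overlap[p] <- overlap[p] + 1L
    }
    out[[mol]] <- list(starts = starts, overlap = overlap)
  }
  out
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p,
# probabilities from log-binomial coefficients (no dhyper)
enum_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  k <- lo:hi
  logp <- lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  probs <- exp(logp)
  obs <- probs[k == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# small helper: a quick psi config on one molecule
one_mol_config <- function(len = 500, positions = 250, f = 0.5,
                           e = 1, b = 0, coverage = 2000, seed = 1,
                           mean_read_length = 80) {
  sim_psi_config(
    molecules = c(M = len),
    sites = tibble::tibble(molecule = "M", position = positions,
                           stoichiometry = f, guide = NA_character_),
    term_efficiency = e, background = b, coverage = coverage,
    mean_read_length = mean_read_length, seed = seed)
}
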