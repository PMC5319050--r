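# Shared fixture builders; everything is generated in code.

# tiny haplotype matrix from an explicit 2N x S matrix
make_hm <- function(H, positions = NULL, pops = NULL, chrom = "1") {
  H <- as.matrix(H)
  n <- nrow(H) / 2
  if (is.null(positions)) positions <- seq_len(ncol(H)) * 100L
  ids <- paste0("s", seq_len(n))
  if (is.null(pops)) pops <- stats::setNames(rep("pop1", n), ids)
  else names(pops) <- ids
  haplo_matrix(H, chrom = chrom, positions = positions,
               sample_ids = ids, pops = pops)
}

# random haplotype matrix: n_hap haplotypes (even), S sites, 2 pops
random_hm <- function(n_hap, S, seed = 1, two_pops = FALSE, p = 0.5) {
  set.seed(seed)
  H <- matrix(rbinom(n_hap * S, 1L, p), n_hap, S)
  n <- n_hap / 2
  pops <- if (two_pops)
    rep(c("pop1", "pop2"), each = ceiling(n / 2))[seq_len(n)]
  else rep("pop1", n)
  make_hm(H, pops = pops)
}

# small neutral simulation shared by several tests
small_sim <- function(seed = 11, n_sites = 2000, seq_length = 2e6, ...) {
  simulate_neutral(sweep_sim_config(n_sites = n_sites,
                                    seq_length = seq_length,
                                    seed = seed, ...))
}

# EHH by brute-force pair enumeration over spanning strings
ehh_oracle <- function(H, positions, core, direction, cutoff = 0.05,
                       max_span = Inf) {
  n <- nrow(H)
  dirstep <- if (direction == "right") 1L else -1L
  offs <- 0
  vals <- 1
  x <- core
  repeat {
    x_next <- x + dirstep
    if (x_next < 1L || x_next > ncol(H)) break
    d <- abs(positions[x_next] - positions[core])
    if (d > max_span) break
    rng <- if (dirstep > 0) core:x_next else x_next:core
    strs <- apply(H[, rng, drop = FALSE], 1, paste, collapse = "")
    same <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      same <- same + (strs[i] == strs[j])
    e <- same / choose(n, 2)
    offs <- c(offs, d)
    vals <- c(vals, e)
    if (e < cutoff) break
    x <- x_next
  }
  list(offsets = offs, ehh = vals,
       ihh = sum(diff(offs) * (head(vals, -1) + vals[-1]) / 2))
}

# Weir-Cockerham per-site components, independent stepwise implementation
# (scalar arithmetic, spreadsheet style)
wc_oracle <- function(counts_alt, counts_het, n_i) {
  r <- length(n_i)
  p_i <- counts_alt / (2 * n_i)
  h_i <- counts_het / n_i
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}
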