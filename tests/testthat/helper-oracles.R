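# Shared test fixtures and independent oracles. Oracles here are written
# from the definitions (triple loops, string counting) and deliberately do
# not reuse the package's optimized code paths.

NUCS <- c("A", "C", "G", "T")
DINUC16 <- as.vector(t(outer(NUCS, NUCS, paste0)))

# brute-force derivative: direct summation over all 4 x 12 x 4 events using
# the public change_count / context_rate definitions
deriv_oracle <- function(d, theta, fv) {
  m <- colSums(d)
  dd <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  for (i in NUCS) for (j in NUCS) for (k in NUCS) for (l in NUCS) {
    if (l == j || m[j] < 1e-14) next
    t_ijk <- d[i, j] * d[j, k] / m[j]
    r <- context_rate(fv, i, j, l, k, theta)
    for (x in NUCS) for (y in NUCS)
      dd[x, y] <- dd[x, y] + t_ijk * r * change_count(c(x, y), c(i, j, l, k))
  }
  dd
}

# string-counting oracle for the change count: overlapping occurrences of a
# dinucleotide within an explicit trinucleotide string
change_count_oracle <- function(target, event) {
  occ <- function(tri) {
    sum(substr(tri, 1, 2) == target, substr(tri, 2, 3) == target)
  }
  occ(paste0(event[1], event[3], event[4])) -
    occ(paste0(event[1], event[2], event[4]))
}

# random valid dinucleotide proportion matrix with consistent margins
# (independent product of a random mononucleotide composition)
random_d <- function() {
  p <- runif(4, 0.05, 1)
  p <- p / sum(p)
  d <- outer(p, p)
  dimnames(d) <- list(NUCS, NUCS)
  d
}

# random factor vector with a few active factors of moderate magnitude
random_fv <- function(mode = "rna", n_active = 2,
                      log_range = log(c(1 / 6, 6)), kappa_range = c(1, 4)) {
  fv <- factor_vector(kappa = runif(1, kappa_range[1], kappa_range[2]),
                      mode = mode)
  cands <- candidate_set(mode)
  for (spec in sample(cands, n_active))
    fv <- set_factor(fv, spec, exp(runif(1, log_range[1], log_range[2])))
  fv
}

# noiseless profiles on the model's own equilibrium curve: gc = omega,
# ratios = model o/e
model_profiles <- function(fv, thetas) {
  lapply(thetas, function(th) {
    eq <- equilibrium(th, fv)
    dinucleotide_profile(gc = eq$omega, ratios = eq$oe,
                         id = sprintf("model_t%.3f", th))
  })
}

# Monte-Carlo standard error of per-dinucleotide o/e ratios by block
# decomposition of a long sequence (overlapping windows make the plain
# binomial SE an underestimate)
oe_block_se <- function(bases, n_blocks = 40) {
  L <- nchar(bases)
  size <- L %/% n_blocks
  starts <- seq(1, by = size, length.out = n_blocks)
  blocks <- substring(bases, starts, starts + size - 1)
  oeb <- t(vapply(blocks, function(b) scan_sequence(b, mode = "rna")$ratios,
                  numeric(16)))
  apply(oeb, 2, stats::sd, na.rm = TRUE) / sqrt(n_blocks)
}

random_iid_sequence <- function(n, p = rep(0.25, 4)) {
  paste(sample(NUCS, n, replace = TRUE, prob = p), collapse = "")
}
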