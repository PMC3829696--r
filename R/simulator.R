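#' Configure a stochastic sequence-evolution run
#'
#' The simulator is the independent stochastic oracle for the deterministic
#' equilibrium solver: it evolves an explicit sequence in which each site
#' mutates at the context-dependent rate r(i, j->l, k) given by its two
#' neighbors, via Gillespie sampling with per-event rate updates confined to
#' the mutated site and its neighbors. Sequence topology is circular by
#' default so every site has both neighbors; linear mode holds the two end
#' bases fixed.
#'
#' @param length sequence length in bases (>= 1000 for equilibrium
#'   sampling).
#' @param theta initial composition: bases drawn i.i.d. with G+C = theta
#'   (C and G equal, A and T equal); also sets the default-matrix theta.
#' @param fv a [factor_vector()].
#' @param seed random seed (mandatory; reproducibility contract).
#' @param subs_per_site expected substitutions per site — the event budget
#'   is `round(subs_per_site * length)`. The default 30 is far past
#'   equilibrium for all factor magnitudes used here.
#' @param burnin_frac fraction of the event budget treated as burn-in when
#'   assessing equilibration (default 0.5).
#' @param boundary `"circular"` or `"linear"`.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(length, theta, fv, seed,
                              subs_per_site = 30, burnin_frac = 0.5,
                              boundary = c("circular", "linear")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(fv, "factor_vector"))
  if (length < 1000)
    stop("simulation length must be at least 1000 for equilibrium sampling")
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (missing(seed) || is.null(seed)) stop("a random seed is required")
  if (subs_per_site <= 0) stop("subs_per_site must be positive")
  structure(list(length = as.integer(length), theta = theta, fv = fv,
                 seed = as.integer(seed), subs_per_site = subs_per_site,
                 burnin_frac = burnin_frac, boundary = boundary),
            class = "simulation_config")
}

#' Evolve a sequence to (stochastic) equilibrium
#'
#' Runs the Gillespie simulation defined by `config`. Equilibration is
#' assessed by comparing dinucleotide proportions over the final two
#' sampling checkpoints (after the burn-in): the run is flagged
#' equilibrated when they differ by less than 2 binomial standard errors
#' everywhere; a warning is emitted otherwise.
#'
#' @param config a [simulation_config()].
#' @param record_tail if > 0, the final `record_tail` substitution events
#'   are returned as SNP-style records (ref, alt, five_prime, three_prime) —
#'   used to feed the flanking-context spectrum analysis.
#' @return list with `sequence` (a [nuc_sequence()]), `type_counts` (named
#'   12-vector of substitution counts by type), `n_events`,
#'   `equilibrated` (logical), `records` (data frame, possibly empty),
#'   `config`.
#' @export
evolve <- function(config, record_tail = 0) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$length
  p <- stationary_mono(config$theta)
  seq0 <- sample.int(4, n, replace = TRUE, prob = p) - 1L
  rates <- rate_array(config$fv, config$theta)
  n_events <- round(config$subs_per_site * n)
  circular <- config$boundary == "circular"

  # run to the pre-final checkpoint, snapshot, then finish
  n1 <- round(n_events * (1 + config$burnin_frac) / 2)  # midpoint of sampling
  r1 <- dc_evolve(seq0, rates, n1, circular = circular)
  record_start <- if (record_tail > 0)
    max((n_events - n1) - record_tail, 0) else -1
  r2 <- dc_evolve(r1$seq, rates, n_events - n1, circular = circular,
                  record_start = record_start)

  prof1 <- scan_codes(r1$seq)
  prof2 <- scan_codes(r2$seq)
  W <- n - !circular
  # two-sample comparison: both snapshots carry sampling noise, and
  # overlapping windows roughly double the binomial variance
  se_diff <- sqrt(pmax(4 * prof2 * (1 - prof2), 1e-12) / W)
  equilibrated <- all(abs(prof1 - prof2) < 3 * se_diff + 4 / W)
  if (!equilibrated)
    warning("dinucleotide proportions still drifting between the final two ",
            "sampling windows; increase subs_per_site")

  type_counts <- r1$type_counts + r2$type_counts
  names(type_counts) <- MUTATION_IDS
  records <- if (record_tail > 0 && nrow(r2$records) > 0) {
    data.frame(ref = NUC[r2$records[, 1] + 1L],
               alt = NUC[r2$records[, 2] + 1L],
               five_prime = NUC[r2$records[, 3] + 1L],
               three_prime = NUC[r2$records[, 4] + 1L],
               stringsAsFactors = FALSE)
  } else data.frame(ref = character(), alt = character(),
                    five_prime = character(), three_prime = character(),
                    stringsAsFactors = FALSE)
  bases <- paste(NUC[r2$seq + 1L], collapse = "")
  mode <- if (config$fv$mode == "rna") "rna" else "dna"
  list(sequence = nuc_sequence(
         sprintf("sim_theta%.3f_seed%d", config$theta, config$seed),
         bases, mode),
       type_counts = type_counts, n_events = n_events,
       equilibrated = equilibrated, records = records, config = config)
}

# dinucleotide proportions of an integer-coded sequence (0..3), circular
scan_codes <- function(codes) {
  a <- codes + 1L
  b <- c(codes[-1], codes[1]) + 1L
  tabulate((a - 1L) * 4L + b, nbins = 16) / length(codes)
}

#' Simulate equilibrium composition profiles over a G+C range
#'
#' Evolves one sequence per theta value under a shared factor vector and
#' scans each into a dinucleotide profile — synthetic "organisms" with known
#' ground-truth mutation parameters spanning a G+C gradient, used for
#' parameter-recovery tests.
#'
#' @param fv a [factor_vector()].
#' @param theta_list theta values in (0, 1).
#' @param length sequence length per theta (>= 1000).
#' @param seed base seed; run i uses seed + i - 1.
#' @param subs_per_site event budget per site (default 30).
#' @return list of [dinucleotide_profile()].
#' @export
equilibrium_profiles <- function(fv, theta_list, length = 2e5, seed = 1,
                                 subs_per_site = 30) {
  if (any(theta_list <= 0 | theta_list >= 1))
    stop("all theta values must be in (0, 1)")
  lapply(seq_along(theta_list), function(i) {
    cfg <- simulation_config(length, theta_list[i], fv, seed = seed + i - 1,
                             subs_per_site = subs_per_site)
    run <- evolve(cfg)
    scan_sequence(run$sequence,
                  mode = if (fv$mode == "rna") "rna" else "dna")
  })
}
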