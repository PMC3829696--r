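# Curve cache: equilibrium solves over the theta grid dominate the greedy
# fit's cost, so curves are memoized on (kappa, factors, grid) rounded to
# 1e-10.
new_curve_cache <- function() new.env(parent = emptyenv())

curve_cache_key <- function(fv, theta_grid) {
  paste(c(round(fv$kappa, 10), round(fv$up, 10), round(fv$down, 10),
          fv$mode, round(theta_grid, 10)), collapse = ",")
}

cached_curve <- function(fv, theta_grid, cache = NULL, tol = 1e-10) {
  if (is.null(cache)) return(build_curve(fv, theta_grid, tol = tol))
  key <- curve_cache_key(fv, theta_grid)
  if (!is.null(cache[[key]])) return(cache[[key]])
  cv <- build_curve(fv, theta_grid, tol = tol)
  cache[[key]] <- cv
  cv
}

#' RMS distance between model predictions and observed profiles
#'
#' Builds the model o/e curve for the given factor vector and returns
#' sqrt( sum_n sum_xy (R_n,xy - M_xy(omega_n))^2 / D ), where D is the
#' number of included (profile, dinucleotide) terms — 16N when every
#' observed ratio is defined; undefined (NA) ratios are excluded with the
#' divisor reduced accordingly.
#'
#' @param fv a [factor_vector()].
#' @param profiles list of [dinucleotide_profile()].
#' @param theta_grid grid for [build_curve()].
#' @param curve optionally a prebuilt curve for `fv` (skips the solve).
#' @param cache optional cache environment from `new_curve_cache()`.
#' @return nonnegative RMS distance.
#' @export
rms_distance <- function(fv, profiles, theta_grid = default_theta_grid(),
                         curve = NULL, cache = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(curve)) curve <- cached_curve(fv, theta_grid, cache)
  omega <- vapply(profiles, function(p) p$gc, numeric(1))
  rng <- range(curve$omega)
  bad <- which(omega < rng[1] | omega > rng[2])
  if (length(bad) > 0)
    stop(sprintf(
      "profile '%s' has G+C %.4f outside the model curve range [%.4f, %.4f]",
      profiles[[bad[1]]]$id, omega[bad[1]], rng[1], rng[2]))
  R <- t(vapply(profiles, function(p) p$ratios, numeric(16)))
  M <- predict_curve(curve, omega)
  if (length(profiles) == 1) M <- matrix(M, 1, 16)
  resid <- (R - M)[!is.na(R)]
  sqrt(sum(resid^2) / length(resid))
}

# bounds of the stage optimizer (log space)
FIT_BOUNDS <- list(kappa = c(0.2, 20), factor = c(1 / 100, 100))

#' Jointly optimize kappa and a set of selected context factors
#'
#' Minimizes [rms_distance()] over kappa and the values of the selected
#' candidate factors by derivative-free Nelder-Mead search in log-parameter
#' space (kappa constrained to \[0.2, 20\], factors to \[1/100, 100\] via a
#' smooth out-of-bounds penalty), multi-started from the supplied previous
#' optimum and from the default values. Deterministic given its inputs.
#'
#' @param profiles list of [dinucleotide_profile()].
#' @param selected character vector of candidate factor specs (see
#'   [candidate_set()]); may be empty to optimize kappa alone.
#' @param mode `"dna"` or `"rna"`.
#' @param theta_grid curve tabulation grid.
#' @param init optional named list `list(kappa = , values = named vector)`
#'   used as the first start.
#' @param cache optional curve cache.
#' @param control list: `maxit` Nelder-Mead iteration cap (default 250),
#'   `reltol` (default 1e-7), `eq_tol` equilibrium tolerance (default 1e-9).
#' @return list with `kappa`, `values` (named vector over `selected`),
#'   `rms`, `fv` (the optimized factor vector).
#' @export
optimize_stage <- function(profiles, selected = character(),
                           mode = c("dna", "rna"),
                           theta_grid = default_theta_grid(),
                           init = NULL, cache = NULL, control = list()) {
  mode <- match.arg(mode)
  maxit <- control$maxit %||% 250
  reltol <- control$reltol %||% 1e-7
  eq_tol <- control$eq_tol %||% 1e-9
  nsel <- length(selected)

  lb <- log(c(FIT_BOUNDS$kappa[1], rep(FIT_BOUNDS$factor[1], nsel)))
  ub <- log(c(FIT_BOUNDS$kappa[2], rep(FIT_BOUNDS$factor[2], nsel)))
  objective <- function(p) {
    pen <- sum(pmax(p - ub, 0)^2) + sum(pmax(lb - p, 0)^2)
    pc <- pmin(pmax(p, lb), ub)
    fv <- factor_vector(kappa = exp(pc[1]), mode = mode)
    if (nsel > 0)
      for (s in seq_len(nsel))
        fv <- set_factor(fv, selected[s], exp(pc[1 + s]))
    val <- tryCatch(
      rms_distance(fv, profiles, theta_grid, cache = cache),
      error = function(e) NA_real_)
    if (!is.finite(val)) return(1e6)
    val + 100 * pen
  }

  starts <- list(c(log(2), rep(0, nsel)))
  if (!is.null(init)) {
    p0 <- c(log(init$kappa %||% 2),
            vapply(selected, function(s) {
              v <- if (!is.null(init$values) && s %in% names(init$values))
                init$values[[s]] else 1
              log(v)
            }, numeric(1)))
    starts <- c(list(p0), starts)
  }
  best <- NULL
  for (p0 in starts) {
    opt <- tryCatch(
      if (length(p0) == 1)
        stats::optim(p0, objective, method = "Brent",
                     lower = lb, upper = ub,
                     control = list(maxit = maxit, reltol = reltol))
      else
        stats::optim(p0, objective, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("stage optimization failed from all starts")
  pc <- pmin(pmax(best$par, lb), ub)
  kappa <- exp(pc[1])
  values <- if (nsel > 0)
    stats::setNames(exp(pc[-1]), selected) else stats::setNames(numeric(0),
                                                                character(0))
  fv <- factor_vector(kappa = kappa, mode = mode)
  if (nsel > 0)
    for (s in seq_len(nsel)) fv <- set_factor(fv, selected[s], values[[s]])
  list(kappa = kappa, values = values,
       rms = rms_distance(fv, profiles, theta_grid, cache = cache),
       fv = fv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Greedy forward selection of context-dependent mutation factors
#'
#' Stage k evaluates, for every not-yet-selected candidate factor, the joint
#' re-optimization of kappa and all previously selected factors plus that
#' candidate, and selects the candidate achieving the lowest RMS. Selection
#' stops at `max_k` factors or when the best relative RMS reduction falls
#' below `min_rel_improvement`. In DNA mode candidates are the 48
#' strand-symmetric pairs (each toggles both paired entries); in RNA mode
#' all 96 factors. Candidates whose RMS differ by less than 1e-9 are
#' tie-broken by lexicographic factor order.
#'
#' @param profiles list of [dinucleotide_profile()].
#' @param mode `"dna"` or `"rna"`.
#' @param max_k maximum number of factors to select (default 8).
#' @param theta_grid curve tabulation grid.
#' @param candidates candidate factor specs; defaults to the full
#'   [candidate_set()] for the mode. A restricted set supports small-scale
#'   exhaustive cross-checks.
#' @param baseline_rms optional [fit_quadratic_baseline()] RMS used to report
#'   baseline-corrected errors.
#' @param min_rel_improvement stop threshold on relative RMS reduction.
#' @param control optimizer control list, see [optimize_stage()].
#' @param verbose print per-stage progress to stderr.
#' @return object of class `fit_result`: list with `selected` (data frame:
#'   stage, factor, alias, value at final stage), `kappa` (per stage,
#'   starting at stage 0 = kappa-only), `rms` (per stage), `corrected_error`
#'   (per stage, if baseline supplied), `alternatives` (per stage, named
#'   vector of each candidate's best achieved RMS), `baseline_rms`, `mode`,
#'   `max_k`, `M` (total parameter count, 49 DNA / 97 RNA), `stage_values`
#'   (list of per-stage optimized factor values).
#' @export
greedy_fit <- function(profiles, mode = c("dna", "rna"), max_k = 8,
                       theta_grid = default_theta_grid(),
                       candidates = NULL, baseline_rms = NULL,
                       min_rel_improvement = 1e-4, control = list(),
                       verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(candidates)) candidates <- candidate_set(mode)
  candidates <- sort(unique(candidates))
  M <- if (mode == "dna") 49L else 97L
  if (max_k > length(candidates))
    stop("max_k exceeds the number of candidate factors")
  omega <- vapply(profiles, function(p) p$gc, numeric(1))
  if (length(unique(round(omega, 10))) == 1)
    warning("all profiles share one G+C value; ",
            "no compositional trend is available to constrain the fit")
  cache <- new_curve_cache()

  stage0 <- optimize_stage(profiles, character(), mode, theta_grid,
                           cache = cache, control = control)
  if (verbose)
    message(sprintf("stage 0: kappa-only fit, RMS = %.6f (kappa = %.3f)",
                    stage0$rms, stage0$kappa))
  kappa_traj <- stage0$kappa
  rms_traj <- stage0$rms
  selected <- character()
  stage_values <- list()
  alternatives <- list()
  prev <- stage0

  for (k in seq_len(max_k)) {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    alt <- stats::setNames(rep(NA_real_, length(remaining)), remaining)
    best_cand <- NULL; best_fit <- NULL
    for (cand in remaining) {
      fit <- tryCatch(
        optimize_stage(profiles, c(selected, cand), mode, theta_grid,
                       init = list(kappa = prev$kappa, values = prev$values),
                       cache = cache, control = control),
        error = function(e) {
          warning("candidate ", cand, " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      alt[cand] <- fit$rms
      if (is.null(best_fit) || fit$rms < best_fit$rms - 1e-9) {
        best_fit <- fit; best_cand <- cand
      }
      if (verbose)
        message(sprintf("stage %d: candidate %-8s RMS = %.6f", k, cand,
                        fit$rms))
    }
    if (is.null(best_fit)) stop("all candidates failed at stage ", k)
    alternatives[[k]] <- alt
    improvement <- if (prev$rms > 1e-12)
      (prev$rms - best_fit$rms) / prev$rms else 0
    if (improvement < min_rel_improvement) {
      if (verbose)
        message(sprintf(
          "stage %d: best relative improvement %.2g below threshold; stopping",
          k, improvement))
      break
    }
    selected <- c(selected, best_cand)
    stage_values[[k]] <- best_fit$values
    kappa_traj <- c(kappa_traj, best_fit$kappa)
    rms_traj <- c(rms_traj, best_fit$rms)
    prev <- best_fit
    if (verbose)
      message(sprintf("stage %d: selected %s = %.3f, RMS = %.6f", k,
                      best_cand, best_fit$values[[best_cand]], best_fit$rms))
  }

  sel_df <- if (length(selected) > 0) {
    data.frame(stage = seq_along(selected), factor = selected,
               alias = vapply(selected, factor_alias, character(1),
                              mode = mode),
               value = vapply(selected, function(s)
                 unname(prev$values[s]), numeric(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(stage = integer(), factor = character(), alias = character(),
               value = numeric(), stringsAsFactors = FALSE)
  }
  corrected <- if (!is.null(baseline_rms))
    vapply(rms_traj, baseline_corrected_error, numeric(1),
           baseline_rms = baseline_rms) else NULL
  structure(list(selected = sel_df, kappa = kappa_traj, rms = rms_traj,
                 corrected_error = corrected, baseline_rms = baseline_rms,
                 alternatives = alternatives, stage_values = stage_values,
                 fv = prev$fv, mode = mode, max_k = max_k, M = M),
            class = "fit_result")
}

# strand-symmetric alias of a factor spec ("C,G>A" <-> "C>T,G"); the spec
# itself for RNA mode
factor_alias <- function(spec, mode = "dna") {
  if (mode != "dna") return(spec)
  format_factor_spec(strand_partner(parse_factor_spec(spec)))
}

#' Does a fitted factor match a target factor?
#'
#' TRUE when the specs are equal or, in DNA mode, strand-symmetric aliases
#' of one another (e.g. `"C>T,G"` and `"C,G>A"` name the same free
#' parameter).
#'
#' @param spec,target factor spec strings.
#' @param mode `"dna"` or `"rna"`.
#' @return logical.
#' @export
factor_matches <- function(spec, target, mode = "dna") {
  canon <- function(s) format_factor_spec(parse_factor_spec(s))
  spec <- canon(spec); target <- canon(target)
  spec == target || (mode == "dna" && factor_alias(spec, mode) == target)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Greedy context-factor fit (%s mode, M = %d)\n",
              toupper(x$mode), x$M))
  cat(sprintf("stage 0: kappa = %.3f, RMS = %.6f\n", x$kappa[1], x$rms[1]))
  if (nrow(x$selected) > 0)
    for (r in seq_len(nrow(x$selected)))
      cat(sprintf("stage %d: %s (= %s) value %.3f, kappa = %.3f, RMS = %.6f%s\n",
                  r, x$selected$factor[r], x$selected$alias[r],
                  x$selected$value[r], x$kappa[r + 1], x$rms[r + 1],
                  if (!is.null(x$corrected_error))
                    sprintf(", corrected error = %.6f",
                            x$corrected_error[r + 1]) else ""))
  invisible(x)
}

#' Baseline-corrected model error
#'
#' The model-vs-data RMS minus the RMS of the per-dinucleotide quadratic
#' baselines, removing the irreducible scatter of the data from the model
#' comparison.
#'
#' @param model_rms model RMS distance (>= 0).
#' @param baseline_rms quadratic-baseline RMS distance (>= 0).
#' @return model_rms - baseline_rms.
#' @examples
#' baseline_corrected_error(0.0378, 0.0275)  # 0.0103
#' @export
baseline_corrected_error <- function(model_rms, baseline_rms) {
  stopifnot(model_rms >= 0, baseline_rms >= 0)
  model_rms - baseline_rms
}

#' Canonicalize a fitted factor for reporting
#'
#' Raising a forward mutation rate usually has a similar equilibrium effect
#' to lowering the reverse rate, so by convention only factors greater than
#' 1 are reported: a fitted value v < 1 is presented as the reverse-mutation
#' factor in the same context with value 1/v, flagged as
#' reciprocal-reported.
#'
#' @param spec factor spec string.
#' @param value fitted positive value.
#' @return list with `spec`, `value`, `reciprocal` (logical).
#' @examples
#' canonicalize_factor("C>T,G", 12.06)   # unchanged
#' canonicalize_factor("A>T,G", 0.125)   # reported as T>A,G = 8
#' @export
canonicalize_factor <- function(spec, value) {
  if (value <= 0) stop("factor value must be positive")
  entry <- parse_factor_spec(spec)
  if (value >= 1)
    return(list(spec = format_factor_spec(entry), value = value,
                reciprocal = FALSE))
  rev <- entry
  rev$from <- entry$to
  rev$to <- entry$from
  list(spec = format_factor_spec(rev), value = 1 / value, reciprocal = TRUE)
}
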