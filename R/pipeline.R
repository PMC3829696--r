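#' Build a validated pipeline configuration
#'
#' Bundles the options of the scan -> baseline -> greedy-fit pipeline.
#' Defaults follow standard practice for genomic analyses: 50,000 bp
#' fragments for long DNA, a 2,500-base minimum for mRNA records, and the
#' default theta tabulation grid.
#'
#' @param fasta input FASTA path.
#' @param mode `"dna"` or `"rna"`.
#' @param fragment_length fragment long records into this many bases; NULL
#'   disables fragmentation. Default 50,000.
#' @param min_length drop records shorter than this (default 0 for DNA;
#'   2,500 is conventional for mRNA).
#' @param theta_grid curve tabulation grid.
#' @param max_k maximum number of context factors to select.
#' @param candidates optional restricted candidate set.
#' @param min_rel_improvement greedy stopping threshold.
#' @param seed seed recorded for provenance (the fit itself is
#'   deterministic).
#' @param control optimizer control list (see [optimize_stage()]).
#' @param out_prefix path prefix for report files; NULL writes no files.
#' @return object of class `run_config`.
#' @export
run_config <- function(fasta, mode = c("dna", "rna"),
                       fragment_length = 50000, min_length = 0,
                       theta_grid = default_theta_grid(), max_k = 8,
                       candidates = NULL, min_rel_improvement = 1e-4,
                       seed = 1, control = list(), out_prefix = NULL) {
  mode <- match.arg(mode)
  if (!is.null(fragment_length) && fragment_length < 100)
    stop("fragment_length must be at least 100 (or NULL)")
  if (max_k < 0) stop("max_k must be nonnegative")
  cfg <- structure(list(fasta = fasta, mode = mode,
                        fragment_length = fragment_length,
                        min_length = min_length, theta_grid = theta_grid,
                        max_k = max_k, candidates = candidates,
                        min_rel_improvement = min_rel_improvement,
                        seed = as.integer(seed), control = control,
                        out_prefix = out_prefix),
                   class = "run_config")
  # hash identifies the analysis (inputs + parameters), not where its
  # reports land
  hashed <- unclass(cfg)
  hashed$out_prefix <- NULL
  cfg$hash <- config_hash(hashed)
  cfg
}

#' Run the full composition-modelling pipeline
#'
#' Scans the FASTA input into dinucleotide profiles (fragmenting long
#' records), fits the per-dinucleotide quadratic baselines, runs the greedy
#' context-factor selection, and reports baseline-corrected model errors
#' per stage. When `out_prefix` is set, writes `<prefix>_profiles.tsv`,
#' `<prefix>_fit.json` and `<prefix>_stages.tsv` (the stagewise table of
#' selected factor, rate, RMS, corrected error), each stamped with the
#' configuration hash; partial outputs are removed if any stage fails.
#'
#' @param config a [run_config()].
#' @param verbose print progress.
#' @return list with `profiles`, `baseline`, `fit` (a `fit_result`),
#'   `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  outputs <- character()
  on_fail <- function(stage, e) {
    for (f in outputs) if (file.exists(f)) unlink(f)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  seqs <- tryCatch(
    read_fasta(config$fasta, config$mode, min_length = config$min_length),
    error = function(e) on_fail("read", e))
  profiles <- tryCatch({
    if (!is.null(config$fragment_length)) {
      seqs <- unlist(lapply(seqs, function(s) {
        if (nchar(s$bases) >= config$fragment_length)
          fragment_sequence(s, config$fragment_length) else list(s)
      }), recursive = FALSE)
    }
    lapply(seqs, scan_sequence, mode = config$mode)
  }, error = function(e) on_fail("scan", e))
  baseline <- tryCatch(fit_quadratic_baseline(profiles),
                       error = function(e) on_fail("baseline", e))
  fit <- tryCatch(
    greedy_fit(profiles, mode = config$mode, max_k = config$max_k,
               theta_grid = config$theta_grid,
               candidates = config$candidates,
               baseline_rms = baseline$baseline_rms,
               min_rel_improvement = config$min_rel_improvement,
               control = config$control, verbose = verbose),
    error = function(e) on_fail("fit", e))

  if (!is.null(config$out_prefix)) {
    prov <- c(config_hash = config$hash, mode = config$mode,
              seed = config$seed)
    pf <- paste0(config$out_prefix, "_profiles.tsv")
    outputs <- c(outputs, pf)
    write_profiles_tsv(profiles, pf, provenance = prov)
    sf <- paste0(config$out_prefix, "_stages.tsv")
    outputs <- c(outputs, sf)
    write_stage_table(fit, sf, provenance = prov)
    jf <- paste0(config$out_prefix, "_fit.json")
    outputs <- c(outputs, jf)
    write_fit_json(fit, jf, config)
  }
  list(profiles = profiles, baseline = baseline, fit = fit, config = config)
}

# stagewise report: stage, factor, alias, value, kappa, rms, corrected error
write_stage_table <- function(fit, path, provenance = NULL) {
  n_stage <- length(fit$rms)
  df <- data.frame(
    stage = seq_len(n_stage) - 1L,
    factor = c("(kappa only)",
               if (nrow(fit$selected) > 0) fit$selected$factor),
    alias = c("", if (nrow(fit$selected) > 0) fit$selected$alias),
    value = c(NA, if (nrow(fit$selected) > 0) fit$selected$value),
    kappa = fit$kappa, rms = fit$rms,
    corrected_error = if (!is.null(fit$corrected_error))
      fit$corrected_error else rep(NA_real_, n_stage),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  utils::write.table(format(df, digits = 8, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a fit result (with its per-stage alternatives ledger) to JSON
#'
#' Selected factors are also reported under the greater-than-1 convention
#' via [canonicalize_factor()].
#'
#' @param fit a `fit_result` from [greedy_fit()].
#' @param path output JSON path.
#' @param config optional [run_config()] whose hash is embedded.
#' @return invisibly, the list written.
#' @export
write_fit_json <- function(fit, path, config = NULL) {
  reported <- if (nrow(fit$selected) > 0)
    lapply(seq_len(nrow(fit$selected)), function(r) {
      can <- canonicalize_factor(fit$selected$factor[r],
                                 fit$selected$value[r])
      list(stage = r, factor = fit$selected$factor[r],
           alias = fit$selected$alias[r], value = fit$selected$value[r],
           reported_factor = can$spec, reported_value = can$value,
           reciprocal_reported = can$reciprocal)
    }) else list()
  obj <- list(
    mode = fit$mode, M = fit$M, max_k = fit$max_k,
    kappa = fit$kappa, rms = fit$rms,
    baseline_rms = fit$baseline_rms,
    corrected_error = fit$corrected_error,
    selected = reported,
    alternatives = lapply(fit$alternatives, as.list),
    config_hash = if (!is.null(config)) config$hash else NULL)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(obj)
}

#' Generate simulator-backed FASTA fixtures with known truth
#'
#' Evolves sequences to equilibrium under each supplied factor set across a
#' theta gradient, writes one FASTA per factor set plus a truth JSON
#' recording the generating parameters (entries with value 1 are dropped as
#' inactive). Rerunning with a different seed changes the sequences but not
#' the recorded truth.
#'
#' @param dir output directory (created if needed).
#' @param theta_list theta values per factor set.
#' @param factor_sets named list of [factor_vector()] objects.
#' @param length sequence length per theta.
#' @param seed base random seed.
#' @param subs_per_site event budget per site.
#' @return invisibly, the truth list.
#' @export
make_fixtures <- function(dir, theta_list = c(0.3, 0.4, 0.5, 0.6, 0.7),
                          factor_sets, length = 50000, seed = 1,
                          subs_per_site = 30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(factor_sets)) || any(names(factor_sets) == ""))
    stop("factor_sets must be a named list")
  truth <- list()
  i <- 0
  for (nm in names(factor_sets)) {
    fv <- factor_sets[[nm]]
    stopifnot(inherits(fv, "factor_vector"))
    seqs <- lapply(seq_along(theta_list), function(t_i) {
      cfg <- simulation_config(length, theta_list[t_i], fv,
                               seed = seed + i * length(theta_list) + t_i - 1,
                               subs_per_site = subs_per_site)
      run <- evolve(cfg)
      s <- run$sequence
      s$id <- sprintf("%s_theta%.3f", nm, theta_list[t_i])
      s
    })
    i <- i + 1
    write_fasta(seqs, file.path(dir, paste0(nm, ".fasta")))
    act <- active_factors(fv)
    truth[[nm]] <- list(
      kappa = fv$kappa, mode = fv$mode, theta = theta_list,
      length = length,
      factors = if (nrow(act) > 0)
        stats::setNames(as.list(act$value), act$spec) else list())
  }
  truth_all <- list(seed = seed, subs_per_site = subs_per_site, sets = truth)
  writeLines(jsonlite::toJSON(truth_all, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(truth_all)
}
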