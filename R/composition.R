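#' Read sequences from a FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file. U is mapped
#' to the canonical internal T; letters outside A,C,G,T are kept as
#' ambiguity codes and break the dinucleotide window chain during scanning.
#'
#' @param path FASTA file path.
#' @param mode `"dna"` or `"rna"` (controls the expected-frequency
#'   convention used by [scan_sequence()] and display only).
#' @param min_length drop records shorter than this many bases (default 0;
#'   mRNA analyses conventionally use 2500).
#' @return list of `nuc_sequence` objects (fields `id`, `bases`, `mode`).
#' @export
read_fasta <- function(path, mode = c("dna", "rna"), min_length = 0) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  keep <- nchar(seqs) >= min_length
  if (!any(keep))
    stop("no records of length >= ", min_length, " in ", path)
  mapply(function(id, s) nuc_sequence(id, s, mode),
         ids[keep], seqs[keep], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Construct a nucleotide sequence object
#'
#' @param id record label.
#' @param bases string over A,C,G,T (U accepted and canonicalized to T;
#'   other letters are treated as ambiguous during scanning).
#' @param mode `"dna"` or `"rna"`.
#' @return object of class `nuc_sequence`.
#' @export
nuc_sequence <- function(id, bases, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  bases <- gsub("U", "T", toupper(paste(bases, collapse = "")), fixed = TRUE)
  if (nchar(bases) == 0) stop("sequence '", id, "' is empty")
  structure(list(id = as.character(id), bases = bases, mode = mode),
            class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  shown <- substr(x$bases, 1, 60)
  if (nchar(x$bases) > 60) shown <- paste0(shown, "...")
  cat(sprintf("<nuc_sequence> %s (%s, %d bases)\n%s\n",
              x$id, x$mode, nchar(x$bases), display_base(shown, x$mode)))
  invisible(x)
}

#' Construct a dinucleotide profile directly
#'
#' Mostly used by the scanner; exposed so synthetic profiles (e.g. points on
#' a known model curve) can be built in tests and simulations.
#'
#' @param gc G+C proportion in \[0, 1\].
#' @param ratios named numeric 16-vector of o/e ratios (names AA..TT;
#'   NA = undefined).
#' @param counts optional named integer 16-vector of dinucleotide counts.
#' @param length number of scored bases.
#' @param id record label.
#' @param mode `"dna"` or `"rna"`.
#' @return object of class `dinucleotide_profile`.
#' @export
dinucleotide_profile <- function(gc, ratios, counts = NULL, length = NA_integer_,
                                 id = "profile", mode = "dna") {
  stopifnot(gc >= 0, gc <= 1)
  ratios <- ratios[DINUCS]
  names(ratios) <- DINUCS
  if (is.null(counts)) counts <- stats::setNames(rep(NA_integer_, 16), DINUCS)
  else { counts <- counts[DINUCS]; names(counts) <- DINUCS }
  structure(list(id = id, gc = gc, length = length,
                 ratios = ratios, counts = counts, mode = mode),
            class = "dinucleotide_profile")
}

#' Scan a sequence into its dinucleotide composition profile
#'
#' Computes G+C content and the 16 observed/expected dinucleotide ratios.
#' Dinucleotides are counted in overlapping windows; windows spanning an
#' ambiguous base or a segment boundary are skipped. Expected frequencies:
#' in DNA mode the G+C-symmetric convention p_C = p_G = gc/2,
#' p_A = p_T = (1-gc)/2; in RNA mode the four observed mononucleotide
#' proportions. A ratio whose expected frequency is zero is returned as NA
#' (undefined).
#'
#' @param seq a [nuc_sequence()], a character string, or a character vector
#'   of segments (no windows are scored across segment boundaries — used
#'   e.g. for double-stranded scanning of a sequence plus its reverse
#'   complement).
#' @param mode `"dna"` or `"rna"`; defaults to the sequence's own mode.
#' @return a [dinucleotide_profile()].
#' @examples
#' p <- scan_sequence(nuc_sequence("ex", "ACGT"))
#' p$ratios[["CG"]]  # (1/3) / 0.0625
#' @export
scan_sequence <- function(seq, mode = NULL) {
  if (inherits(seq, "nuc_sequence")) {
    if (is.null(mode)) mode <- seq$mode
    id <- seq$id
    segments <- seq$bases
  } else {
    if (is.null(mode)) mode <- "dna"
    id <- "sequence"
    segments <- gsub("U", "T", toupper(as.character(seq)), fixed = TRUE)
  }
  mode <- match.arg(mode, c("dna", "rna"))
  segments <- gsub("[^ACGT]", "N", segments)
  dss <- Biostrings::DNAStringSet(segments)
  mono <- colSums(Biostrings::alphabetFrequency(dss)[, NUC, drop = FALSE])
  n_bases <- sum(mono)
  if (n_bases < 2)
    stop("sequence '", id, "' has fewer than 2 unambiguous bases")
  counts <- colSums(Biostrings::dinucleotideFrequency(dss))[DINUCS]
  gc <- unname((mono["C"] + mono["G"]) / n_bases)
  p <- if (mode == "dna")
    c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  else mono / n_bases
  expected <- dinuc_matrix_to_vector(outer(p, p))
  obs <- counts / max(sum(counts), 1)
  ratios <- ifelse(expected > 0, obs / expected, NA_real_)
  names(ratios) <- DINUCS
  dinucleotide_profile(gc = gc, ratios = ratios, counts = counts,
                       length = n_bases, id = id, mode = mode)
}

#' Scan a DNA sequence together with its reverse complement
#'
#' Double-stranded scanning: counts from the sequence and its reverse
#' complement are pooled (no window is scored across the strand boundary),
#' so o/e(XY) equals o/e(Y'X') exactly.
#'
#' @param seq a [nuc_sequence()] or character string.
#' @return a [dinucleotide_profile()] in DNA mode.
#' @export
scan_double_stranded <- function(seq) {
  bases <- if (inherits(seq, "nuc_sequence")) seq$bases else
    gsub("U", "T", toupper(as.character(seq)), fixed = TRUE)
  id <- if (inherits(seq, "nuc_sequence")) seq$id else "sequence"
  bases <- gsub("[^ACGT]", "N", bases)
  p <- scan_sequence(c(bases, reverse_complement(bases)), mode = "dna")
  p$id <- id
  p
}

#' Split a sequence into consecutive fragments
#'
#' Non-overlapping fragments of `fragment_length` bases; a trailing
#' remainder shorter than half the fragment length is discarded, longer
#' remainders are kept as a final short fragment.
#'
#' @param seq a [nuc_sequence()].
#' @param fragment_length fragment size in bases, at least 100 (genomic
#'   analyses conventionally use 50,000).
#' @return list of `nuc_sequence` fragments with ids `<id>_frag<k>`.
#' @export
fragment_sequence <- function(seq, fragment_length = 50000) {
  stopifnot(inherits(seq, "nuc_sequence"))
  if (fragment_length < 100) stop("fragment_length must be at least 100")
  L <- nchar(seq$bases)
  if (L < fragment_length)
    stop("sequence '", seq$id, "' (", L,
         " bases) is shorter than fragment_length = ", fragment_length)
  n_full <- L %/% fragment_length
  rem <- L - n_full * fragment_length
  starts <- seq(1, by = fragment_length, length.out = n_full)
  ends <- starts + fragment_length - 1
  if (rem >= fragment_length / 2) {
    starts <- c(starts, n_full * fragment_length + 1)
    ends <- c(ends, L)
  }
  lapply(seq_along(starts), function(kk) {
    nuc_sequence(paste0(seq$id, "_frag", kk),
                 substr(seq$bases, starts[kk], ends[kk]), seq$mode)
  })
}

# ---- quadratic baselines --------------------------------------------------

#' Per-dinucleotide quadratic baseline fit
#'
#' Fits, for each dinucleotide, an ordinary least-squares quadratic
#' R ~ a0 + a1 omega + a2 omega^2 through the profiles' o/e ratios as a
#' function of their G+C content. The residual RMS of these 16 independent
#' best-possible smooth fits is the irreducible scatter of the data; it is
#' normalized exactly like the model RMS (denominator = number of included
#' (profile, dinucleotide) terms, 16N when no ratio is undefined) so that
#' model RMS minus baseline RMS is a like-for-like model error.
#'
#' @param profiles list of [dinucleotide_profile()] with at least 3 distinct
#'   G+C values.
#' @return object of class `quadratic_baseline`: list with `coefficients`
#'   (16 x 3 matrix, columns a0, a1, a2) and `baseline_rms`.
#' @export
fit_quadratic_baseline <- function(profiles) {
  stopifnot(length(profiles) >= 3)
  gc <- vapply(profiles, function(p) p$gc, numeric(1))
  if (length(unique(round(gc, 12))) < 3)
    stop("quadratic baseline needs at least 3 distinct G+C values")
  R <- t(vapply(profiles, function(p) p$ratios, numeric(16)))
  X <- cbind(1, gc, gc^2)
  coef <- matrix(NA_real_, 16, 3,
                 dimnames = list(DINUCS, c("a0", "a1", "a2")))
  ss <- 0; nterms <- 0L
  for (col in seq_len(16)) {
    ok <- !is.na(R[, col])
    if (sum(ok) >= 3) {
      fit <- stats::lm.fit(X[ok, , drop = FALSE], R[ok, col])
      coef[col, ] <- fit$coefficients
      ss <- ss + sum(fit$residuals^2)
      nterms <- nterms + sum(ok)
    }
  }
  if (nterms == 0) stop("no defined o/e ratios to fit")
  structure(list(coefficients = coef, baseline_rms = sqrt(ss / nterms)),
            class = "quadratic_baseline")
}

#' Evaluate a quadratic baseline at given G+C values
#'
#' @param baseline a [fit_quadratic_baseline()] result.
#' @param omega numeric vector of G+C proportions.
#' @return length(omega) x 16 matrix of baseline o/e values.
#' @export
predict_baseline <- function(baseline, omega) {
  stopifnot(inherits(baseline, "quadratic_baseline"))
  X <- cbind(1, omega, omega^2)
  out <- X %*% t(baseline$coefficients)
  colnames(out) <- DINUCS
  out
}

# ---- sampling-error model -------------------------------------------------

#' Fit the empirical RMS-versus-length relationship
#'
#' Models the dependence of composition RMS on sequence length as
#' RMS(L) = a / L^b + c by nonlinear least squares with all three
#' parameters constrained nonnegative. The intercept c is the model error
#' remaining for fragments of infinite length, i.e. not attributable to
#' sampling.
#'
#' @param lengths positive sequence lengths (>= 4 values).
#' @param rms_values RMS distances observed at those lengths.
#' @return object of class `sampling_error_fit` with fields `a`, `b`, `c`.
#' @export
fit_sampling_error <- function(lengths, rms_values) {
  stopifnot(length(lengths) == length(rms_values))
  if (length(lengths) < 4)
    stop("at least 4 (length, RMS) pairs are required")
  if (any(lengths <= 0)) stop("lengths must be positive")
  df <- data.frame(L = as.numeric(lengths), y = as.numeric(rms_values))
  if (stats::sd(df$y) < 1e-12)          # constant RMS: no length dependence
    return(structure(list(a = 0, b = 0.5, c = mean(df$y)),
                     class = "sampling_error_fit"))
  c0 <- max(min(df$y) * 0.9, 0)
  pos <- df$y - c0 > 0
  slope <- if (sum(pos) >= 2)
    stats::coef(stats::lm(log(df$y[pos] - c0) ~ log(df$L[pos]))) else c(0, -0.5)
  starts <- list(
    list(a = exp(slope[[1]]), b = max(-slope[[2]], 0.05), c = c0),
    list(a = 1, b = 0.5, c = c0),
    list(a = max(df$y) * min(df$L)^0.4, b = 0.4, c = 0)
  )
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / L^b + c, data = df, start = st,
                        lower = c(a = 0, b = 0, c = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      cf <- stats::coef(fit)
      return(structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                            c = unname(cf["c"])),
                       class = "sampling_error_fit"))
    }
    last_err <- conditionMessage(fit)
  }
  stop("sampling-error fit did not converge after restarts: ", last_err)
}

#' Evaluate the sampling-error model at a sequence length
#'
#' @param fit a [fit_sampling_error()] result (or list with a, b, c).
#' @param length positive sequence length(s).
#' @return predicted RMS value a / length^b + c.
#' @examples
#' fit <- structure(list(a = 2.2, b = 0.42, c = 0.0095),
#'                  class = "sampling_error_fit")
#' evaluate_sampling_error(fit, 50000)  # ~0.0329
#' @export
evaluate_sampling_error <- function(fit, length) {
  if (any(length <= 0)) stop("length must be positive")
  fit$a / length^fit$b + fit$c
}

#' @export
print.sampling_error_fit <- function(x, ...) {
  cat(sprintf("RMS(L) = %.4g / L^%.4g + %.4g\n", x$a, x$b, x$c))
  invisible(x)
}

#' Write scan profiles to TSV
#'
#' Columns: id, length, gc, then the 16 o/e ratios in alphabetical
#' dinucleotide order, printed to 6 decimal places.
#'
#' @param profiles list of [dinucleotide_profile()].
#' @param path output file path.
#' @param provenance optional named character vector written as
#'   `# key=value` header comments.
#' @return invisibly, the data frame written.
#' @export
write_profiles_tsv <- function(profiles, path, provenance = NULL) {
  df <- profiles_to_df(profiles)
  df$gc <- sprintf("%.6f", df$gc)
  for (dn in DINUCS) df[[dn]] <- sprintf("%.6f", df[[dn]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

profiles_to_df <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    row <- data.frame(id = p$id, length = p$length, gc = p$gc,
                      stringsAsFactors = FALSE)
    for (dn in DINUCS) row[[dn]] <- unname(p$ratios[dn])
    row
  }))
}

#' Read scan profiles from a TSV written by [write_profiles_tsv()]
#'
#' @param path TSV path.
#' @param mode profile mode label.
#' @return list of [dinucleotide_profile()].
#' @export
read_profiles_tsv <- function(path, mode = "dna") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(r) {
    ratios <- as.numeric(df[r, DINUCS])
    names(ratios) <- DINUCS
    dinucleotide_profile(gc = df$gc[r], ratios = ratios,
                         length = df$length[r], id = df$id[r], mode = mode)
  })
}
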