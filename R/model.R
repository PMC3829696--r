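#' Default substitution rate matrix
#'
#' The context-free rate matrix: substitutions toward C or G occur at rate
#' `theta`, toward A or T at rate `1 - theta`, with transitions
#' (A<->G, C<->T) multiplied by `kappa`. With all context factors equal to 1
#' this process has stationary mononucleotide proportions
#' C = G = `theta`/2, A = T = `(1 - theta)`/2, so `theta` is the equilibrium
#' G+C content of the default model. Rates are unnormalized: only the
#' equilibrium is meaningful and the overall time scale is arbitrary.
#'
#' @param theta equilibrium G+C proportion of the default process, in (0,1).
#' @param kappa transition/transversion rate ratio, > 0.
#' @return 4x4 numeric matrix with rows = "from" and columns = "to"
#'   nucleotide (A, C, G, T); the diagonal is 0 (unused).
#' @examples
#' default_rates(0.5, 2.1)
#' @export
default_rates <- function(theta, kappa) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta >= 1)
    stop("theta must be a single number in (0, 1)")
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("kappa must be a single positive number")
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (j in 1:4) for (l in 1:4) {
    if (j == l) next
    base <- if (NUC[l] %in% c("C", "G")) theta else 1 - theta
    Q[j, l] <- if (abs(j - l) == 2) kappa * base else base
  }
  Q
}

# ---- context factor vectors ----------------------------------------------

#' Create a context-dependent factor vector
#'
#' Holds kappa together with the multiplicative context factors
#' f(X, Y->W) (upstream neighbor X) and f(Y->W, Z) (downstream neighbor Z),
#' 96 factors in all, defaulting to 1. In `"dna"` mode the strand-symmetry
#' constraint f(X, Y->W) = f(Y'->W', X') (primes = complements) is enforced,
#' leaving 48 free factors; `"rna"` mode keeps all 96 free.
#'
#' Factors are addressed by spec strings: `"C,G>A"` is the upstream factor
#' f(C, G->A) and `"C>T,G"` is the downstream factor f(C->T, G) (C mutating
#' to T when followed by G — the CpG methylation-deamination context). U is
#' accepted as an alias for T.
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param mode `"dna"` (strand-symmetric) or `"rna"` (all factors free).
#' @param factors optional named numeric vector of factor spec -> value,
#'   applied via [set_factor()].
#' @return an object of class `factor_vector`.
#' @examples
#' fv <- factor_vector(kappa = 3, mode = "dna", factors = c("C>T,G" = 12))
#' get_factor(fv, "C,G>A")  # strand-symmetric partner, also 12
#' @export
factor_vector <- function(kappa = 1, mode = c("dna", "rna"), factors = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0)
    stop("kappa must be a single positive number")
  fv <- structure(list(
    kappa = kappa,
    up = matrix(1, 4, 12, dimnames = list(NUC, MUTATION_IDS)),
    down = matrix(1, 12, 4, dimnames = list(MUTATION_IDS, NUC)),
    mode = mode
  ), class = "factor_vector")
  if (!is.null(factors)) {
    if (is.null(names(factors))) stop("factors must be a named vector")
    for (spec in names(factors)) fv <- set_factor(fv, spec, factors[[spec]])
  }
  fv
}

# parse "X,Y>W" (up) or "Y>W,Z" (down) into list(side, base, from, to)
parse_factor_spec <- function(spec) {
  s <- gsub("U", "T", toupper(gsub("[[:space:]]", "", spec)))
  m_up <- regmatches(s, regexec("^([ACGT]),([ACGT])>([ACGT])$", s))[[1]]
  if (length(m_up) == 4)
    return(list(side = "up", base = m_up[2], from = m_up[3], to = m_up[4]))
  m_dn <- regmatches(s, regexec("^([ACGT])>([ACGT]),([ACGT])$", s))[[1]]
  if (length(m_dn) == 4)
    return(list(side = "down", base = m_dn[4], from = m_dn[2], to = m_dn[3]))
  stop("cannot parse factor spec '", spec,
       "' (expected 'X,Y>W' for upstream or 'Y>W,Z' for downstream context)")
}

format_factor_spec <- function(entry) {
  if (entry$side == "up") paste0(entry$base, ",", entry$from, ">", entry$to)
  else paste0(entry$from, ">", entry$to, ",", entry$base)
}

# strand-symmetric partner: up f(X, Y->W) <-> down f(Y'->W', X')
strand_partner <- function(entry) {
  if (entry$side == "up")
    list(side = "down", base = complement_base(entry$base),
         from = complement_base(entry$from), to = complement_base(entry$to))
  else
    list(side = "up", base = complement_base(entry$base),
         from = complement_base(entry$from), to = complement_base(entry$to))
}

#' Set or read one context factor
#'
#' In DNA mode [set_factor()] also sets the strand-symmetric partner entry,
#' keeping the 48-parameter constraint satisfied.
#'
#' @param fv a [factor_vector()].
#' @param spec factor spec string, e.g. `"C>T,G"` or `"A,C>T"`.
#' @param value positive factor value.
#' @return `set_factor`: the modified factor vector; `get_factor`: the value.
#' @export
set_factor <- function(fv, spec, value) {
  stopifnot(inherits(fv, "factor_vector"))
  if (!is.numeric(value) || length(value) != 1 || value <= 0)
    stop("factor value must be a single positive number")
  entry <- parse_factor_spec(spec)
  fv <- set_entry(fv, entry, value)
  if (fv$mode == "dna") fv <- set_entry(fv, strand_partner(entry), value)
  fv
}

set_entry <- function(fv, entry, value) {
  mi <- mutation_index(entry$from, entry$to)
  if (entry$side == "up") fv$up[entry$base, mi] <- value
  else fv$down[mi, entry$base] <- value
  fv
}

#' @rdname set_factor
#' @export
get_factor <- function(fv, spec) {
  stopifnot(inherits(fv, "factor_vector"))
  entry <- parse_factor_spec(spec)
  mi <- mutation_index(entry$from, entry$to)
  if (entry$side == "up") fv$up[entry$base, mi] else fv$down[mi, entry$base]
}

#' @export
print.factor_vector <- function(x, ...) {
  cat("Context-dependent factor vector (", toupper(x$mode), " mode)\n",
      sep = "")
  cat("  kappa =", format(x$kappa), "\n")
  act <- active_factors(x)
  if (nrow(act) == 0) cat("  all context factors at default 1\n")
  else {
    cat("  non-default factors:\n")
    for (r in seq_len(nrow(act)))
      cat(sprintf("    %-8s = %g\n", act$spec[r], act$value[r]))
  }
  invisible(x)
}

# data.frame of entries differing from 1 (DNA mode: canonical free set only,
# i.e. the 48 upstream entries)
active_factors <- function(fv, tol = 1e-12) {
  out <- list()
  for (X in NUC) for (mi in seq_len(12)) {
    v <- fv$up[X, mi]
    if (abs(v - 1) > tol)
      out[[length(out) + 1]] <- data.frame(
        spec = paste0(X, ",", MUTATION_IDS[mi]), side = "up",
        base = X, from = MUTATIONS$from[mi], to = MUTATIONS$to[mi], value = v,
        stringsAsFactors = FALSE)
  }
  if (fv$mode == "rna") {
    for (mi in seq_len(12)) for (Z in NUC) {
      v <- fv$down[mi, Z]
      if (abs(v - 1) > tol)
        out[[length(out) + 1]] <- data.frame(
          spec = paste0(MUTATION_IDS[mi], ",", Z), side = "down",
          base = Z, from = MUTATIONS$from[mi], to = MUTATIONS$to[mi],
          value = v, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(spec = character(), side = character(),
                      base = character(), from = character(),
                      to = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Candidate factor identifiers for model selection
#'
#' In DNA mode the candidates are the 48 strand-symmetric factor pairs, each
#' named by its upstream member `"X,Y>W"` (setting one sets both entries).
#' In RNA mode all 96 upstream and downstream factors are free candidates.
#'
#' @param mode `"dna"` or `"rna"`.
#' @return character vector of factor spec strings.
#' @export
candidate_set <- function(mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  up <- as.vector(t(outer(NUC, MUTATION_IDS, function(x, m) paste0(x, ",", m))))
  up <- sort(up)
  if (mode == "dna") return(up)
  down <- sort(as.vector(t(outer(MUTATION_IDS, NUC,
                                 function(m, z) paste0(m, ",", z)))))
  c(up, down)
}

# ---- rates ----------------------------------------------------------------

#' Context-dependent substitution rate
#'
#' Rate of the substitution Y->W inside trinucleotide XYZ:
#' `f(X, Y->W) * Q_YW * f(Y->W, Z)`, the two neighbor factors acting
#' multiplicatively and independently on the default rate.
#'
#' @param fv a [factor_vector()].
#' @param x,y,w,z nucleotides (upstream, from, to, downstream).
#' @param theta equilibrium G+C parameter of the default matrix.
#' @return nonnegative rate.
#' @examples
#' fv <- factor_vector(kappa = 2.1, factors = c("C>T,G" = 27.6 / 2.1))
#' context_rate(fv, "A", "C", "T", "G", theta = 0.5)  # 27.6 * (1 - 0.5)
#' @export
context_rate <- function(fv, x, y, w, z, theta) {
  stopifnot(inherits(fv, "factor_vector"))
  x <- gsub("U", "T", toupper(x)); y <- gsub("U", "T", toupper(y))
  w <- gsub("U", "T", toupper(w)); z <- gsub("U", "T", toupper(z))
  if (y == w) stop("from and to nucleotides must differ")
  Q <- default_rates(theta, fv$kappa)
  mi <- mutation_index(y, w)
  fv$up[x, mi] * Q[y, w] * fv$down[mi, z]
}

# full rate tensor r[i, j, l, k] (A,C,G,T indices), flattened for the
# compiled core; zero where j == l
rate_array <- function(fv, theta) {
  dc_rate_array(fv$up, fv$down, fv$kappa, theta)
}

# ---- change count ---------------------------------------------------------

#' Dinucleotide change count for a trinucleotide substitution event
#'
#' When trinucleotide ijk mutates at its middle base to ilk, the number of
#' copies of a target dinucleotide xy changes by the number of occurrences
#' of xy in ilk minus the number in ijk (overlapping occurrences within the
#' trinucleotide are counted). The result is always in -2..2.
#'
#' @param target length-2 character vector `c(x, y)` or string `"xy"`.
#' @param event length-4 character vector `c(i, j, l, k)` (trinucleotide
#'   ijk with its middle base mutating j -> l) or a list with those names.
#' @return integer in \{-2, -1, 0, 1, 2\}.
#' @examples
#' change_count(c("C", "A"), c("C", "A", "T", "G"))  # CAG -> CTG loses a CpA
#' change_count("TT", c("T", "C", "T", "T"))         # TCT -> TTT gains two TpT
#' @export
change_count <- function(target, event) {
  if (length(target) == 1) target <- strsplit(target, "")[[1]]
  target <- gsub("U", "T", toupper(target))
  event <- gsub("U", "T", toupper(unlist(event, use.names = FALSE)))
  if (length(target) != 2 || length(event) != 4)
    stop("target must be a dinucleotide and event a (i, j, l, k) quadruple")
  if (!all(c(target, event) %in% NUC)) stop("invalid nucleotide in input")
  i <- event[1]; j <- event[2]; l <- event[3]; k <- event[4]
  if (j == l) stop("event must change the middle base (j != l)")
  occurrences <- function(mid) {
    sum(identical(c(i, mid), target), identical(c(mid, k), target))
  }
  as.integer(occurrences(l) - occurrences(j))
}

#' Time derivative of the dinucleotide proportions
#'
#' Under the trinucleotide-independence approximation (the proportion of
#' trinucleotide ijk is d_ij d_jk / m_j), each substitution event
#' (i, j->l, k) occurs with flux t_ijk * r(i, j->l, k) and changes the
#' dinucleotide counts by +1 for il and lk and -1 for ij and jk. Terms with
#' m_j below 1e-14 contribute 0 (removable singularity).
#'
#' @param d 4x4 matrix (or 16-vector in AA, AC, ..., TT order) of
#'   dinucleotide proportions summing to 1 with consistent margins.
#' @param theta default-matrix G+C parameter.
#' @param fv a [factor_vector()].
#' @param check if TRUE (default), margin consistency of `d` is verified.
#' @return 4x4 matrix of time derivatives (rows = first base).
#' @export
composition_derivative <- function(d, theta, fv, check = TRUE) {
  d <- as_dinuc_matrix(d)
  if (check) {
    if (abs(sum(d) - 1) > 1e-6) stop("dinucleotide proportions must sum to 1")
    if (max(abs(rowSums(d) - colSums(d))) > 1e-6)
      stop("inconsistent margins: row sums must equal column sums")
  }
  dd <- dc_deriv(as.vector(d), rate_array(fv, theta))
  matrix(dd, 4, 4, dimnames = list(NUC, NUC))
}

as_dinuc_matrix <- function(d) {
  if (is.matrix(d)) {
    stopifnot(all(dim(d) == c(4, 4)))
    dimnames(d) <- list(NUC, NUC)
    return(d)
  }
  stopifnot(length(d) == 16)
  if (!is.null(names(d))) d <- d[DINUCS]
  # DINUCS order is row-major (AA, AC, ...): fill by row
  matrix(d, 4, 4, byrow = TRUE, dimnames = list(NUC, NUC))
}

dinuc_matrix_to_vector <- function(m) {
  v <- as.vector(t(m))
  names(v) <- DINUCS
  v
}

# ---- equilibrium ----------------------------------------------------------

#' Equilibrium dinucleotide composition of the context-dependent model
#'
#' Integrates the 16 coupled dinucleotide equations from the independent
#' product composition at the default-model stationary proportions
#' (C = G = theta/2) until the proportions stabilize, then polishes the
#' stationary point with a constrained Newton pass.
#'
#' @param theta default-matrix G+C parameter in (0,1).
#' @param fv a [factor_vector()].
#' @param tol convergence tolerance on the maximum absolute time derivative.
#' @return object of class `equilibrium_state`: list with `d` (4x4
#'   dinucleotide proportions), `m` (mononucleotide proportions), `omega`
#'   (equilibrium G+C), `oe` (named 16-vector of model o/e ratios
#'   d_XY / (m_X m_Y)), `theta`, `factors`, `residual`.
#' @examples
#' eq <- equilibrium(0.5, factor_vector(kappa = 3,
#'                                      factors = c("C>T,G" = 12)))
#' eq$oe[["CG"]]  # CpG suppressed below 1
#' @export
equilibrium <- function(theta, fv, tol = 1e-10) {
  stopifnot(inherits(fv, "factor_vector"))
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  p <- stationary_mono(theta)
  d0 <- outer(p, p)
  res <- dc_equilibrium(rate_array(fv, theta), as.vector(d0), tol = tol)
  if (!isTRUE(res$converged))
    stop(sprintf(
      "equilibrium solve did not converge (residual %.3g at theta = %g)",
      res$residual, theta))
  d <- matrix(res$d, 4, 4, dimnames = list(NUC, NUC))
  m <- (rowSums(d) + colSums(d)) / 2
  oe <- dinuc_matrix_to_vector(d / outer(m, m))
  structure(list(d = d, m = m, omega = unname(m["C"] + m["G"]),
                 oe = oe, theta = theta, factors = fv,
                 residual = res$residual),
            class = "equilibrium_state")
}

stationary_mono <- function(theta) {
  c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2, T = (1 - theta) / 2)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "Equilibrium state: theta = %g, omega (G+C) = %.6f, residual = %.2g\n",
    x$theta, x$omega, x$residual))
  cat("o/e ratios:\n")
  print(round(x$oe, 4))
  invisible(x)
}

# ---- model curve ----------------------------------------------------------

#' Default theta grid for model curve tabulation
#'
#' 46 points from 0.05 to 0.95 in steps of 0.02, spanning the G+C range of
#' typical genomic data (roughly 20--80%) with margin.
#' @return numeric vector.
#' @export
default_theta_grid <- function() seq(0.05, 0.95, by = 0.02)

#' Tabulate model o/e ratios over a theta grid
#'
#' Solves the equilibrium once per grid point and stores the resulting
#' (omega, 16 o/e ratios) pairs. The curve supports interpolation of the
#' model prediction M_XY(omega, F) at any observed G+C content within the
#' tabulated omega range via [predict_curve()].
#'
#' @param fv a [factor_vector()].
#' @param theta_grid strictly increasing grid inside (0,1), at least 10
#'   points.
#' @param tol equilibrium tolerance passed to [equilibrium()].
#' @return object of class `model_curve`: list with `omega` (vector), `M`
#'   (length(grid) x 16 matrix of o/e ratios, columns in AA..TT order),
#'   `theta_grid`, `factors`.
#' @export
build_curve <- function(fv, theta_grid = default_theta_grid(), tol = 1e-10) {
  stopifnot(inherits(fv, "factor_vector"))
  if (length(theta_grid) < 10) stop("theta grid must have at least 10 points")
  if (any(diff(theta_grid) <= 0)) stop("theta grid must be strictly increasing")
  if (min(theta_grid) <= 0 || max(theta_grid) >= 1)
    stop("theta grid must lie inside (0, 1)")
  omega <- numeric(length(theta_grid))
  M <- matrix(NA_real_, length(theta_grid), 16,
              dimnames = list(NULL, DINUCS))
  for (g in seq_along(theta_grid)) {
    eq <- equilibrium(theta_grid[g], fv, tol = tol)
    omega[g] <- eq$omega
    M[g, ] <- eq$oe
  }
  if (any(diff(omega) <= 0))
    stop("equilibrium G+C is not strictly increasing over the theta grid; ",
         "interpolation in omega is ill-posed for this factor vector")
  structure(list(omega = omega, M = M, theta_grid = theta_grid, factors = fv),
            class = "model_curve")
}

#' Interpolate model o/e ratios at an observed G+C content
#'
#' Piecewise-linear interpolation in omega, per dinucleotide; exact at the
#' stored grid points. No extrapolation: omega outside the tabulated range
#' is an error.
#'
#' @param curve a [build_curve()] result.
#' @param omega observed G+C proportion(s) within the curve's omega range.
#' @return if one omega, a named 16-vector; otherwise a length(omega) x 16
#'   matrix.
#' @export
predict_curve <- function(curve, omega) {
  stopifnot(inherits(curve, "model_curve"))
  rng <- range(curve$omega)
  bad <- omega < rng[1] | omega > rng[2]
  if (any(bad))
    stop(sprintf(
      "omega %s outside the tabulated range [%.4f, %.4f]; extend the theta grid",
      paste(format(omega[bad]), collapse = ", "), rng[1], rng[2]))
  out <- vapply(seq_len(16), function(col) {
    stats::approx(curve$omega, curve$M[, col], xout = omega)$y
  }, numeric(length(omega)))
  if (length(omega) == 1) {
    out <- as.vector(out)
    names(out) <- DINUCS
    out
  } else {
    out <- matrix(out, nrow = length(omega), dimnames = list(NULL, DINUCS))
    out
  }
}

#' @export
print.model_curve <- function(x, ...) {
  cat(sprintf(
    "Model o/e curve: %d theta grid points, omega in [%.4f, %.4f]\n",
    length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}
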