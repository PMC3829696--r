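#' Read SNP records from TSV
#'
#' Expects four columns: reference base, alternate base, 5' flanking base,
#' 3' flanking base (header optional; extra columns ignored). Rows with
#' ref == alt or letters outside A,C,G,T are rejected with a per-line
#' diagnostic; the number of rejects is reported as an attribute.
#'
#' @param path TSV file path.
#' @return data frame with columns ref, alt, five_prime, three_prime and
#'   attribute `n_rejected`.
#' @export
read_snp_tsv <- function(path) {
  if (!file.exists(path)) stop("SNP file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (toupper(raw[1, 1]) %in% c("REF", "REFERENCE")) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) < 4) stop("SNP TSV needs 4 columns: ref, alt, 5' base, 3' base")
  df <- data.frame(ref = toupper(raw[[1]]), alt = toupper(raw[[2]]),
                   five_prime = toupper(raw[[3]]),
                   three_prime = toupper(raw[[4]]), stringsAsFactors = FALSE)
  valid <- df$ref %in% NUC & df$alt %in% NUC & df$five_prime %in% NUC &
    df$three_prime %in% NUC & df$ref != df$alt
  if (any(!valid)) {
    bad <- which(!valid)
    warning(length(bad), " malformed SNP record(s) rejected (lines ",
            paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "", ")")
  }
  out <- df[valid, , drop = FALSE]
  if (nrow(out) == 0) stop("no valid SNP records in ", path)
  attr(out, "n_rejected") <- sum(!valid)
  out
}

#' Tally SNPs by mutation type and 3' flanking base
#'
#' @param records data frame with columns ref, alt, three_prime (e.g. from
#'   [read_snp_tsv()] or the simulator's event records).
#' @return object of class `context_spectrum` with `counts` (12 x 4 integer
#'   matrix: rows = mutation types Y>W, columns = 3' base) and `totals`
#'   (per-type row sums); enrichments are added by [normalize_spectrum()].
#' @export
tally_snp_contexts <- function(records) {
  stopifnot(nrow(records) >= 1)
  ok <- records$ref %in% NUC & records$alt %in% NUC &
    records$three_prime %in% NUC & records$ref != records$alt
  if (any(!ok)) {
    warning(sum(!ok), " malformed record(s) dropped in tally")
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no valid records to tally")
  type <- factor(paste0(records$ref, ">", records$alt), levels = MUTATION_IDS)
  ctx <- factor(records$three_prime, levels = NUC)
  counts <- table(type, ctx)
  counts <- matrix(as.integer(counts), 12, 4,
                   dimnames = list(MUTATION_IDS, NUC))
  structure(list(counts = counts, totals = rowSums(counts),
                 enrichment = NULL, dinuc_freqs = NULL),
            class = "context_spectrum")
}

#' Normalize a context spectrum to expected frequencies
#'
#' For each mutation type Y>W and 3' base Z the expected count is
#' `total(Y>W) * freq(YZ) / sum_Z' freq(YZ')` — the context distribution a
#' context-blind mutation process would produce given the genome's
#' dinucleotide composition — and the enrichment is observed/expected. The
#' per-type totals cancel any overall transition/transversion skew by
#' construction, so a context-independent process yields enrichment 1
#' everywhere. Enrichments are invariant to global rescaling of
#' `dinuc_freqs`.
#'
#' @param spectrum a [tally_snp_contexts()] result.
#' @param dinuc_freqs named 16-vector of genome dinucleotide frequencies
#'   (names AA..TT; any positive scale).
#' @return the spectrum with `enrichment` (12 x 4 matrix) and `expected`
#'   filled in. A zero expected count with nonzero observed count yields an
#'   infinite enrichment, flagged with a warning.
#' @export
normalize_spectrum <- function(spectrum, dinuc_freqs) {
  stopifnot(inherits(spectrum, "context_spectrum"))
  dinuc_freqs <- dinuc_freqs[DINUCS]
  if (anyNA(dinuc_freqs)) stop("dinuc_freqs must cover all 16 dinucleotides")
  if (any(dinuc_freqs < 0)) stop("dinucleotide frequencies must be >= 0")
  fmat <- as_dinuc_matrix(dinuc_freqs)   # fmat[Y, Z] = freq(YZ)
  expected <- matrix(0, 12, 4, dimnames = list(MUTATION_IDS, NUC))
  for (mi in seq_len(12)) {
    Y <- MUTATIONS$from[mi]
    ctx_freq <- fmat[Y, ]
    tot_f <- sum(ctx_freq)
    if (tot_f <= 0) next
    expected[mi, ] <- spectrum$totals[mi] * ctx_freq / tot_f
  }
  enrichment <- ifelse(expected > 0, spectrum$counts / expected,
                       ifelse(spectrum$counts > 0, Inf, 0))
  dimnames(enrichment) <- dimnames(expected)
  if (any(is.infinite(enrichment)))
    warning("observed mutations in context(s) with zero expected frequency; ",
            "enrichment reported as Inf")
  spectrum$expected <- expected
  spectrum$enrichment <- enrichment
  spectrum$dinuc_freqs <- dinuc_freqs
  spectrum
}

#' @export
print.context_spectrum <- function(x, ...) {
  cat("SNP 3' dinucleotide-context spectrum\n")
  cat(sprintf("  %d records over 12 mutation types\n", sum(x$counts)))
  if (!is.null(x$enrichment)) {
    cat("  enrichment (observed / context-blind expected):\n")
    print(round(x$enrichment, 3))
  } else {
    print(x$counts)
  }
  invisible(x)
}

#' Write enrichment spectrum to TSV
#'
#' Rows = 12 mutation types, columns = 4 downstream contexts, values =
#' enrichment to 3 decimal places.
#'
#' @param spectrum a normalized [normalize_spectrum()] result.
#' @param path output path.
#' @param provenance optional named vector of `# key=value` header comments.
#' @return invisibly, the matrix written.
#' @export
write_spectrum_tsv <- function(spectrum, path, provenance = NULL) {
  if (is.null(spectrum$enrichment))
    stop("spectrum has no enrichments; run normalize_spectrum() first")
  df <- data.frame(mutation = rownames(spectrum$enrichment),
                   stringsAsFactors = FALSE)
  for (z in NUC) df[[z]] <- sprintf("%.3f", spectrum$enrichment[, z])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(spectrum$enrichment)
}

#' Read genome dinucleotide frequencies from TSV
#'
#' Two columns: dinucleotide, frequency (header optional).
#'
#' @param path TSV path.
#' @return named 16-vector in AA..TT order.
#' @export
read_dinuc_freqs_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!toupper(raw[1, 1]) %in% DINUCS) raw <- raw[-1, , drop = FALSE]
  freqs <- stats::setNames(as.numeric(raw[[2]]), toupper(raw[[1]]))
  missing <- setdiff(DINUCS, names(freqs))
  if (length(missing) > 0)
    stop("dinucleotide frequencies missing for: ",
         paste(missing, collapse = ", "))
  freqs[DINUCS]
}
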