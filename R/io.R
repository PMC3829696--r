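#' Serialize a factor vector to JSON
#'
#' Format: `{"kappa": x, "mode": "dna"|"rna", "factors": [{"context":
#' "up"|"down", "base": ..., "from": ..., "to": ..., "value": ...}, ...]}`.
#' Only non-default entries are written; in DNA mode the listing is
#' canonicalized to the 48 free upstream entries.
#'
#' @param fv a [factor_vector()].
#' @param path output path; if NULL the JSON string is returned.
#' @return invisibly the JSON string (or the string itself if `path` is
#'   NULL).
#' @export
write_factor_json <- function(fv, path = NULL) {
  stopifnot(inherits(fv, "factor_vector"))
  act <- active_factors(fv)
  factors <- lapply(seq_len(nrow(act)), function(r)
    list(context = act$side[r], base = act$base[r], from = act$from[r],
         to = act$to[r], value = act$value[r]))
  obj <- list(kappa = fv$kappa, mode = fv$mode, factors = factors)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Read a factor vector from JSON
#'
#' @param path JSON file path (or a JSON string).
#' @return a [factor_vector()].
#' @export
read_factor_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(obj$kappa) || is.null(obj$mode))
    stop("factor JSON must contain 'kappa' and 'mode'")
  fv <- factor_vector(kappa = obj$kappa, mode = obj$mode)
  for (f in obj$factors) {
    entry <- list(side = match.arg(f$context, c("up", "down")),
                  base = toupper(f$base),
                  from = gsub("U", "T", toupper(f$from)),
                  to = gsub("U", "T", toupper(f$to)))
    fv <- set_factor(fv, format_factor_spec(entry), f$value)
  }
  fv
}

#' Write a tabulated model curve to TSV
#'
#' Columns: theta, omega, then the 16 model o/e ratios in alphabetical
#' dinucleotide order.
#'
#' @param curve a [build_curve()] result.
#' @param path output path.
#' @param provenance optional named vector of `# key=value` header comments.
#' @return invisibly, the data frame written.
#' @export
write_curve_tsv <- function(curve, path, provenance = NULL) {
  stopifnot(inherits(curve, "model_curve"))
  df <- data.frame(theta = curve$theta_grid, omega = curve$omega)
  for (dn in DINUCS) df[[dn]] <- curve$M[, dn]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write sequences to FASTA
#'
#' @param seqs list of [nuc_sequence()] objects.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$bases,
                                         character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# short stable content hash (FNV-1a over the serialized object) used to
# stamp outputs with their generating configuration
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                     # xor touches only the low byte
    h <- ((h - low + bitwXor(as.integer(low), b)) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
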