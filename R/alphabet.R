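#' @useDynLib dinucontext, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Canonical internal alphabet. RNA input is mapped to it on entry (U -> T)
# and mapped back for display only, so a single code path serves both modes.
NUC <- c("A", "C", "G", "T")
NUC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# 16 dinucleotides in fixed alphabetical order (AA, AC, ..., TT)
DINUCS <- as.vector(t(outer(NUC, NUC, paste0)))

# 12 ordered substitutions (from, to), lexicographic
MUTATIONS <- local({
  grid <- expand.grid(to = NUC, from = NUC, stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[grid$from != grid$to, ]
  grid <- grid[order(grid$from, grid$to), ]
  rownames(grid) <- paste0(grid$from, ">", grid$to)
  grid
})
MUTATION_IDS <- rownames(MUTATIONS)

nuc_index <- function(x) {
  i <- match(x, NUC)
  if (anyNA(i)) stop("invalid nucleotide: ", paste(x[is.na(i)], collapse = ", "))
  i
}

mutation_index <- function(from, to) {
  i <- match(paste0(from, ">", to), MUTATION_IDS)
  if (anyNA(i)) stop("invalid substitution: ", from, ">", to)
  i
}

complement_base <- function(x) unname(NUC_COMPLEMENT[x])

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences over A,C,G,T (case-insensitive;
#'   other letters are complemented to themselves' ambiguity code N).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# display helper: T -> U when mode == "rna"
display_base <- function(x, mode) if (mode == "rna") gsub("T", "U", x) else x
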