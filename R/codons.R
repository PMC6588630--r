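# Codon-level utilities shared by the synthetic-data generators, the mining
# gene models, and the GY94 machinery. The universal genetic code is taken
# from Biostrings; all codon-model state spaces exclude the three stop codons
# (61 sense codons, indexed in alphabetical codon order).

.codon_env <- new.env(parent = emptyenv())

#' Sense-codon table for the universal genetic code
#'
#' Returns a cached list describing the 61 sense codons: the codon strings,
#' their encoded amino acids, and pairwise single-nucleotide-change structure
#' used by the GY94 rate matrix (which position differs, transition vs
#' transversion, synonymous vs nonsynonymous).
#'
#' @return A list with elements `codons` (character 61), `aa` (character 61),
#'   `ndiff` (61 x 61 integer matrix of differing positions), `is_ts` (logical
#'   matrix, transition at the single differing site), `is_syn` (logical
#'   matrix, same encoded amino acid).
#' @export
codon_table <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc_map <- Biostrings::GENETIC_CODE
  all_codons <- names(gc_map)
  sense <- all_codons[gc_map != "*"]
  aa <- unname(gc_map[sense])
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(mat[, p], mat[, p], "!=")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  is_ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    diff_p <- outer(mat[, p], mat[, p], "!=")
    same_class <- outer(purine[mat[, p]], purine[mat[, p]], "==")
    is_ts <- is_ts | (diff_p & same_class & ndiff == 1L)
  }
  is_syn <- outer(aa, aa, "==")
  tab <- list(codons = sense, aa = aa, ndiff = ndiff, is_ts = is_ts,
              is_syn = is_syn)
  .codon_env$tab <- tab
  tab
}

# Split a DNA string into codon strings (truncates a trailing partial codon).
split_codons <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return(character(0))
  substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Translate a DNA string; codons with ambiguity or gaps become "X",
# stop codons "*".
translate_dna <- function(dna) {
  cods <- split_codons(dna)
  if (length(cods) == 0L) return("")
  gc_map <- Biostrings::GENETIC_CODE
  aa <- gc_map[cods]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# Reverse complement of a plain character DNA string.
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# Codon indices (1..61) for a coding sequence; NA for non-sense codons.
codon_indices <- function(dna) {
  tab <- codon_table()
  match(split_codons(dna), tab$codons)
}
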