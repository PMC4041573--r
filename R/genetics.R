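# Codon-level helpers shared by every module. The standard genetic code is
# taken from Biostrings; "*" denotes a stop codon throughout the package.

#' Standard codon table
#'
#' Named character vector mapping the 64 codons (DNA alphabet) to one-letter
#' amino-acid codes, with `"*"` for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' codon_table()[["ATG"]]
codon_table <- function() {
  if (is.null(.dmscan_env$codon_table)) {
    .dmscan_env$codon_table <- Biostrings::GENETIC_CODE
  }
  .dmscan_env$codon_table
}

DNA_BASES <- c("A", "C", "G", "T")

# amino acids with hydrophobic side chains (default partition used by the
# dimer-interface analysis; glycine is excluded from that analysis entirely
# because it is aliphatic, and proline is classified hydrophilic)
DEFAULT_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C")

.check_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  ok <- grepl(pat, x)
  if (!all(ok)) {
    stop("sequence contains characters outside ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T", call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x A single DNA string (A/C/G/T/N).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a nucleotide string into codons; nchar must be a multiple of 3
.codons <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a nucleotide string
#'
#' Plain standard-genetic-code translation of an in-frame coding string.
#' Codons containing `N` translate to `"X"`.
#'
#' @param x In-frame DNA string whose length is a multiple of 3.
#' @return Amino-acid string (may contain `"*"` and `"X"`).
#' @export
translate_nt <- function(x) {
  cods <- .codons(toupper(x))
  aa <- unname(codon_table()[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse-translate a peptide deterministically
#'
#' Picks, for every amino acid, the alphabetically first codon encoding it.
#' Used to build synthetic reference sequences and test fixtures; the choice
#' of codon is irrelevant downstream because scoring happens in protein space.
#'
#' @param aa Amino-acid string (one-letter codes; `"*"` allowed).
#' @return DNA string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa) {
  tab <- codon_table()
  first_codon <- vapply(split(names(tab), tab), function(x) sort(x)[1L], "")
  chars <- strsplit(aa, NULL)[[1L]]
  bad <- setdiff(chars, names(first_codon))
  if (length(bad)) stop("no codon for symbol(s): ", paste(bad, collapse = ", "))
  paste(first_codon[chars], collapse = "")
}

# purine/pyrimidine classes; a substitution within a class is a transition
.is_transition <- function(from, to) {
  pur <- c("A", "G")
  (from %in% pur) == (to %in% pur)
}
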