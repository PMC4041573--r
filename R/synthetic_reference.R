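# A synthetic stand-in for the expression plasmid. The true vector sequence
# is not distributed with the package; no result depends on it, because all
# scoring happens in protein space against whatever reference is loaded. The
# stand-in reproduces the *shape* of the construct: a 137-codon target ORF
# with the engineered alanine at residue 62 (the C62A photocycle knockout)
# and a leucine at residue 65, plus a 286-codon ampicillin-resistance-like
# control ORF on the opposite strand, separated by short linkers.
#
# Sequence content is generated by a fixed linear congruential generator so
# the reference is byte-identical across runs and independent of R's global
# RNG, while remaining aperiodic (short reads must map uniquely).

.lcg_new <- function(seed = 20140602) {
  env <- new.env(parent = emptyenv())
  env$x <- as.double(seed)
  env
}

.lcg_int <- function(lcg, n, k) {
  # n draws from 0..k-1
  out <- integer(n)
  for (i in seq_len(n)) {
    lcg$x <- (1103515245 * lcg$x + 12345) %% 2147483648
    out[i] <- as.integer(floor(lcg$x / 65536)) %% k
  }
  out
}

# deterministic pseudo-peptide over 19 amino acids (no stops); position 1 is M
.synthetic_peptide <- function(n, lcg, fixed = c()) {
  alpha <- c("A", "R", "N", "D", "E", "Q", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V", "G")
  aa <- alpha[.lcg_int(lcg, n, length(alpha)) + 1L]
  aa[1L] <- "M"
  if (length(fixed)) aa[as.integer(names(fixed))] <- fixed
  paste(aa, collapse = "")
}

# reverse translation with LCG-varied codon choice (avoids repetitive DNA)
.synthetic_cds <- function(aa, lcg) {
  tab <- codon_table()
  by_aa <- split(names(tab), tab)
  chars <- strsplit(aa, NULL)[[1L]]
  cods <- vapply(chars, function(a) {
    opts <- sort(by_aa[[a]])
    opts[.lcg_int(lcg, 1L, length(opts)) + 1L]
  }, "", USE.NAMES = FALSE)
  paste(cods, collapse = "")
}

.synthetic_linker <- function(n, lcg) {
  paste(DNA_BASES[.lcg_int(lcg, n, 4L) + 1L], collapse = "")
}

#' Write the packaged synthetic reference plasmid
#'
#' Generates a deterministic synthetic plasmid emulating the layout of an
#' FbFP expression vector: a 137-residue target ORF (alanine fixed at residue
#' 62, leucine at residue 65) on the plus strand and a 286-residue
#' beta-lactamase-like control ORF on the minus strand, each followed by a
#' stop codon, with 60-bp linkers between the elements. The plasmid is marked
#' circular. Sequences are synthetic pseudo-random coding sequences, not the
#' real vector; the generator is self-seeded, so the output never depends on
#' R's global RNG state.
#'
#' @param dir Directory in which to write `synthetic_plasmid.fa` and
#'   `synthetic_orfs.yaml`.
#' @param target_length Number of residues in the target protein (default 137).
#' @param control_length Number of residues in the control protein (default 286).
#' @return A list with elements `fasta` and `orf_config` (file paths).
#' @export
#' @examples
#' paths <- write_synthetic_reference(tempdir())
#' model <- load_reference(paths$fasta, paths$orf_config)
#' residue_at(model, "fbfp", 62)
write_synthetic_reference <- function(dir, target_length = 137L,
                                      control_length = 286L) {
  stopifnot(target_length >= 65L, control_length >= 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lcg <- .lcg_new()

  target_aa <- .synthetic_peptide(target_length, lcg,
                                  fixed = c(`62` = "A", `65` = "L"))
  control_aa <- .synthetic_peptide(control_length, lcg)
  target_nt <- paste0(.synthetic_cds(target_aa, lcg), "TAA")
  control_nt <- paste0(.synthetic_cds(control_aa, lcg), "TGA")

  l1 <- .synthetic_linker(60L, lcg)
  l2 <- .synthetic_linker(60L, lcg)
  l3 <- .synthetic_linker(60L, lcg)

  t_start <- nchar(l1)
  t_end <- t_start + nchar(target_nt)
  c_start <- t_end + nchar(l2)
  c_end <- c_start + nchar(control_nt)
  plasmid <- paste0(l1, target_nt, l2, revcomp(control_nt), l3)

  fasta <- file.path(dir, "synthetic_plasmid.fa")
  writeLines(c(">synthetic_plasmid synthetic stand-in expression vector",
               gsub("(.{70})", "\\1\n", plasmid)), fasta)

  cfg <- list(
    circular = TRUE,
    orfs = list(
      list(orf_id = "fbfp", start = t_start, end = t_end,
           strand = "+", role = "target"),
      list(orf_id = "ampR", start = c_start, end = c_end,
           strand = "-", role = "control")
    )
  )
  orf_config <- file.path(dir, "synthetic_orfs.yaml")
  yaml::write_yaml(cfg, orf_config)
  list(fasta = fasta, orf_config = orf_config)
}

#' Load the packaged synthetic reference
#'
#' Convenience wrapper: writes the synthetic stand-in plasmid to a temporary
#' (or given) directory and loads it.
#'
#' @inheritParams write_synthetic_reference
#' @param dir Directory for the generated files (a fresh temporary directory
#'   by default).
#' @return A `reference_model`.
#' @export
synthetic_reference <- function(dir = tempfile("dmscan_ref_"),
                                target_length = 137L, control_length = 286L) {
  p <- write_synthetic_reference(dir, target_length, control_length)
  load_reference(p$fasta, p$orf_config)
}
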