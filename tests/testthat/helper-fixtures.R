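# Fixtures are built in code at test time; nothing binary ships with the
# package. All fixtures are deterministic.

# two fixed 49-residue peptides (aperiodic, so their coding sequences do not
# create repeats that would make short reads multi-map)
TOY_PEPTIDE_A <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLS"
TOY_PEPTIDE_B <- "MSIQHFRVALIPFFAAFCLPVFAHPETLVKVKDAEDQLGARVGYIELDL"

# 600-bp toy plasmid: 60-bp linkers, two 150-bp ORFs (49 aa + stop)
write_toy_reference <- function(dir = tempfile("toy_ref_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  orf_a <- paste0(reverse_translate(TOY_PEPTIDE_A), "TAA")
  orf_b <- paste0(reverse_translate(TOY_PEPTIDE_B), "TGA")
  mk_linker <- function(chars) paste(chars, collapse = "")
  l1 <- mk_linker(rep(c("T", "G", "C", "A", "A", "C"), 10))
  l2 <- mk_linker(rep(c("G", "T", "T", "A", "C", "G"), 10))
  l3 <- mk_linker(rep(c("C", "A", "G", "G", "T", "A"), 10))
  plasmid <- paste0(l1, orf_a, l2, orf_b, l3)
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">toy_plasmid", plasmid), fasta)
  cfg <- list(circular = TRUE, orfs = list(
    list(orf_id = "toyA", start = 60L, end = 210L, strand = "+",
         role = "target"),
    list(orf_id = "toyB", start = 270L, end = 420L, strand = "+",
         role = "control")))
  orf_config <- file.path(dir, "toy_orfs.yaml")
  yaml::write_yaml(cfg, orf_config)
  list(fasta = fasta, orf_config = orf_config, plasmid = plasmid)
}

toy_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- write_toy_reference()
      cache <<- load_reference(p$fasta, p$orf_config)
    }
    cache
  }
})

# shared synthetic study-scale reference (137-aa target, 286-aa control)
study_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_reference()
    cache
  }
})

# independent brute-force mapping oracle: score = mismatches of the best
# ungapped placement over every offset of both strands of the circular
# plasmid; implemented with plain character vectors, no shared code with
# the mapper internals.
brute_map <- function(read, model) {
  L <- model$length
  dbl <- strsplit(paste0(model$seq, model$seq), NULL)[[1L]]
  score_strand <- function(chars) {
    m <- length(chars)
    vapply(0:(L - 1L), function(o) sum(chars != dbl[(o + 1L):(o + m)]),
           integer(1))
  }
  fwd <- strsplit(toupper(read), NULL)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- rev(unname(comp[fwd]))
  mmP <- score_strand(fwd)
  mmM <- score_strand(rc)
  b <- min(mmP, mmM)
  list(n_mismatch = b,
       plus_offsets = which(mmP == b) - 1L,
       minus_offsets = which(mmM == b) - 1L,
       similarity = (length(fwd) - b) / length(fwd))
}

# random DNA string helper
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# apply a specific codon change to an ORF coding sequence (codon index is
# 1-based); returns the full-length variant CDS
edit_codon <- function(cds, codon_idx, new_codon) {
  stopifnot(nchar(new_codon) == 3L)
  paste0(substr(cds, 1L, (codon_idx - 1L) * 3L), new_codon,
         substr(cds, codon_idx * 3L + 1L, nchar(cds)))
}

# synthesise an error-free mapped-read data frame tiling an ORF-bearing
# plasmid with fixed-length reads at every offset (full coverage)
tile_reads <- function(plasmid, read_len = 48L, step = 1L) {
  dbl <- paste0(plasmid, plasmid)
  starts <- seq(0L, nchar(plasmid) - 1L, by = step)
  data.frame(read_id = sprintf("tile%04d", starts),
             seq = substring(dbl, starts + 1L, starts + read_len),
             ref_start = starts, strand = "+",
             n_mismatch = 0L, similarity = 1, has_indel = FALSE,
             stringsAsFactors = FALSE)
}
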