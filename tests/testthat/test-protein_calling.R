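# a dedicated model whose target ORF carries leucine codon CTC at residue 65
leu65_reference <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pep <- paste0(TOY_PEPTIDE_A, substr(TOY_PEPTIDE_B, 2, 21), TOY_PEPTIDE_A)
    # 118 residues; fix L at 65 with codon CTC
    cds <- reverse_translate(pep)
    cds <- edit_codon(cds, 65L, "CTC")
    cds <- paste0(cds, "TAA")
    dir <- tempfile(); dir.create(dir)
    plasmid <- paste0(reverse_translate("MDEKT"), cds, reverse_translate("MQRST"))
    writeLines(c(">leu65", plasmid), file.path(dir, "leu65.fa"))
    cfg <- list(circular = TRUE, orfs = list(
      list(orf_id = "tgt", start = 15L, end = 15L + nchar(cds), strand = "+",
           role = "target"),
      list(orf_id = "ctl", start = 0L, end = 15L, strand = "+",
           role = "control")))
    cache <<- load_reference(file.path(dir, "leu65.fa"), cfg)
    cache
  }
})

mapped_row <- function(model, ref_start, len) {
  dbl <- paste0(model$seq, model$seq)
  list(ref_start = ref_start, seq = substring(dbl, ref_start + 1,
                                              ref_start + len),
       has_indel = FALSE)
}

test_that("frame trimming removes the out-of-frame bases at both ends", {
  model <- toy_reference()
  os <- 60L  # toyA start
  # in frame, 48 bases: nothing trimmed, 16 codons
  seg <- frame_trim(mapped_row(model, os + 9L, 48L), model, "toyA")
  expect_equal(seg$n_trim5, 0L)
  expect_equal(seg$n_trim3, 0L)
  expect_equal(nchar(seg$aa_seq), 16L)
  expect_equal(seg$first_residue, 4L)

  # phase 1 (second base of a codon), 50 bases: trim 2 at 5', 48 remain
  seg <- frame_trim(mapped_row(model, os + 10L, 50L), model, "toyA")
  expect_equal(seg$n_trim5, 2L)
  expect_equal(seg$n_trim3, 0L)
  expect_equal(nchar(seg$aa_seq), 16L)

  # phase 2, 50 bases: trim 1 at 5', 49 remain, trim 1 at 3', 16 codons
  seg <- frame_trim(mapped_row(model, os + 11L, 50L), model, "toyA")
  expect_equal(seg$n_trim5, 1L)
  expect_equal(seg$n_trim3, 1L)
  expect_equal(nchar(seg$aa_seq), 16L)

  # reads entirely outside the ORF produce no segment
  expect_null(frame_trim(mapped_row(model, 220L, 40L), model, "toyA"))
  # fewer than one full codon inside the ORF
  expect_null(frame_trim(mapped_row(model, os - 40L, 42L), model, "toyA"))
  # indel reads must be filtered upstream
  bad <- mapped_row(model, os, 48L); bad$has_indel <- TRUE
  expect_error(frame_trim(bad, model, "toyA"), "indel")
})

test_that("frame trimming is codon-exact on the minus strand", {
  model <- study_reference()
  o <- model$orfs[model$orfs$orf_id == "ampR", ]
  seg <- frame_trim(mapped_row(model, o$end - 48L, 48L), model, "ampR")
  expect_equal(seg$n_trim5, 0L)
  expect_equal(seg$first_residue, 1L)
  expect_equal(seg$aa_seq, substr(translate_orf(model, "ampR"), 1, 16))
})

test_that("fuzzed placements always yield full-codon segments", {
  model <- toy_reference()
  set.seed(47)
  for (i in 1:200) {
    rs <- sample(0:479, 1)
    len <- sample(20:60, 1)
    for (orf in c("toyA", "toyB")) {
      seg <- frame_trim(mapped_row(model, rs, len), model, orf)
      if (!is.null(seg)) {
        expect_true(nchar(seg$obs_nt) %% 3 == 0)
        expect_true(seg$n_trim5 %in% 0:2 && seg$n_trim3 %in% 0:2)
        expect_gte(seg$first_residue, 1)
      }
    }
  }
})

test_that("substitution calling detects L65F and skips synonymous changes", {
  model <- leu65_reference()
  o <- model$orfs[model$orfs$orf_id == "tgt", ]
  expect_equal(residue_at(model, "tgt", 65), "L")

  # wild-type segment: no calls
  seg <- frame_trim(mapped_row(model, o$start, 48L), model, "tgt")
  expect_equal(nrow(call_substitutions(seg, model)), 0L)

  variant_read <- function(new_codon) {
    dbl <- paste0(model$seq, model$seq)
    read_start <- o$start + 64L * 3L - 12L  # codon 65 sits mid-read
    read <- substring(dbl, read_start + 1, read_start + 48)
    substr(read, 13, 15) <- new_codon
    list(ref_start = read_start, seq = read, has_indel = FALSE)
  }
  # CTC -> TTC is L65F
  seg <- frame_trim(variant_read("TTC"), model, "tgt")
  calls <- call_substitutions(seg, model)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 65L)
  expect_equal(calls$wt_aa, "L")
  expect_equal(calls$obs_aa, "F")
  # CTG -> TTG would also be leucine: CTG encodes L, TTG encodes L
  seg <- frame_trim(variant_read("TTG"), model, "tgt")
  expect_equal(nrow(call_substitutions(seg, model)), 0L)
  # stop gain is called with "*"
  seg <- frame_trim(variant_read("TAA"), model, "tgt")
  calls <- call_substitutions(seg, model)
  expect_equal(calls$obs_aa, "*")
})

test_that("tallies are additive occurrence counts with coverage bounds", {
  model <- leu65_reference()
  o <- model$orfs[model$orfs$orf_id == "tgt", ]
  dbl <- paste0(model$seq, model$seq)
  read_start <- o$start + 64L * 3L - 12L
  read <- substring(dbl, read_start + 1, read_start + 48)
  substr(read, 13, 15) <- "TTC"
  df <- data.frame(read_id = c("a", "b"), seq = read, ref_start = read_start,
                   strand = "+", n_mismatch = 1L, similarity = 47 / 48,
                   has_indel = FALSE, stringsAsFactors = FALSE)
  tal <- tally_library(df, model, "FR", orf_ids = "tgt")
  row <- tal$counts[tal$counts$position == 65, ]
  expect_equal(row$obs_aa, "F")
  expect_equal(row$count, 2L)
  expect_equal(tal$coverage$tgt[65], 2L)
  expect_equal(tal$n_reads_orf[["tgt"]], 2L)
  expect_equal(tal$n_bases_orf[["tgt"]], 96)

  # empty input -> empty tally
  tal0 <- tally_library(df[0, ], model, "FR", orf_ids = "tgt")
  expect_equal(nrow(tal0$counts), 0L)
  expect_equal(tal0$n_reads_orf[["tgt"]], 0L)
})

test_that("read-based calling equals direct protein comparison (oracle)", {
  model <- toy_reference()
  sp <- build_spectrum()
  wt_prot <- translate_orf(model, "toyA")
  o <- model$orfs[model$orfs$orf_id == "toyA", ]
  set.seed(53)
  for (rep in 1:10) {
    variant <- mutate_sequence(orf_nt(model, "toyA"), sp, c(1L, 5L))
    # protein-level oracle: direct comparison of translations
    v_aa <- strsplit(substr(translate_nt(variant), 1, nchar(wt_prot)), NULL)[[1L]]
    w_aa <- strsplit(wt_prot, NULL)[[1L]]
    d <- which(v_aa != w_aa)
    oracle <- sort(paste0(d, v_aa[d]))

    # read-based: splice variant into plasmid, tile error-free reads, call
    varpl <- paste0(substr(model$seq, 1, o$start), variant,
                    substr(model$seq, o$end + 1, model$length))
    reads <- tile_reads(varpl, read_len = 48L)
    tal <- tally_library(reads, model, "FR", orf_ids = "toyA")
    got <- tal$counts[tal$counts$position <= nchar(wt_prot), ]
    expect_equal(sort(paste0(got$position, got$obs_aa)), oracle)

    # conservation: total occurrences equal summed per-entry counts
    expect_equal(sum(tal$counts$count),
                 sum(tal$counts$count[tal$counts$orf_id == "toyA"]))
  }
})

test_that("tally TSV interchange round-trips", {
  model <- leu65_reference()
  counts <- data.frame(orf_id = "tgt", position = c(65L, 70L),
                       wt_aa = c("L", residue_at(model, "tgt", 70)),
                       obs_aa = c("F", "*"), count = c(5L, 2L))
  tal <- mutation_tally(counts, "FL",
                        protein_lengths = c(tgt = 118L),
                        n_reads_orf = c(tgt = 100L))
  path <- tempfile(fileext = ".tsv")
  write_tally_tsv(tal, path, header = "unit test")
  back <- read.delim(path, comment.char = "#")
  expect_equal(nrow(back), 2L)
  expect_equal(back$count, c(5L, 2L))
  expect_equal(back$library_id, c("FL", "FL"))
})
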