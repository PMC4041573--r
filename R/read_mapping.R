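# Short-read mapper. Reads are placed by exhaustive ungapped scoring over
# every offset of the (doubled, hence origin-aware) circular plasmid on both
# strands — exact, simple, and fast enough at plasmid scale because the
# per-offset mismatch profile is computed with vectorised byte comparisons.
# A bounded gap-rescue pass (local alignment) runs only when no ungapped
# placement reaches the similarity fraction; reads rescued with indels are
# flagged and excluded from protein calling downstream.

#' Mapping parameters
#'
#' Cost and acceptance settings in the style of CLC-type mappers: positive
#' mismatch/insertion/deletion costs, a similarity fraction (minimum fraction
#' of matching bases for an accepted placement), and a length fraction
#' (minimum fraction of the read that must align).
#'
#' @param mismatch_cost Cost per mismatching base (default 2; 3 is the common
#'   stricter alternative).
#' @param insertion_cost Cost per inserted base (default 3).
#' @param deletion_cost Cost per deleted base (default 3).
#' @param similarity_fraction Minimum fraction of matching bases, in (0, 1]
#'   (default 0.8).
#' @param length_fraction Minimum aligned fraction of the read, in (0, 1]
#'   (default 0.5; only gap-rescued placements can align less than the full
#'   read).
#' @return Object of class `map_params`.
#' @export
map_params <- function(mismatch_cost = 2, insertion_cost = 3,
                       deletion_cost = 3, similarity_fraction = 0.8,
                       length_fraction = 0.5) {
  stopifnot(mismatch_cost > 0, insertion_cost > 0, deletion_cost > 0,
            similarity_fraction > 0, similarity_fraction <= 1,
            length_fraction > 0, length_fraction <= 1)
  structure(list(mismatch_cost = mismatch_cost, insertion_cost = insertion_cost,
                 deletion_cost = deletion_cost,
                 similarity_fraction = similarity_fraction,
                 length_fraction = length_fraction),
            class = "map_params")
}

# cached raw-byte index of the doubled plasmid (origin-spanning placements)
.ref_index <- function(model) {
  if (is.null(model$cache$idx)) {
    dbl <- paste0(model$seq, model$seq)
    model$cache$idx <- list(L = model$length, dbl_raw = charToRaw(dbl))
  }
  model$cache$idx
}

# complement lookup for raw bytes (N -> N)
.comp_raw <- local({
  tab <- raw(256)
  tab[as.integer(charToRaw("ACGTN")) + 1L] <- charToRaw("TGCAN")
  tab
})

.rc_raw <- function(r) rev(.comp_raw[as.integer(r) + 1L])

# mismatch count at every offset 0..L-1 of the doubled reference
.mm_profile <- function(dbl_raw, read_raw, L) {
  m <- length(read_raw)
  mm <- integer(L)
  for (j in seq_len(m)) {
    mm <- mm + (dbl_raw[j:(j + L - 1L)] != read_raw[j])
  }
  mm
}

# core placement of one read; returns NULL when below the similarity fraction
.place_ungapped <- function(fwd_raw, rc_raw, idx, params) {
  m <- length(fwd_raw)
  mmP <- .mm_profile(idx$dbl_raw, fwd_raw, idx$L)
  mmM <- .mm_profile(idx$dbl_raw, rc_raw, idx$L)
  b <- min(mmP, mmM)
  sim <- (m - b) / m
  if (sim < params$similarity_fraction) return(NULL)
  pP <- which(mmP == b) - 1L
  pM <- which(mmM == b) - 1L
  n_best <- length(pP) + length(pM)
  # tie-break: leftmost reference coordinate, then plus strand
  if (length(pP) && (!length(pM) || pP[1L] <= pM[1L])) {
    ref_start <- pP[1L]; strand <- "+"
  } else {
    ref_start <- pM[1L]; strand <- "-"
  }
  list(ref_start = ref_start, strand = strand, n_mismatch = b,
       similarity = sim, ambiguous = n_best > 1L, has_indel = FALSE,
       aligned_len = m)
}

# local-alignment rescue for reads that fail ungapped placement
.place_gapped <- function(read, idx, params) {
  dbl <- rawToChar(idx$dbl_raw)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -params$mismatch_cost)
  best <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read else revcomp(read)
    aln <- Biostrings::pairwiseAlignment(
      pat, dbl, type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = params$insertion_cost)
    pat_aln <- as.character(Biostrings::pattern(aln))
    alen <- nchar(pat_aln)
    sim <- Biostrings::nmatch(aln) / alen
    if (is.null(best) || Biostrings::score(aln) > best$score) {
      ind <- Biostrings::nindel(aln)
      has_indel <- sum(Biostrings::insertion(ind)[, "WidthSum"]) +
        sum(Biostrings::deletion(ind)[, "WidthSum"]) > 0
      best <- list(score = Biostrings::score(aln), sim = sim, alen = alen,
                   ref_start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
                   strand = strand, has_indel = has_indel,
                   aligned_seq = gsub("-", "", pat_aln, fixed = TRUE),
                   n_mismatch = Biostrings::nmismatch(aln))
    }
  }
  if (best$sim < params$similarity_fraction ||
      best$alen < params$length_fraction * nchar(read)) {
    return(NULL)
  }
  list(ref_start = best$ref_start %% idx$L, strand = best$strand,
       n_mismatch = best$n_mismatch, similarity = best$sim,
       ambiguous = FALSE, has_indel = best$has_indel,
       aligned_len = best$alen, aligned_seq = best$aligned_seq)
}

#' Map a single read to the plasmid
#'
#' Scores the read ungapped at every offset of both strands of the circular
#' plasmid (the origin-spanning junction is scanned via a doubled sequence)
#' and keeps the best-scoring placement if its similarity reaches
#' `similarity_fraction`. Ties are broken toward the leftmost reference
#' coordinate, then the plus strand; a read with several equally good
#' placements is flagged `ambiguous` (and dropped by [map_library()], which
#' retains uniquely mapped reads only). When no ungapped placement qualifies
#' and `gap_rescue` is `TRUE`, a local alignment with the configured indel
#' costs is attempted; rescued reads containing indels are flagged
#' `has_indel`.
#'
#' `N` bases are allowed and always count as mismatches.
#'
#' @param read DNA string (A/C/G/T/N), no longer than the plasmid.
#' @param model A `reference_model`.
#' @param params A [map_params()] object.
#' @param gap_rescue Attempt gapped rescue when ungapped placement fails
#'   (default `TRUE`).
#' @return An object of class `mapped_read` (list with `ref_start` — 0-based
#'   plasmid offset, `strand`, `seq` — the read projected onto the plus
#'   strand, `n_mismatch`, `similarity`, `ambiguous`, `has_indel`,
#'   `aligned_pairs`), or `NULL` when unmapped.
#' @export
map_read <- function(read, model, params = map_params(), gap_rescue = TRUE) {
  stopifnot(is.character(read), length(read) == 1L, nchar(read) > 0L)
  read <- toupper(read)
  .check_dna(read, allow_n = TRUE)
  if (nchar(read) > model$length) stop("read longer than plasmid")
  idx <- .ref_index(model)
  fwd <- charToRaw(read)
  rc <- .rc_raw(fwd)
  hit <- .place_ungapped(fwd, rc, idx, params)
  if (is.null(hit) && gap_rescue) hit <- .place_gapped(read, idx, params)
  if (is.null(hit)) return(NULL)
  m <- nchar(read)
  seq_plus <- if (!is.null(hit$aligned_seq)) hit$aligned_seq
              else if (hit$strand == "+") read else revcomp(read)
  ap <- NULL
  if (!hit$has_indel && is.null(hit$aligned_seq)) {
    ref_idx <- (hit$ref_start + seq_len(m) - 1L) %% idx$L
    obs <- charToRaw(seq_plus)
    ref <- idx$dbl_raw[hit$ref_start + seq_len(m)]
    read_index <- if (hit$strand == "+") seq_len(m) else rev(seq_len(m))
    ap <- data.frame(read_index = read_index, ref_index = ref_idx,
                     match = obs == ref)
  }
  structure(c(hit, list(seq = seq_plus, aligned_pairs = ap)),
            class = "mapped_read")
}

#' Map a FASTQ library to the plasmid
#'
#' Maps every read of a single-end FASTQ file (Phred+33) with the same rules
#' as [map_read()]. Only uniquely mapped reads are retained; ambiguous and
#' unmapped reads are counted in the statistics. Indel-rescued reads are
#' retained but flagged, so that protein calling can exclude them.
#'
#' @param fastq_path Path to a FASTQ file.
#' @param model A `reference_model`.
#' @param params A [map_params()] object.
#' @param gap_rescue Attempt gapped rescue for reads failing ungapped
#'   placement (default `TRUE`).
#' @return Object of class `mapped_library`: list with `reads` (data frame:
#'   `read_id`, `seq` — plus-strand projection, `ref_start`, `strand`,
#'   `n_mismatch`, `similarity`, `has_indel`) and `stats` (a `mapping_stats`
#'   list: `n_total_reads`, `n_mapped_reads`, `n_ambiguous`, `n_unmapped`,
#'   `n_mapped_bases`, `mean_read_length`).
#' @export
map_library <- function(fastq_path, model, params = map_params(),
                        gap_rescue = TRUE) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq_path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", fastq_path, "': ",
                             conditionMessage(e), call. = FALSE))
  n <- length(reads)
  idx <- .ref_index(model)
  stats <- list(n_total_reads = n, n_mapped_reads = 0L, n_ambiguous = 0L,
                n_unmapped = 0L, n_mapped_bases = 0L,
                mean_read_length = if (n) mean(Biostrings::width(reads)) else 0)
  if (n == 0L) {
    return(structure(list(
      reads = data.frame(read_id = character(0), seq = character(0),
                         ref_start = integer(0), strand = character(0),
                         n_mismatch = integer(0), similarity = numeric(0),
                         has_indel = logical(0)),
      stats = structure(stats, class = "mapping_stats")),
      class = "mapped_library"))
  }

  seq_chr <- as.character(reads)
  rc_chr <- as.character(Biostrings::reverseComplement(reads))
  ids <- sub("\\s.*$", "", names(reads))

  read_id <- character(n); seq_out <- character(n)
  ref_start <- integer(n); strand <- character(n)
  n_mismatch <- integer(n); similarity <- numeric(n); has_indel <- logical(n)
  kept <- 0L

  for (i in seq_len(n)) {
    fwd <- charToRaw(seq_chr[i])
    rc <- charToRaw(rc_chr[i])
    hit <- .place_ungapped(fwd, rc, idx, params)
    if (is.null(hit) && gap_rescue) hit <- .place_gapped(seq_chr[i], idx, params)
    if (is.null(hit)) {
      stats$n_unmapped <- stats$n_unmapped + 1L
    } else if (hit$ambiguous) {
      stats$n_ambiguous <- stats$n_ambiguous + 1L
    } else {
      kept <- kept + 1L
      read_id[kept] <- ids[i]
      seq_out[kept] <- if (!is.null(hit$aligned_seq)) hit$aligned_seq
                       else if (hit$strand == "+") seq_chr[i] else rc_chr[i]
      ref_start[kept] <- hit$ref_start
      strand[kept] <- hit$strand
      n_mismatch[kept] <- hit$n_mismatch
      similarity[kept] <- hit$similarity
      has_indel[kept] <- hit$has_indel
      stats$n_mapped_bases <- stats$n_mapped_bases + hit$aligned_len
    }
  }
  stats$n_mapped_reads <- kept
  keep <- seq_len(kept)
  structure(list(
    reads = data.frame(read_id = read_id[keep], seq = seq_out[keep],
                       ref_start = ref_start[keep], strand = strand[keep],
                       n_mismatch = n_mismatch[keep],
                       similarity = similarity[keep],
                       has_indel = has_indel[keep], stringsAsFactors = FALSE),
    stats = structure(stats, class = "mapping_stats")),
    class = "mapped_library")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf("reads: %d total, %d uniquely mapped, %d ambiguous, %d unmapped\n",
              x$n_total_reads, x$n_mapped_reads, x$n_ambiguous, x$n_unmapped))
  cat(sprintf("mapped bases: %d; mean read length: %.1f\n",
              x$n_mapped_bases, x$mean_read_length))
  invisible(x)
}

#' Export mappings as minimal SAM
#'
#' Writes mandatory-field SAM records (ungapped reads only, full-length `M`
#' CIGAR) for interoperability with standard viewers. Placements that wrap
#' the circular origin are skipped with a warning, since linear SAM
#' coordinates cannot represent them.
#'
#' @param mapped A `mapped_library`.
#' @param model The `reference_model` used for mapping.
#' @param path Output SAM path.
#' @param ref_name Reference name for the SAM header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mapped, model, path, ref_name = "plasmid") {
  df <- mapped$reads[!mapped$reads$has_indel, , drop = FALSE]
  wraps <- df$ref_start + nchar(df$seq) > model$length
  if (any(wraps)) {
    warning(sum(wraps), " origin-spanning placement(s) skipped in SAM export")
    df <- df[!wraps, , drop = FALSE]
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, model$length))
  flag <- ifelse(df$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                 df$read_id, flag, ref_name, df$ref_start + 1L,
                 nchar(df$seq), df$seq, strrep("I", nchar(df$seq)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
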