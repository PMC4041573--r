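# Protein calling: convert mapped reads into codon-aligned amino-acid
# substitution calls ("translational trimming"). A read is trimmed to the
# maximal full-codon span inside each ORF — one or two bases are removed at
# the biological 5' end when the read starts out of frame, and at the 3' end
# when it leaves a partial codon — then translated and compared to the
# wild-type protein. Codons covered only partially (1-2 bases) contribute
# neither calls nor coverage.

# per-ORF precomputation used by the hot calling loop
.orf_ctx <- function(model, orf_id) {
  key <- paste0("orf_ctx_", orf_id)
  if (is.null(model$cache[[key]])) {
    o <- .get_orf(model, orf_id)
    nt <- orf_nt(model, orf_id)  # coding orientation
    prot <- translate_orf(model, orf_id)
    model$cache[[key]] <- list(
      orf_id = orf_id, start = o$start, end = o$end, strand = o$strand,
      nt = nt, n_codons = nchar(nt) %/% 3L,
      prot = prot, prot_chars = strsplit(prot, NULL)[[1L]],
      prot_len = nchar(prot))
  }
  model$cache[[key]]
}

# trim one plus-projected read span to full codons of one ORF.
# rs: 0-based plasmid start; rlen: bases; returns NULL or a list with
# first_residue, n_codons, obs_nt (coding orientation), n_trim5, n_trim3.
.trim_one <- function(ctx, rs, rlen, seq, L) {
  a <- rs; b <- rs + rlen            # read interval, doubled coordinates
  os <- ctx$start; oe <- ctx$end     # ORF interval (oe may exceed L)
  # try the ORF in both unrolled copies of the circular plasmid
  x <- max(a, os); y <- min(b, oe)
  if (y - x < 3L) {
    x <- max(a, os + L); y <- min(b, oe + L)
    if (y - x < 3L) return(NULL)
    os <- os + L; oe <- oe + L
  }
  if (ctx$strand == "+") {
    r <- (x - os) %% 3L
    n_trim5 <- (3L - r) %% 3L
    x2 <- x + n_trim5
    n_trim3 <- (y - x2) %% 3L
    y2 <- y - n_trim3
    if (y2 - x2 < 3L) return(NULL)
    first_codon <- (x2 - os) %/% 3L + 1L
    obs <- substr(seq, x2 - a + 1L, y2 - a)
  } else {
    # biological 5' end of a minus-strand ORF sits at plasmid coordinate oe
    r <- (oe - y) %% 3L
    n_trim5 <- (3L - r) %% 3L
    y2 <- y - n_trim5
    n_trim3 <- (y2 - x) %% 3L
    x2 <- x + n_trim3
    if (y2 - x2 < 3L) return(NULL)
    first_codon <- (oe - y2) %/% 3L + 1L
    obs <- revcomp(substr(seq, x2 - a + 1L, y2 - a))
  }
  n_codons <- nchar(obs) %/% 3L
  # codons past the protein (the stop codon) are not scored residues but the
  # read may still gain a stop there; keep them, cap at ORF codon count
  if (first_codon > ctx$n_codons) return(NULL)
  list(first_residue = first_codon, n_codons = n_codons, obs_nt = obs,
       n_trim5 = n_trim5, n_trim3 = n_trim3)
}

#' Frame-trim a mapped read against an ORF
#'
#' Returns the maximal in-frame, full-codon sub-span of the read within the
#' ORF as a `codon_segment`, or `NULL` when fewer than one complete codon of
#' the ORF is covered (including reads entirely outside the ORF). The
#' trimming amounts are `(3 - phase) %% 3` at the biological 5' end and the
#' remaining overhang modulo 3 at the 3' end. Indel-flagged reads are an
#' error: they must be filtered out upstream.
#'
#' @param mapped A `mapped_read` from [map_read()], or any list/one-row data
#'   frame with `ref_start`, `seq` (plus-strand projection) and `has_indel`.
#' @param model A `reference_model`.
#' @param orf_id ORF identifier.
#' @return `NULL`, or an object of class `codon_segment`: list with `orf_id`,
#'   `first_residue` (1-based), `aa_seq` (observed amino acids, may include
#'   `"*"`), `obs_nt`, `n_trim5`, `n_trim3`.
#' @export
frame_trim <- function(mapped, model, orf_id) {
  if (isTRUE(mapped$has_indel)) {
    stop("indel-flagged reads cannot be frame-trimmed; filter them upstream")
  }
  ctx <- .orf_ctx(model, orf_id)
  tr <- .trim_one(ctx, as.integer(mapped$ref_start), nchar(mapped$seq),
                  mapped$seq, model$length)
  if (is.null(tr)) return(NULL)
  structure(list(orf_id = orf_id, first_residue = tr$first_residue,
                 aa_seq = translate_nt(tr$obs_nt), obs_nt = tr$obs_nt,
                 n_trim5 = tr$n_trim5, n_trim3 = tr$n_trim3),
            class = "codon_segment")
}

#' Call amino-acid substitutions in a codon segment
#'
#' Compares the observed amino acids to the wild-type protein. Synonymous
#' codon changes produce no call; stop gains are called with `"*"`; codons
#' containing `N` (translated `"X"`) are never called. The ORF's terminal
#' stop codon is compared as residue `protein length + 1` with wild type
#' `"*"`, so destroying it yields a call as well.
#'
#' @param segment A `codon_segment` from [frame_trim()].
#' @param model A `reference_model`.
#' @return Data frame with columns `orf_id`, `position`, `wt_aa`, `obs_aa`
#'   (zero rows when the segment matches wild type).
#' @export
call_substitutions <- function(segment, model) {
  stopifnot(inherits(segment, "codon_segment"))
  ctx <- .orf_ctx(model, segment$orf_id)
  n <- nchar(segment$aa_seq)
  pos <- segment$first_residue + seq_len(n) - 1L
  if (pos[n] > ctx$n_codons) {
    stop("segment residue range exceeds ORF length")
  }
  obs <- strsplit(segment$aa_seq, NULL)[[1L]]
  wt_full <- c(ctx$prot_chars, rep("*", ctx$n_codons - ctx$prot_len))
  wt <- wt_full[pos]
  d <- which(obs != wt & obs != "X")
  data.frame(orf_id = rep(segment$orf_id, length(d)),
             position = pos[d], wt_aa = wt[d], obs_aa = obs[d],
             stringsAsFactors = FALSE)
}

#' Construct a mutation tally
#'
#' Container for per-library substitution occurrence counts and coverage
#' denominators. Normally produced by [tally_library()], but can be built
#' directly — e.g. from a published count table — for the scoring functions.
#'
#' @param counts Data frame with columns `orf_id`, `position`, `wt_aa`,
#'   `obs_aa`, `count` (integer occurrence counts, i.e. supporting reads).
#' @param library_id `"FR"` or `"FL"`.
#' @param coverage Named list: per ORF, an integer vector of in-frame codon
#'   coverage per residue. Defaults to per-position count sums (a lower
#'   bound) when not supplied.
#' @param n_reads_orf Named integer vector: reads contributing at least one
#'   full codon to each ORF.
#' @param n_bases_orf Named integer vector: in-frame bases contributed.
#' @param protein_lengths Named integer vector of protein lengths per ORF.
#' @return Object of class `mutation_tally`.
#' @export
mutation_tally <- function(counts, library_id,
                           coverage = NULL, n_reads_orf = NULL,
                           n_bases_orf = NULL, protein_lengths = NULL) {
  stopifnot(library_id %in% c("FR", "FL"),
            all(c("orf_id", "position", "wt_aa", "obs_aa", "count") %in%
                  names(counts)))
  counts$count <- as.integer(counts$count)
  counts <- counts[counts$count > 0L, , drop = FALSE]
  if (any(counts$count < 0L)) stop("negative counts")
  if (any(counts$wt_aa == counts$obs_aa)) {
    stop("obs_aa equal to wt_aa is not a substitution")
  }
  orfs <- unique(counts$orf_id)
  if (is.null(protein_lengths)) {
    protein_lengths <- vapply(orfs, function(o)
      max(counts$position[counts$orf_id == o]), 0)
  }
  if (is.null(coverage)) {
    coverage <- lapply(setNames(nm = names(protein_lengths)), function(o) {
      v <- integer(protein_lengths[[o]] + 1L)  # + stop-codon slot
      sub <- counts[counts$orf_id == o, ]
      agg <- tapply(sub$count, sub$position, sum)
      v[as.integer(names(agg))] <- as.integer(agg)
      v
    })
  }
  if (is.null(n_reads_orf)) {
    n_reads_orf <- vapply(setNames(nm = names(protein_lengths)), function(o)
      sum(counts$count[counts$orf_id == o]), 0)
  }
  if (is.null(n_bases_orf)) n_bases_orf <- n_reads_orf * 0
  for (i in seq_len(nrow(counts))) {
    o <- counts$orf_id[i]
    if (counts$count[i] > coverage[[o]][counts$position[i]]) {
      stop("count exceeds coverage at ", o, " position ", counts$position[i])
    }
  }
  structure(list(library_id = library_id, counts = counts,
                 coverage = coverage, n_reads_orf = n_reads_orf,
                 n_bases_orf = n_bases_orf,
                 protein_lengths = as.list(protein_lengths)),
            class = "mutation_tally")
}

#' Tally amino-acid substitutions over a mapped library
#'
#' Runs frame trimming and substitution calling over every uniquely mapped,
#' indel-free read and accumulates per-ORF occurrence counts and coverage.
#' Duplicate reads are counted independently (occurrence counting, no
#' deduplication); a read carrying k substitutions contributes k counts; a
#' read covering several ORFs contributes to each.
#'
#' @param mapped A `mapped_library` from [map_library()] (or a compatible
#'   data frame in its `reads` slot format).
#' @param model A `reference_model`.
#' @param library_id `"FR"` or `"FL"`.
#' @param orf_ids ORFs to tally (default: all annotated ORFs).
#' @return A [mutation_tally()] object.
#' @export
tally_library <- function(mapped, model, library_id, orf_ids = NULL) {
  df <- if (inherits(mapped, "mapped_library")) mapped$reads else mapped
  if (is.null(orf_ids)) orf_ids <- model$orfs$orf_id
  df <- df[!df$has_indel, , drop = FALSE]
  L <- model$length

  ctxs <- lapply(setNames(nm = orf_ids), .orf_ctx, model = model)
  cov <- lapply(ctxs, function(ctx) integer(ctx$n_codons))
  n_reads_orf <- setNames(integer(length(orf_ids)), orf_ids)
  n_bases_orf <- setNames(numeric(length(orf_ids)), orf_ids)
  acc_pos <- list(); acc_aa <- list(); acc_orf <- list(); k <- 0L

  rs_all <- as.integer(df$ref_start)
  rlen_all <- nchar(df$seq)
  for (i in seq_len(nrow(df))) {
    for (ctx in ctxs) {
      tr <- .trim_one(ctx, rs_all[i], rlen_all[i], df$seq[i], L)
      if (is.null(tr)) next
      last <- min(tr$first_residue + tr$n_codons - 1L, ctx$n_codons)
      span <- tr$first_residue:last
      cov[[ctx$orf_id]][span] <- cov[[ctx$orf_id]][span] + 1L
      n_reads_orf[[ctx$orf_id]] <- n_reads_orf[[ctx$orf_id]] + 1L
      n_bases_orf[[ctx$orf_id]] <- n_bases_orf[[ctx$orf_id]] + nchar(tr$obs_nt)
      # fast path: identical nucleotides -> no substitution calls
      wt_nt <- substr(ctx$nt, (tr$first_residue - 1L) * 3L + 1L,
                      (tr$first_residue - 1L) * 3L + nchar(tr$obs_nt))
      if (tr$obs_nt == wt_nt) next
      obs <- strsplit(translate_nt(tr$obs_nt), NULL)[[1L]]
      wt_full <- c(ctx$prot_chars, rep("*", ctx$n_codons - ctx$prot_len))
      wt <- wt_full[span]
      obs <- obs[seq_along(span)]
      d <- which(obs != wt & obs != "X")
      if (length(d)) {
        k <- k + 1L
        acc_pos[[k]] <- span[d]
        acc_aa[[k]] <- obs[d]
        acc_orf[[k]] <- rep(ctx$orf_id, length(d))
      }
    }
  }

  if (k) {
    pos <- unlist(acc_pos); aa <- unlist(acc_aa); orf <- unlist(acc_orf)
    key <- paste(orf, pos, aa, sep = "\r")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    counts <- data.frame(orf_id = parts[, 1L],
                         position = as.integer(parts[, 2L]),
                         obs_aa = parts[, 3L],
                         count = as.integer(tab), stringsAsFactors = FALSE)
    wt_of <- function(o, p) {
      ctx <- ctxs[[o]]
      if (p > ctx$prot_len) "*" else ctx$prot_chars[p]
    }
    counts$wt_aa <- mapply(wt_of, counts$orf_id, counts$position)
    counts <- counts[order(counts$orf_id, counts$position, counts$obs_aa),
                     c("orf_id", "position", "wt_aa", "obs_aa", "count")]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(orf_id = character(0), position = integer(0),
                         wt_aa = character(0), obs_aa = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  }
  prot_len <- vapply(ctxs, function(x) x$prot_len, 0L)
  mutation_tally(counts, library_id, coverage = cov,
                 n_reads_orf = n_reads_orf, n_bases_orf = n_bases_orf,
                 protein_lengths = prot_len)
}

#' @export
print.mutation_tally <- function(x, ...) {
  cat("mutation_tally [", x$library_id, "]: ",
      nrow(x$counts), " distinct substitutions, ",
      sum(x$counts$count), " occurrences\n", sep = "")
  for (o in names(x$n_reads_orf)) {
    cat(sprintf("  %-10s %d reads, %.0f bases\n", o, x$n_reads_orf[[o]],
                x$n_bases_orf[[o]]))
  }
  invisible(x)
}

#' Write / read the tally interchange TSV
#'
#' Columns: `library_id`, `orf_id`, `position`, `wt_aa`, `obs_aa`, `count`,
#' `coverage` — the interchange format between the calling and scoring
#' layers.
#'
#' @param tally A `mutation_tally`.
#' @param path Output TSV path.
#' @param header Optional comment line(s) written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_tally_tsv <- function(tally, path, header = NULL) {
  df <- tally$counts
  df$library_id <- tally$library_id
  df$coverage <- mapply(function(o, p) tally$coverage[[o]][p],
                        df$orf_id, df$position)
  df <- df[, c("library_id", "orf_id", "position", "wt_aa", "obs_aa",
               "count", "coverage")]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
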