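# Scoring layer: sequencing-error background from the control gene,
# frequency filtering, FR/FL set algebra, the per-residue positional-effect
# score, cutoff calibration against a standard site set, and the
# dimer-interface hydrophobicity analysis.

#' Estimate the sequencing-error rate from the control gene
#'
#' The control ORF (antibiotic-resistance gene) is under constant selection,
#' so every amino-acid substitution called there is a sequencing error. The
#' protein-level error rate is 100 x (substitution occurrence counts in the
#' control ORF) / (reads contributing to the control ORF).
#'
#' @param tally A `mutation_tally`.
#' @param control_orf Control ORF id (defaults to the single ORF present in
#'   the tally's coverage that is named `"ampR"`, else must be given).
#' @return Object of class `error_rate_estimate`: list with `library_id`,
#'   `n_control_mutations`, `n_control_reads`, `rate_percent`.
#' @export
estimate_error_rate <- function(tally, control_orf = "ampR") {
  stopifnot(inherits(tally, "mutation_tally"))
  n_reads <- tally$n_reads_orf[[control_orf]]
  if (is.null(n_reads) || n_reads == 0) {
    stop("no reads recorded for control ORF '", control_orf, "'")
  }
  n_mut <- sum(tally$counts$count[tally$counts$orf_id == control_orf])
  structure(list(library_id = tally$library_id,
                 n_control_mutations = n_mut,
                 n_control_reads = n_reads,
                 rate_percent = 100 * n_mut / n_reads),
            class = "error_rate_estimate")
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf("%s sequencing error: %d mutations / %d control reads = %.3f%%\n",
              x$library_id, x$n_control_mutations, x$n_control_reads,
              x$rate_percent))
  invisible(x)
}

#' Filter substitution calls below the sequencing-error background
#'
#' Removes every `(position, obs_aa)` entry of the chosen ORF whose frequency
#' is strictly below the library's sequencing-error rate; surviving counts
#' are unchanged. The frequency of an entry is `100 * count / denominator`,
#' where the denominator is, per residue, the in-frame codon coverage of its
#' position (`denominator = "coverage"`, the default) or, globally, the
#' number of reads contributing to the ORF (`denominator = "reads"`). The
#' coverage mode is the default because it measures each call against the
#' number of reads that could have produced it; the read-count mode mirrors
#' the control-gene rate definition verbatim and is kept as an alternative.
#'
#' The operation is idempotent and monotone: filtering twice changes
#' nothing, and the output entries are a subset of the input entries.
#'
#' @param tally A `mutation_tally`.
#' @param rate An `error_rate_estimate` (from the same library), or a bare
#'   percentage.
#' @param orf_id ORF to filter (default: every ORF in the tally).
#' @param denominator `"coverage"` or `"reads"`.
#' @return A filtered `mutation_tally`.
#' @export
filter_by_error <- function(tally, rate, orf_id = NULL,
                            denominator = c("coverage", "reads")) {
  stopifnot(inherits(tally, "mutation_tally"))
  denominator <- match.arg(denominator)
  if (inherits(rate, "error_rate_estimate")) {
    if (!identical(rate$library_id, tally$library_id)) {
      stop("error-rate estimate comes from library ", rate$library_id,
           ", tally from ", tally$library_id)
    }
    rate <- rate$rate_percent
  }
  df <- tally$counts
  in_scope <- if (is.null(orf_id)) rep(TRUE, nrow(df)) else df$orf_id %in% orf_id
  den <- if (denominator == "reads") {
    as.numeric(tally$n_reads_orf[df$orf_id])
  } else {
    mapply(function(o, p) tally$coverage[[o]][p], df$orf_id, df$position)
  }
  freq <- ifelse(den > 0, 100 * df$count / den, 0)
  keep <- !in_scope | freq >= rate
  out <- tally
  out$counts <- df[keep, , drop = FALSE]
  rownames(out$counts) <- NULL
  out
}

#' Shared and unique substitution identities between FR and FL libraries
#'
#' Partitions the *distinct* substitution identities `(position, obs_aa)` of
#' the target ORF (not occurrence counts) into those present in both
#' libraries, those unique to FL, and those unique to FR.
#'
#' @param fr_tally,fl_tally Filtered `mutation_tally` objects.
#' @param orf_id ORF to compare (default: the first ORF of the FL tally's
#'   counts; pass explicitly for mixed tallies).
#' @return List with character-vector elements `shared`, `fl_unique`,
#'   `fr_unique` (`"position:obs_aa"` keys) and integer `sizes`.
#' @export
shared_unique <- function(fr_tally, fl_tally, orf_id = NULL) {
  key <- function(t) {
    df <- t$counts
    if (!is.null(orf_id)) df <- df[df$orf_id %in% orf_id, , drop = FALSE]
    unique(paste(df$position, df$obs_aa, sep = ":"))
  }
  fr <- key(fr_tally); fl <- key(fl_tally)
  shared <- intersect(fr, fl)
  out <- list(shared = shared,
              fl_unique = setdiff(fl, shared),
              fr_unique = setdiff(fr, shared))
  out$sizes <- c(fr = length(fr), fl = length(fl), shared = length(shared),
                 fl_unique = length(out$fl_unique),
                 fr_unique = length(out$fr_unique))
  out
}

#' Per-residue positional-effect profile
#'
#' For each residue of the target protein, sums substitution occurrence
#' counts over all amino acids in each library and computes the positional
#' effect: `effect = fl_count / (fl_count + fr_count)` — the fraction of
#' mutation occurrences at that residue that come from the function-lost
#' library. A residue with effect near 1 is sensitive (mutations there
#' abolish function); near 0, tolerant. Residues with zero total mutations
#' get `NA`, never 0 or 1, since both extremes are informative.
#'
#' Stop-gain calls at a residue are included in its sums; calls at the
#' ORF's terminal stop codon are not residues and are ignored.
#'
#' @param fr_tally,fl_tally Filtered `mutation_tally` objects for the FR and
#'   FL libraries.
#' @param orf_id Target ORF id (default `"fbfp"`).
#' @return Object of class `positional_effect_profile`: a data frame with
#'   columns `position`, `wt_aa`, `fr_count`, `fl_count`, `effect`.
#' @export
positional_effect <- function(fr_tally, fl_tally, orf_id = "fbfp") {
  stopifnot(identical(fr_tally$library_id, "FR"),
            identical(fl_tally$library_id, "FL"))
  len <- fr_tally$protein_lengths[[orf_id]]
  if (is.null(len)) len <- fl_tally$protein_lengths[[orf_id]]
  if (is.null(len)) stop("ORF '", orf_id, "' not present in either tally")
  len <- as.integer(len)

  sum_by_pos <- function(tally) {
    df <- tally$counts
    df <- df[df$orf_id == orf_id & df$position <= len, , drop = FALSE]
    v <- integer(len)
    if (nrow(df)) {
      agg <- tapply(df$count, df$position, sum)
      v[as.integer(names(agg))] <- as.integer(agg)
    }
    v
  }
  fr <- sum_by_pos(fr_tally)
  fl <- sum_by_pos(fl_tally)
  tot <- fr + fl
  effect <- ifelse(tot > 0L, fl / pmax(tot, 1L), NA_real_)

  wt <- rep(NA_character_, len)
  for (t in list(fr_tally, fl_tally)) {
    df <- t$counts[t$counts$orf_id == orf_id & t$counts$position <= len, ]
    wt[df$position] <- df$wt_aa
  }
  structure(data.frame(position = seq_len(len), wt_aa = wt,
                       fr_count = fr, fl_count = fl, effect = effect,
                       stringsAsFactors = FALSE),
            orf_id = orf_id,
            class = c("positional_effect_profile", "data.frame"))
}

#' Calibrate the sensitive-residue cutoff against standard sites
#'
#' Sweeps every observed effect value as a candidate threshold and selects
#' the one maximising Youden's J statistic (sensitivity + specificity - 1)
#' for recovering the given standard site set (e.g. known cofactor-binding
#' residues); ties are broken toward the higher threshold. Residues with
#' undefined effect are treated as negative calls.
#'
#' @param profile A `positional_effect_profile`.
#' @param standard_sites Integer vector of known functional residue
#'   positions, all within the protein.
#' @return List with `threshold`, `sensitive_set` (positions with defined
#'   effect >= threshold), `n_standard_captured`, `youden_j`, and the sweep
#'   table `candidates`.
#' @export
calibrate_cutoff <- function(profile, standard_sites) {
  stopifnot(inherits(profile, "positional_effect_profile"),
            length(standard_sites) >= 1L)
  standard_sites <- unique(as.integer(standard_sites))
  if (any(standard_sites < 1L | standard_sites > nrow(profile))) {
    stop("standard sites outside protein length")
  }
  eff <- profile$effect
  if (all(is.na(eff))) stop("all positional effects undefined")
  pos <- profile$position
  is_std <- pos %in% standard_sites

  cand <- sort(unique(eff[!is.na(eff)]))
  stats <- vapply(cand, function(th) {
    call_pos <- !is.na(eff) & eff >= th
    sens <- sum(call_pos & is_std) / sum(is_std)
    spec <- sum(!call_pos & !is_std) / sum(!is_std)
    c(sens = sens, spec = spec, j = sens + spec - 1)
  }, c(sens = 0, spec = 0, j = 0))
  jmax <- max(stats["j", ])
  best <- max(which(stats["j", ] >= jmax - 1e-12))  # ties -> higher threshold
  threshold <- cand[best]
  sensitive <- pos[!is.na(eff) & eff >= threshold]
  list(threshold = threshold, sensitive_set = sensitive,
       n_standard_captured = sum(standard_sites %in% sensitive),
       youden_j = jmax,
       candidates = data.frame(threshold = cand, t(stats)))
}

#' Hydrophobicity of substitutions at dimer-interface positions
#'
#' For a chosen set of residues (e.g. the nine beta-sheet positions that
#' mediate homo-dimerisation), counts substitution occurrences per library
#' whose observed amino acid is hydrophobic versus hydrophilic. Glycine
#' substitutions are excluded entirely (aliphatic, in neither class), as are
#' stop gains. The totals row is the column sum of the per-position rows.
#'
#' @param fr_tally,fl_tally Filtered `mutation_tally` objects.
#' @param positions Integer vector of residue positions to analyse.
#' @param hydrophobic_set Amino acids counted as hydrophobic (default
#'   A, V, L, I, M, F, W, C; proline counts as hydrophilic).
#' @param exclude Amino acids excluded from the analysis (default glycine).
#' @param orf_id Target ORF id (default `"fbfp"`).
#' @return Object of class `hydrophobicity_table`: list with `by_position`
#'   (data frame: `position`, `fr_hydrophobic`, `fr_hydrophilic`,
#'   `fl_hydrophobic`, `fl_hydrophilic`), `totals` (named numeric), and the
#'   classification sets.
#' @export
hydrophobicity_counts <- function(fr_tally, fl_tally, positions,
                                  hydrophobic_set = DEFAULT_HYDROPHOBIC,
                                  exclude = "G", orf_id = "fbfp") {
  stopifnot(length(hydrophobic_set) >= 1L)
  positions <- as.integer(positions)
  count_class <- function(tally, p, hydro) {
    df <- tally$counts
    sel <- df$orf_id == orf_id & df$position == p &
      !(df$obs_aa %in% c(exclude, "*")) &
      (df$obs_aa %in% hydrophobic_set) == hydro
    sum(df$count[sel])
  }
  rows <- data.frame(
    position = positions,
    fr_hydrophobic = vapply(positions, count_class, 0, tally = fr_tally, hydro = TRUE),
    fr_hydrophilic = vapply(positions, count_class, 0, tally = fr_tally, hydro = FALSE),
    fl_hydrophobic = vapply(positions, count_class, 0, tally = fl_tally, hydro = TRUE),
    fl_hydrophilic = vapply(positions, count_class, 0, tally = fl_tally, hydro = FALSE))
  totals <- colSums(rows[, -1L, drop = FALSE])
  structure(list(by_position = rows, totals = totals,
                 hydrophobic_set = hydrophobic_set, excluded = exclude),
            class = "hydrophobicity_table")
}

#' @export
print.hydrophobicity_table <- function(x, ...) {
  print(x$by_position, row.names = FALSE)
  cat("totals:", paste(names(x$totals), x$totals, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Position-by-library and position-by-amino-acid frequency matrices
#'
#' Builds the matrices behind the positional heatmaps: a `position x
#' {FR, FL}` matrix of occurrence counts and, per library, a `position x
#' amino acid` matrix. With `normalize = TRUE` each row is scaled to sum to
#' 1 (rows with no data are left at zero — no division by zero).
#'
#' @param fr_tally,fl_tally Filtered `mutation_tally` objects.
#' @param orf_id Target ORF id (default `"fbfp"`).
#' @param normalize Row-normalise to `[0, 1]` (default `TRUE`).
#' @param include_stop Include a `"*"` column in the per-amino-acid matrices
#'   (default `FALSE`: stop gains are trivially deleterious and would
#'   dominate the scale).
#' @return List with `position_library` (matrix) and `per_aa` (list of
#'   matrices `FR`, `FL`).
#' @export
heatmap_matrix <- function(fr_tally, fl_tally, orf_id = "fbfp",
                           normalize = TRUE, include_stop = FALSE) {
  len <- as.integer(fr_tally$protein_lengths[[orf_id]] %||%
                      fl_tally$protein_lengths[[orf_id]])
  aa_levels <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (include_stop) aa_levels <- c(aa_levels, "*")
  per_aa_mat <- function(tally) {
    m <- matrix(0, len, length(aa_levels),
                dimnames = list(seq_len(len), aa_levels))
    df <- tally$counts
    df <- df[df$orf_id == orf_id & df$position <= len &
               df$obs_aa %in% aa_levels, , drop = FALSE]
    for (i in seq_len(nrow(df))) {
      m[df$position[i], df$obs_aa[i]] <- m[df$position[i], df$obs_aa[i]] +
        df$count[i]
    }
    m
  }
  fr_m <- per_aa_mat(fr_tally)
  fl_m <- per_aa_mat(fl_tally)
  pl <- cbind(FR = rowSums(fr_m), FL = rowSums(fl_m))
  rownames(pl) <- seq_len(len)
  norm_rows <- function(m) {
    s <- rowSums(m)
    m[s > 0, ] <- m[s > 0, , drop = FALSE] / s[s > 0]
    m
  }
  if (normalize) {
    pl <- norm_rows(pl); fr_m <- norm_rows(fr_m); fl_m <- norm_rows(fl_m)
  }
  list(position_library = pl, per_aa = list(FR = fr_m, FL = fl_m))
}

#' Render a positional heatmap
#'
#' Convenience plot of the `position x {FR, FL}` matrix (requires the
#' `pheatmap` package).
#'
#' @param hm Result of [heatmap_matrix()].
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @return The `pheatmap` object, invisibly.
#' @export
plot_effect_heatmap <- function(hm, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_effect_heatmap requires the 'pheatmap' package")
  }
  m <- t(hm$position_library)
  p <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                          filename = file %||% NA)
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
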