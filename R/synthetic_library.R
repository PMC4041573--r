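# Synthetic generative model of the screen: a ground-truth fitness map over
# (residue, amino acid), iterated mutagenesis/selection cycles in which
# function-retained variants seed the next cycle, equal-mass pooling across
# cycles, and single-end read sequencing with substitution errors.
#
# The phenotype model is epistasis-free: a variant loses function iff it
# carries at least one lost-class amino-acid substitution, gains a stop, or
# breaks the reading frame. This matches the assumption the scoring layer
# makes when it attributes function loss to individual sites, which is what
# makes parameter recovery a meaningful test.

#' Build a ground-truth fitness map
#'
#' Designates `n_deleterious` residue positions of the target protein as
#' deleterious sites: every non-wild-type amino acid at such a position is
#' lost-class (a knockout site). All substitutions at the remaining positions
#' are retained-class. Stop gains and frame breaks are always lost-class
#' regardless of position. Position 1 (the start codon) is never drawn as a
#' deleterious site, since any non-synonymous change there is confounded with
#' loss of translation initiation.
#'
#' @param model A `reference_model`.
#' @param n_deleterious Number of deleterious positions (default 30).
#' @param orf_id Target ORF (defaults to the ORF with role `target`).
#' @return An object of class `fitness_map`: list with `orf_id`,
#'   `protein_length`, `deleterious_positions` (sorted integer vector), and
#'   `wt` (wild-type protein string).
#' @export
make_fitness_map <- function(model, n_deleterious = 30L, orf_id = NULL) {
  if (is.null(orf_id)) orf_id <- .target_orf(model)
  wt <- translate_orf(model, orf_id)
  len <- nchar(wt)
  stopifnot(n_deleterious >= 1L, n_deleterious <= len - 1L)
  del <- sort(sample(2:len, n_deleterious))
  structure(list(orf_id = orf_id, protein_length = len,
                 deleterious_positions = del, wt = wt),
            class = "fitness_map")
}

#' Phenotype class of an amino-acid substitution
#'
#' @param fitness A `fitness_map`.
#' @param pos Residue position(s), 1-based.
#' @param aa Observed amino acid(s) (`"*"` for stop).
#' @return Character vector of `"retained"` / `"lost"`; the wild-type amino
#'   acid at any position is always `"retained"`.
#' @export
fitness_class <- function(fitness, pos, aa) {
  stopifnot(inherits(fitness, "fitness_map"), length(pos) == length(aa))
  wt <- substring(fitness$wt, pos, pos)
  lost <- aa == "*" |
    (pos %in% fitness$deleterious_positions & aa != wt)
  ifelse(lost, "lost", "retained")
}

#' Assign a phenotype to a variant coding sequence
#'
#' Translates the variant (which must include the stop codon, like the
#' wild-type ORF) and applies the epistasis-free AND model: the phenotype is
#' `"lost"` if any substitution is lost-class, any stop codon is gained, or
#' the terminal stop codon is destroyed; `"retained"` otherwise. A variant
#' carrying retained-class substitutions plus a single lost-class one is
#' therefore lost.
#'
#' @param variant DNA string, same length as the target ORF.
#' @param model A `reference_model`.
#' @param fitness A `fitness_map`.
#' @return `"retained"` or `"lost"`.
#' @export
assign_phenotype <- function(variant, model, fitness) {
  o <- .get_orf(model, fitness$orf_id)
  if (nchar(variant) != o$end - o$start) {
    stop("variant length (", nchar(variant), ") does not match ORF length (",
         o$end - o$start, ")")
  }
  aa <- translate_nt(variant)
  n <- nchar(aa)
  body_len <- fitness$protein_length
  body <- substr(aa, 1L, body_len)
  if (grepl("\\*", body)) return("lost")
  if (n > body_len && substr(aa, n, n) != "*") return("lost")
  wt_chars <- strsplit(fitness$wt, NULL)[[1L]]
  obs_chars <- strsplit(body, NULL)[[1L]]
  diff <- which(obs_chars != wt_chars)
  if (!length(diff)) return("retained")
  cls <- fitness_class(fitness, diff, obs_chars[diff])
  if (any(cls == "lost")) "lost" else "retained"
}

#' Construct a variant library
#'
#' @param cds Character vector of coding sequences.
#' @param cycle Integer vector of cycle-of-origin indices.
#' @param library_id `"FR"` or `"FL"`.
#' @param template_id Optional integer vector: row index (within the previous
#'   cycle's FR library) of each variant's template, `NA` for wild type.
#' @return Object of class `variant_library`: data frame with columns
#'   `variant_id`, `cycle`, `cds`, `template_id` and attribute `library_id`.
#' @export
variant_library <- function(cds, cycle, library_id, template_id = NA_integer_) {
  stopifnot(library_id %in% c("FR", "FL"), length(cds) == length(cycle))
  df <- data.frame(
    variant_id = sprintf("%s_c%02d_v%04d", library_id, cycle, seq_along(cds)),
    cycle = as.integer(cycle), cds = cds,
    template_id = rep_len(as.integer(template_id), length(cds)),
    stringsAsFactors = FALSE)
  structure(df, library_id = library_id,
            class = c("variant_library", "data.frame"))
}

#' Run iterated mutagenesis/selection cycles
#'
#' Emulates the screen: in cycle 1 the wild-type ORF is the PCR template; in
#' cycle `k > 1` templates are drawn uniformly from the function-retained
#' variants of cycle `k - 1`. Candidate variants are generated with
#' [mutate_sequence()] and routed by [assign_phenotype()] until each class
#' holds `n_per_class` variants for the cycle, mirroring the picking of equal
#' numbers of fluorescent and non-fluorescent colonies.
#'
#' @param model A `reference_model`.
#' @param fitness A `fitness_map`.
#' @param spectrum A `mutation_spectrum`.
#' @param n_cycles Number of mutagenesis/selection cycles (default 10).
#' @param n_per_class Variants selected per class per cycle (default 200).
#' @param n_mut_range Substitutions per PCR, uniform interval (default 1–6).
#' @param max_attempts_per_cycle Safety bound on candidate generation per
#'   cycle; exceeding it signals a fitness map too extreme to populate both
#'   classes.
#' @return List with elements `fr` and `fl`, each a `variant_library` of
#'   `n_cycles * n_per_class` variants.
#' @export
run_selection_cycles <- function(model, fitness, spectrum,
                                 n_cycles = 10L, n_per_class = 200L,
                                 n_mut_range = c(1L, 6L),
                                 max_attempts_per_cycle = 1000L * n_per_class) {
  stopifnot(n_cycles >= 1L, n_per_class >= 1L)
  wt_cds <- orf_nt(model, fitness$orf_id)
  fr_all <- list(); fl_all <- list()
  templates <- wt_cds

  for (cyc in seq_len(n_cycles)) {
    fr <- character(0); fl <- character(0)
    fr_tpl <- integer(0); fl_tpl <- integer(0)
    attempts <- 0L
    while ((length(fr) < n_per_class || length(fl) < n_per_class)) {
      attempts <- attempts + 1L
      if (attempts > max_attempts_per_cycle) {
        stop("cycle ", cyc, ": could not collect ", n_per_class,
             " variants per class within ", max_attempts_per_cycle,
             " attempts; fitness map too extreme")
      }
      ti <- if (length(templates) == 1L) 1L else sample.int(length(templates), 1L)
      cand <- mutate_sequence(templates[ti], spectrum, n_mut_range)
      ph <- assign_phenotype(cand, model, fitness)
      if (ph == "retained" && length(fr) < n_per_class) {
        fr <- c(fr, cand); fr_tpl <- c(fr_tpl, if (cyc == 1L) NA_integer_ else ti)
      } else if (ph == "lost" && length(fl) < n_per_class) {
        fl <- c(fl, cand); fl_tpl <- c(fl_tpl, if (cyc == 1L) NA_integer_ else ti)
      }
    }
    fr_all[[cyc]] <- variant_library(fr, rep(cyc, n_per_class), "FR", fr_tpl)
    fl_all[[cyc]] <- variant_library(fl, rep(cyc, n_per_class), "FL", fl_tpl)
    templates <- fr  # function-retained variants seed the next cycle
  }

  bind <- function(parts, id) {
    df <- do.call(rbind, lapply(parts, as.data.frame))
    structure(df, library_id = id, class = c("variant_library", "data.frame"))
  }
  list(fr = bind(fr_all, "FR"), fl = bind(fl_all, "FL"))
}

#' Ground-truth amino-acid substitutions of a variant library
#'
#' Compares each variant's translation to the wild-type protein and lists
#' every amino-acid substitution it carries, both as a per-variant
#' semicolon-joined token string (e.g. `"L65F;Q123R"`) and in long format.
#'
#' @param library A `variant_library`.
#' @param model A `reference_model`.
#' @param orf_id Target ORF (defaults to the `target` role).
#' @return List with `per_variant` (data frame: `variant_id`, `library`,
#'   `cycle`, `substitutions`) and `long` (data frame: `variant_id`,
#'   `library`, `cycle`, `position`, `wt_aa`, `obs_aa`).
#' @export
ground_truth <- function(library, model, orf_id = NULL) {
  if (is.null(orf_id)) orf_id <- .target_orf(model)
  wt <- translate_orf(model, orf_id)
  wt_chars <- strsplit(wt, NULL)[[1L]]
  lib_id <- attr(library, "library_id")
  rows <- vector("list", nrow(library))
  tokens <- character(nrow(library))
  for (i in seq_len(nrow(library))) {
    aa <- translate_nt(library$cds[i])
    obs <- strsplit(substr(aa, 1L, nchar(wt)), NULL)[[1L]]
    d <- which(obs != wt_chars)
    tokens[i] <- paste(sprintf("%s%d%s", wt_chars[d], d, obs[d]), collapse = ";")
    if (length(d)) {
      rows[[i]] <- data.frame(variant_id = library$variant_id[i],
                              library = lib_id, cycle = library$cycle[i],
                              position = d, wt_aa = wt_chars[d],
                              obs_aa = obs[d], stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(long)) {
    long <- data.frame(variant_id = character(0), library = character(0),
                       cycle = integer(0), position = integer(0),
                       wt_aa = character(0), obs_aa = character(0))
  }
  per_variant <- data.frame(variant_id = library$variant_id, library = lib_id,
                            cycle = library$cycle, substitutions = tokens,
                            stringsAsFactors = FALSE)
  list(per_variant = per_variant, long = long)
}

#' Simulate pooled single-end sequencing reads
#'
#' Draws reads from whole-plasmid fragments of library variants: the variant
#' coding sequence is spliced into the plasmid at the target ORF, cycles are
#' weighted equally (equal-mass pooling), fragment start positions are
#' uniform over the (circular) plasmid, and substitution sequencing errors
#' are applied at `base_error_rate` per base. Qualities are constant
#' Phred+33 `"I"` (Q40); the simulator does not model quality degradation.
#'
#' @param model A `reference_model`.
#' @param library A `variant_library`.
#' @param n_reads Number of reads to draw.
#' @param read_len Read length in bases (default 50).
#' @param base_error_rate Per-base substitution sequencing-error probability.
#' @param orf_id Target ORF into which variant sequences are spliced.
#' @return Data frame with columns `read_id`, `seq`, `variant_id`, `cycle`,
#'   `start` (0-based plasmid offset), `n_errors`.
#' @export
simulate_reads <- function(model, library, n_reads, read_len = 50L,
                           base_error_rate = 0, orf_id = NULL) {
  stopifnot(n_reads >= 1L)
  if (read_len > model$length) stop("read_len exceeds plasmid length")
  if (is.null(orf_id)) orf_id <- .target_orf(model)
  o <- .get_orf(model, orf_id)
  L <- model$length
  lib_id <- attr(library, "library_id")

  # equal-mass pooling: cycle uniform, then variant uniform within cycle
  cycles <- sort(unique(library$cycle))
  cyc <- cycles[sample.int(length(cycles), n_reads, replace = TRUE)]
  idx_by_cycle <- split(seq_len(nrow(library)), library$cycle)
  vidx <- integer(n_reads)
  for (cy in cycles) {
    sel <- which(cyc == cy)
    pool <- idx_by_cycle[[as.character(cy)]]
    vidx[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
  }
  start <- sample.int(L, n_reads, replace = TRUE) - 1L

  # splice each distinct variant into the plasmid once, then slice reads
  seqs <- character(n_reads)
  for (vi in unique(vidx)) {
    cds <- library$cds[vi]
    ins <- if (o$strand == "-") revcomp(cds) else cds
    if (o$end <= L) {
      varpl <- paste0(substr(model$seq, 1L, o$start), ins,
                      substr(model$seq, o$end + 1L, L))
    } else {
      # ORF wraps the origin: tail of the insert replaces the plasmid head
      tail_len <- o$end - L
      varpl <- paste0(substr(ins, nchar(ins) - tail_len + 1L, nchar(ins)),
                      substr(model$seq, tail_len + 1L, o$start),
                      substr(ins, 1L, nchar(ins) - tail_len))
    }
    doubled <- paste0(varpl, varpl)
    sel <- which(vidx == vi)
    seqs[sel] <- substring(doubled, start[sel] + 1L, start[sel] + read_len)
  }

  # substitution sequencing errors
  n_err <- if (base_error_rate > 0) rbinom(n_reads, read_len, base_error_rate)
           else integer(n_reads)
  for (i in which(n_err > 0L)) {
    chars <- strsplit(seqs[i], NULL)[[1L]]
    at <- sample.int(read_len, n_err[i])
    for (p in at) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    seqs[i] <- paste(chars, collapse = "")
  }

  data.frame(
    read_id = sprintf("%s_r%06d_%s", lib_id, seq_len(n_reads),
                      library$variant_id[vidx]),
    seq = seqs, variant_id = library$variant_id[vidx],
    cycle = library$cycle[vidx], start = start, n_errors = n_err,
    stringsAsFactors = FALSE)
}

#' Write simulated reads to FASTQ
#'
#' Four-line FASTQ records with constant Phred+33 quality `"I"`.
#'
#' @param reads Data frame from [simulate_reads()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  out <- c(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(out, path)
  invisible(path)
}
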