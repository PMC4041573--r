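# Reference model: the expression plasmid, its annotated ORFs (one scored
# target gene, one control gene used for sequencing-error estimation), and
# codon-level translation services.
#
# Coordinate conventions: plasmid coordinates are 0-based half-open; residue
# positions are 1-based within each ORF, so reports match the usual residue
# labels (C62, L65, ...). Minus-strand ORFs are reverse-complemented before
# translation and always reported in protein space.

#' Load and validate a plasmid reference with ORF annotations
#'
#' Reads a single-record FASTA and an ORF annotation config (YAML or JSON, or
#' an equivalent R list) and returns a validated reference model. The config
#' must annotate exactly one ORF with `role: target` (the scored gene) and
#' exactly one with `role: control` (the antibiotic-resistance gene used for
#' error-rate estimation).
#'
#' Every ORF must lie within the plasmid (coordinates may run past the
#' sequence end only when `circular: true`, in which case the ORF wraps
#' across the origin), have a length that is a multiple of three, and
#' translate without internal stop codons. A trailing stop codon is allowed
#' and excluded from the protein.
#'
#' @param fasta_path Path to a single-record FASTA file (case-insensitive
#'   sequence; only A/C/G/T after upper-casing).
#' @param orf_config Path to a YAML/JSON file, or a list, with an optional
#'   logical `circular` and an `orfs` list whose entries carry `orf_id`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `strand`
#'   (`"+"`/`"-"`), and `role` (`"target"`/`"control"`).
#' @return An object of class `reference_model`: a list with `seq`, `length`,
#'   `circular`, `orfs` (data frame), and `proteins` (named list of wild-type
#'   amino-acid strings, stop codon excluded).
#' @seealso [translate_orf()], [residue_at()], [write_synthetic_reference()]
#' @export
load_reference <- function(fasta_path, orf_config) {
  if (is.character(fasta_path) && !file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  recs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(recs) != 1L) {
    stop("expected exactly one FASTA record, found ", length(recs))
  }
  seq <- toupper(as.character(recs[[1L]]))
  .check_dna(seq)

  cfg <- .read_orf_config(orf_config)
  orfs <- cfg$orfs
  circular <- isTRUE(cfg$circular)
  L <- nchar(seq)

  if (sum(orfs$role == "target") != 1L || sum(orfs$role == "control") != 1L) {
    stop("ORF config must annotate exactly one 'target' and one 'control' ORF")
  }
  if (anyDuplicated(orfs$orf_id)) stop("duplicate orf_id in config")

  model <- structure(
    list(seq = seq, length = L, circular = circular, orfs = orfs,
         proteins = list(), cache = new.env(parent = emptyenv())),
    class = "reference_model"
  )

  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    if (o$start < 0L || o$start >= L) {
      stop("ORF '", o$orf_id, "' start out of bounds")
    }
    max_end <- if (circular) o$start + L else L
    if (o$end <= o$start || o$end > max_end) {
      stop("ORF '", o$orf_id, "' out of bounds",
           if (!circular) " (wrap-around requires circular: true)")
    }
    if ((o$end - o$start) %% 3L != 0L) {
      stop("ORF '", o$orf_id, "' length not multiple of 3")
    }
    nt <- orf_nt(model, o$orf_id)
    aa <- translate_nt(nt)
    n <- nchar(aa)
    body <- if (substr(aa, n, n) == "*") substr(aa, 1L, n - 1L) else aa
    if (grepl("\\*", body)) {
      stop("ORF '", o$orf_id, "' contains an internal stop codon")
    }
    model$proteins[[o$orf_id]] <- body
  }
  model
}

.read_orf_config <- function(orf_config) {
  if (is.character(orf_config)) {
    if (!file.exists(orf_config)) stop("ORF config file not found: ", orf_config)
    cfg <- if (grepl("\\.json$", orf_config, ignore.case = TRUE)) {
      jsonlite::read_json(orf_config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(orf_config)
    }
  } else if (is.list(orf_config)) {
    cfg <- orf_config
  } else {
    stop("orf_config must be a file path or a list")
  }
  if (is.null(cfg$orfs)) stop("ORF config lacks an 'orfs' entry")
  req <- c("orf_id", "start", "end", "strand", "role")
  rows <- lapply(cfg$orfs, function(o) {
    miss <- setdiff(req, names(o))
    if (length(miss)) stop("ORF entry missing field(s): ", paste(miss, collapse = ", "))
    if (!o$strand %in% c("+", "-")) stop("ORF strand must be '+' or '-'")
    if (!o$role %in% c("target", "control")) stop("ORF role must be 'target' or 'control'")
    data.frame(orf_id = as.character(o$orf_id), start = as.integer(o$start),
               end = as.integer(o$end), strand = o$strand, role = o$role,
               stringsAsFactors = FALSE)
  })
  list(orfs = do.call(rbind, rows), circular = isTRUE(cfg$circular))
}

.get_orf <- function(model, orf_id) {
  i <- match(orf_id, model$orfs$orf_id)
  if (is.na(i)) stop("unknown orf_id: ", orf_id)
  model$orfs[i, ]
}

#' Coding nucleotide sequence of an ORF
#'
#' Extracts the ORF from the plasmid (wrapping across the origin for circular
#' plasmids) and reverse-complements minus-strand ORFs, so the result always
#' reads 5' to 3' in coding orientation.
#'
#' @param model A `reference_model`.
#' @param orf_id ORF identifier.
#' @return DNA string of the coding sequence (including any stop codon).
#' @export
orf_nt <- function(model, orf_id) {
  o <- .get_orf(model, orf_id)
  s <- if (o$end <= model$length) {
    substr(model$seq, o$start + 1L, o$end)
  } else {
    paste0(substr(model$seq, o$start + 1L, model$length),
           substr(model$seq, 1L, o$end - model$length))
  }
  if (o$strand == "-") revcomp(s) else s
}

#' Translate an annotated ORF
#'
#' @inheritParams orf_nt
#' @return Wild-type amino-acid string; the trailing stop codon, if the ORF
#'   ends in one, is excluded.
#' @export
translate_orf <- function(model, orf_id) {
  .get_orf(model, orf_id)  # validates orf_id
  model$proteins[[orf_id]]
}

#' Wild-type residue at a protein position
#'
#' @inheritParams orf_nt
#' @param pos 1-based residue index within the ORF's protein.
#' @return Single amino-acid letter, e.g. `"L"` for L65.
#' @export
residue_at <- function(model, orf_id, pos) {
  prot <- translate_orf(model, orf_id)
  if (length(pos) != 1L || !is.numeric(pos) || pos != as.integer(pos) ||
      pos < 1L || pos > nchar(prot)) {
    stop("residue position out of range (1..", nchar(prot), ")")
  }
  substr(prot, pos, pos)
}

#' @export
print.reference_model <- function(x, ...) {
  cat("reference_model: ", x$length, " bp plasmid (",
      if (x$circular) "circular" else "linear", ")\n", sep = "")
  for (i in seq_len(nrow(x$orfs))) {
    o <- x$orfs[i, ]
    cat(sprintf("  %-10s %6d..%-6d %s %-8s %d aa\n", o$orf_id, o$start, o$end,
                o$strand, o$role, nchar(x$proteins[[o$orf_id]])))
  }
  invisible(x)
}

.target_orf <- function(model) model$orfs$orf_id[model$orfs$role == "target"]
.control_orf <- function(model) model$orfs$orf_id[model$orfs$role == "control"]
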