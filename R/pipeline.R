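# End-to-end orchestration: simulate (or load) -> map -> call -> score, as a
# single seeded, reproducible run with a machine-readable JSON report. Each
# stage remains individually callable; the pipeline only sequences them and
# records the numbers.

#' Default pipeline configuration
#'
#' Returns the configuration of a full synthetic run emulating the study
#' design: ten mutagenesis/selection cycles of 200 variants per class per
#' cycle (libraries of 2,000 variants each), 1–6 nucleotide substitutions
#' per PCR, an error-prone PCR spectrum with transversion/transition ratio
#' 0.9 and no A/T vs G/C bias, 30 deleterious residues out of 137, 15 of
#' them designated as the known standard sites for cutoff calibration,
#' 50-bp single-end reads, and a per-base sequencing-error rate calibrated
#' so the control-gene protein-level error rate is about 0.13%.
#'
#' @param seed Integer seed controlling every random stage.
#' @param n_reads Reads per library (default 30,000; scale to taste).
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_reads = 30000L) {
  list(
    seed = as.integer(seed),
    reference = list(synthetic = TRUE),
    simulate = list(
      n_cycles = 10L, n_per_class = 200L, n_mut_range = c(1L, 6L),
      tv_ts_ratio = 0.9, at_gc_balance = 1.0,
      n_deleterious = 30L, n_standard_sites = 15L,
      read_len = 50L, n_reads = as.integer(n_reads),
      base_error_rate = 3.7e-05
    ),
    map = list(mismatch_cost = 2, insertion_cost = 3, deletion_cost = 3,
               similarity_fraction = 0.8, length_fraction = 0.5),
    filter = list(denominator = "coverage")
  )
}

.validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$seed))
  has_sim <- !is.null(config$simulate)
  has_fastq <- !is.null(config$fastq)
  if (has_sim == has_fastq) {
    stop("config must provide exactly one of 'simulate' or 'fastq'")
  }
  if (has_fastq && (is.null(config$fastq$fr) || is.null(config$fastq$fl))) {
    stop("config$fastq must name 'fr' and 'fl' FASTQ paths")
  }
  config
}

#' Run the full deep-mutational-scanning pipeline
#'
#' Executes simulate (or load FASTQ) -> map -> call -> filter -> score and
#' writes all stage outputs plus a JSON report to `out_dir`. With a fixed
#' seed and configuration the report is byte-identical across runs.
#'
#' The report contains: mapping statistics per library, control-gene error
#' rates, substitution set sizes before and after filtering, the
#' shared/unique partition, the calibrated threshold and sensitive residue
#' set, and — for simulated inputs — recovery sensitivity and specificity of
#' the sensitive set against the ground-truth deleterious positions (over
#' all residues; residues with undefined effect count as negative calls).
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @param out_dir Output directory (created if missing).
#' @return The report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  prov <- sprintf("dmscan %s config=%s seed=%d",
                  as.character(packageVersion("dmscan")), cfg_hash,
                  config$seed)
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  # --- reference ------------------------------------------------------
  if (isTRUE(config$reference$synthetic) || is.null(config$reference)) {
    paths <- write_synthetic_reference(file.path(out_dir, "reference"))
  } else {
    paths <- list(fasta = config$reference$fasta,
                  orf_config = config$reference$orf_config)
  }
  model <- load_reference(paths$fasta, paths$orf_config)
  target <- .target_orf(model)
  control <- .control_orf(model)
  msg("reference", model$length, " bp plasmid; target '", target,
      "' (", nchar(model$proteins[[target]]), " aa)")

  # --- input: simulate or load ---------------------------------------
  truth <- NULL; fitness <- NULL; standard_sites <- config$standard_sites
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    spectrum <- build_spectrum(sim$tv_ts_ratio, sim$at_gc_balance)
    fitness <- make_fitness_map(model, sim$n_deleterious)
    if (is.null(standard_sites)) {
      standard_sites <- sort(sample(fitness$deleterious_positions,
                                    sim$n_standard_sites))
    }
    msg("simulate", "running ", sim$n_cycles, " selection cycles x ",
        sim$n_per_class, "/class")
    libs <- run_selection_cycles(model, fitness, spectrum,
                                 n_cycles = sim$n_cycles,
                                 n_per_class = sim$n_per_class,
                                 n_mut_range = sim$n_mut_range)
    truth <- rbind(ground_truth(libs$fr, model)$per_variant,
                   ground_truth(libs$fl, model)$per_variant)
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fq <- list(fr = file.path(out_dir, "fr.fastq"),
               fl = file.path(out_dir, "fl.fastq"))
    for (lib in c("fr", "fl")) {
      reads <- simulate_reads(model, libs[[lib]], n_reads = sim$n_reads,
                              read_len = sim$read_len,
                              base_error_rate = sim$base_error_rate)
      write_fastq(reads, fq[[lib]])
    }
    msg("simulate", "wrote ", sim$n_reads, " reads per library")
  } else {
    fq <- list(fr = config$fastq$fr, fl = config$fastq$fl)
  }

  # --- map + call -----------------------------------------------------
  params <- do.call(map_params, config$map %||% list())
  tallies <- list(); stats <- list(); rates <- list()
  for (lib in c("fr", "fl")) {
    mapped <- map_library(fq[[lib]], model, params)
    stats[[lib]] <- mapped$stats
    msg("map", lib, ": ", mapped$stats$n_mapped_reads, "/",
        mapped$stats$n_total_reads, " uniquely mapped")
    tallies[[lib]] <- tally_library(mapped, model, toupper(lib))
    rates[[lib]] <- estimate_error_rate(tallies[[lib]], control)
    msg("call", lib, ": ", nrow(tallies[[lib]]$counts),
        " distinct substitutions; control error ",
        sprintf("%.3f%%", rates[[lib]]$rate_percent))
  }

  # --- filter + score -------------------------------------------------
  denom <- config$filter$denominator %||% "coverage"
  filtered <- list(
    fr = filter_by_error(tallies$fr, rates$fr, orf_id = target,
                         denominator = denom),
    fl = filter_by_error(tallies$fl, rates$fl, orf_id = target,
                         denominator = denom))
  part <- shared_unique(filtered$fr, filtered$fl, orf_id = target)
  profile <- positional_effect(filtered$fr, filtered$fl, orf_id = target)
  calib <- if (!is.null(standard_sites)) {
    calibrate_cutoff(profile, standard_sites)
  }

  hydro <- if (!is.null(config$hydrophobicity$positions)) {
    hydrophobicity_counts(filtered$fr, filtered$fl,
                          config$hydrophobicity$positions,
                          orf_id = target)
  }

  recovery <- NULL
  if (!is.null(fitness) && !is.null(calib)) {
    del <- fitness$deleterious_positions
    all_pos <- seq_len(fitness$protein_length)
    called <- all_pos %in% calib$sensitive_set
    is_del <- all_pos %in% del
    recovery <- list(
      n_deleterious = length(del),
      sensitivity = sum(called & is_del) / sum(is_del),
      specificity = sum(!called & !is_del) / sum(!is_del))
    msg("score", sprintf("recovery: sensitivity %.3f, specificity %.3f",
                         recovery$sensitivity, recovery$specificity))
  }

  # --- outputs --------------------------------------------------------
  write_tally_tsv(filtered$fr, file.path(out_dir, "fr_tally.tsv"), prov)
  write_tally_tsv(filtered$fl, file.path(out_dir, "fl_tally.tsv"), prov)
  pe_path <- file.path(out_dir, "positional_effect.tsv")
  pe <- as.data.frame(profile)
  if (!is.null(calib)) pe$sensitive <- pe$position %in% calib$sensitive_set
  con <- file(pe_path, "w"); writeLines(paste0("# ", prov), con)
  utils::write.table(pe, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  hm <- heatmap_matrix(filtered$fr, filtered$fl, orf_id = target)
  utils::write.table(
    data.frame(position = as.integer(rownames(hm$position_library)),
               hm$position_library),
    file.path(out_dir, "heatmap.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  report <- list(
    tool = "dmscan", version = as.character(packageVersion("dmscan")),
    seed = config$seed, config_hash = cfg_hash,
    mapping = lapply(stats, unclass),
    error_rates = lapply(rates, unclass),
    n_substitutions_unfiltered = lapply(tallies, function(t)
      sum(t$counts$orf_id == target)),
    n_substitutions_filtered = lapply(filtered, function(t)
      sum(t$counts$orf_id == target)),
    partition = as.list(part$sizes),
    threshold = calib$threshold,
    n_sensitive = length(calib$sensitive_set),
    sensitive_set = calib$sensitive_set,
    standard_sites = standard_sites,
    n_standard_captured = calib$n_standard_captured,
    deleterious_positions = if (!is.null(fitness)) fitness$deleterious_positions,
    recovery = recovery,
    hydrophobicity = if (!is.null(hydro)) as.list(hydro$totals)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
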