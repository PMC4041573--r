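# small helper: build a tally directly from (position, obs_aa, count) rows
quick_tally <- function(rows, library_id, n_reads = 10000L, len = 137L,
                        coverage_per_pos = NULL) {
  counts <- data.frame(orf_id = rep_len("fbfp", nrow(rows)),
                       position = rows$position,
                       wt_aa = rows$wt_aa, obs_aa = rows$obs_aa,
                       count = rows$count, stringsAsFactors = FALSE)
  cov <- NULL
  if (!is.null(coverage_per_pos)) {
    cov <- list(fbfp = rep.int(as.integer(coverage_per_pos), len + 1L))
  }
  mutation_tally(counts, library_id, coverage = cov,
                 n_reads_orf = c(fbfp = n_reads, ampR = n_reads),
                 protein_lengths = c(fbfp = len, ampR = 286L))
}

rows_df <- function(position, obs_aa, count,
                    wt_aa = rep_len("L", length(position))) {
  data.frame(position = position, wt_aa = wt_aa, obs_aa = obs_aa,
             count = count, stringsAsFactors = FALSE)
}

test_that("error rate is control mutations over control reads", {
  counts <- data.frame(orf_id = "ampR", position = c(10L, 20L),
                       wt_aa = "A", obs_aa = c("V", "T"), count = c(8L, 5L))
  tal <- mutation_tally(counts, "FR",
                        coverage = list(ampR = rep.int(5000L, 287L)),
                        n_reads_orf = c(fbfp = 1L, ampR = 10000L),
                        protein_lengths = c(fbfp = 137L, ampR = 286L))
  est <- estimate_error_rate(tal, "ampR")
  expect_equal(est$rate_percent, 0.13)
  expect_equal(est$n_control_mutations, 13)

  tal0 <- quick_tally(rows_df(5L, "V", 3L), "FR")
  est0 <- estimate_error_rate(tal0, "ampR")  # no control calls -> 0%
  expect_equal(est0$rate_percent, 0)
  tal0$n_reads_orf[["ampR"]] <- 0L
  expect_error(estimate_error_rate(tal0, "ampR"), "no reads")
})

test_that("frequency filter removes sub-error-rate entries and is idempotent", {
  # counts 1 and 50 over 10,000 reads: 0.01% and 0.5% against 0.13%
  tal <- quick_tally(rows_df(c(10L, 20L), c("V", "W"), c(1L, 50L)), "FL",
                     coverage_per_pos = 10000L)
  rate <- structure(list(library_id = "FL", n_control_mutations = 13L,
                         n_control_reads = 10000L, rate_percent = 0.13),
                    class = "error_rate_estimate")
  for (den in c("reads", "coverage")) {
    f <- filter_by_error(tal, rate, orf_id = "fbfp", denominator = den)
    expect_equal(f$counts$position, 20L)
    expect_equal(f$counts$count, 50L)  # surviving counts unchanged
    f2 <- filter_by_error(f, rate, orf_id = "fbfp", denominator = den)
    expect_identical(f2$counts, f$counts)  # idempotent
  }
  # rate 0 keeps everything
  expect_equal(nrow(filter_by_error(tal, 0)$counts), 2L)
  # library mismatch is refused
  rate_fr <- rate; rate_fr$library_id <- "FR"
  expect_error(filter_by_error(tal, rate_fr), "library")
})

test_that("filtering is monotone: output entries are a subset of input", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    tal <- quick_tally(rows_df(sample(1:137, n), sample(c("V", "W", "R"), n, TRUE),
                               sample(1:80, n, TRUE)),
                       "FL", coverage_per_pos = 3000L)
    th <- runif(1, 0, 2)
    f <- filter_by_error(tal, th)
    key <- function(d) paste(d$position, d$obs_aa)
    expect_true(all(key(f$counts) %in% key(tal$counts)))
    expect_true(all(f$counts$count %in% tal$counts$count))
  }
})

test_that("shared/unique partition follows set arithmetic", {
  fr <- quick_tally(rows_df(c(1L, 2L), c("V", "W"), c(5L, 5L), wt_aa = "A"), "FR")
  fl <- quick_tally(rows_df(c(1L, 2L), c("V", "W"), c(7L, 2L), wt_aa = "A"), "FL")
  part <- shared_unique(fr, fl)
  expect_length(part$fl_unique, 0L)
  expect_length(part$fr_unique, 0L)
  expect_equal(unname(part$sizes["shared"]), 2L)

  fr2 <- quick_tally(rows_df(1L, "V", 5L, "A"), "FR")
  fl2 <- quick_tally(rows_df(2L, "W", 5L, "A"), "FL")
  part2 <- shared_unique(fr2, fl2)
  expect_length(part2$shared, 0L)
  expect_equal(unname(part2$sizes[c("fl_unique", "fr_unique")]), c(1L, 1L))

  set.seed(67)
  for (i in 1:10) {
    fr3 <- quick_tally(rows_df(sample(1:137, 20), sample(c("V", "W", "R"), 20, TRUE),
                               rep(5L, 20)), "FR")
    fl3 <- quick_tally(rows_df(sample(1:137, 20), sample(c("V", "W", "R"), 20, TRUE),
                               rep(5L, 20)), "FL")
    p <- shared_unique(fr3, fl3)
    expect_equal(unname(p$sizes["shared"] + p$sizes["fl_unique"]),
                 unname(p$sizes["fl"]))
    expect_equal(unname(p$sizes["shared"] + p$sizes["fr_unique"]),
                 unname(p$sizes["fr"]))
  }
})

test_that("positional effect is FL over total, undefined on empty positions", {
  fr <- quick_tally(rows_df(c(28L, 30L), c("V", "W"), c(27L, 10L), "A"), "FR")
  fl <- quick_tally(rows_df(c(28L, 31L), c("T", "R"), c(45L, 47L), "A"), "FL")
  prof <- positional_effect(fr, fl)
  expect_equal(prof$effect[28], 45 / (45 + 27))
  expect_equal(prof$effect[28], 0.625)
  expect_equal(prof$effect[30], 0)    # FL absent, FR present
  expect_equal(prof$effect[31], 1)    # FR absent, FL present
  expect_true(is.na(prof$effect[29])) # no mutations: undefined, not 0
  expect_equal(nrow(prof), 137L)

  # bounded in [0,1] and increasing in fl_count at fixed fr_count
  effs <- vapply(1:60, function(fl_n) {
    positional_effect(quick_tally(rows_df(5L, "V", 12L), "FR"),
                      quick_tally(rows_df(5L, "W", fl_n), "FL"))$effect[5]
  }, 0)
  expect_true(all(effs >= 0 & effs <= 1))
  expect_true(all(diff(effs) > 0))
})

test_that("cutoff calibration recovers a perfectly separated standard set", {
  std <- c(10L, 20L, 30L)
  rows_fr <- rows_df(setdiff(1:40, std), "V", 50L)
  rows_fl <- rows_df(1:40, "W", c(5L))
  fr <- quick_tally(rows_fr, "FR", len = 40L)
  fl <- quick_tally(rows_fl, "FL", len = 40L)
  prof <- positional_effect(fr, fl)
  # standard sites have effect 1 (FL only), everything else 5/55
  calib <- calibrate_cutoff(prof, std)
  expect_equal(calib$threshold, 1)
  expect_setequal(calib$sensitive_set, std)
  expect_equal(calib$n_standard_captured, 3L)
  expect_equal(calib$youden_j, 1)
  expect_error(calibrate_cutoff(prof, c(10L, 900L)), "outside")
})

test_that("hydrophobicity counts reproduce a printed-style interface table", {
  # nine interface positions with FR/FL hydrophobic+hydrophilic loads
  pos <- c(25L, 27L, 29L, 41L, 111L, 113L, 118L, 120L, 122L)
  fr_rows <- rbind(
    rows_df(pos, "V", c(124L, 55L, 44L, 24L, 159L, 162L, 7L, 18L, 18L), "Y"),
    rows_df(pos, "S", c(11L, 1L, 1L, 1L, 7L, 97L, 12L, 1L, 67L), "Y"))
  fl_rows <- rbind(
    rows_df(pos, "L", c(1L, 1L, 4L, 1L, 1L, 1L, 1L, 1L, 1L), "Y"),
    rows_df(pos, "N", c(1L, 6L, 28L, 42L, 17L, 1L, 5L, 36L, 15L), "Y"))
  fr <- quick_tally(fr_rows, "FR")
  fl <- quick_tally(fl_rows, "FL")
  tab <- hydrophobicity_counts(fr, fl, pos)
  expect_equal(unname(tab$totals),
               unname(colSums(as.matrix(tab$by_position[, -1]))))
  expect_equal(unname(tab$totals["fr_hydrophobic"]), sum(fr_rows$count[1:9]))

  # glycine and stop substitutions are excluded from both classes
  fr_g <- quick_tally(rbind(fr_rows, rows_df(25L, "G", 500L, "Y"),
                            rows_df(25L, "*", 500L, "Y")), "FR")
  tab_g <- hydrophobicity_counts(fr_g, fl, pos)
  expect_equal(tab_g$totals, tab$totals)

  # empty position set -> all-zero table
  tab0 <- hydrophobicity_counts(fr, fl, integer(0))
  expect_equal(unname(tab0$totals), c(0, 0, 0, 0))
})

test_that("heatmap rows are normalised without dividing by zero", {
  fr <- quick_tally(rows_df(5L, "V", 9L), "FR", len = 10L)
  fl <- quick_tally(rows_df(7L, "W", 3L), "FL", len = 10L)
  hm <- heatmap_matrix(fr, fl, normalize = TRUE)
  expect_equal(unname(hm$position_library[5, ]), c(1, 0))
  expect_equal(unname(hm$position_library[7, ]), c(0, 1))
  expect_true(all(hm$position_library[c(1:4, 6, 8:10), ] == 0))
  rs <- rowSums(hm$per_aa$FR)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))

  # degenerate: no counts at all
  fr0 <- quick_tally(rows_df(integer(0), character(0), integer(0)), "FR",
                     len = 10L)
  hm0 <- heatmap_matrix(fr0, fr0, normalize = TRUE)
  expect_true(all(hm0$position_library == 0))
})
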