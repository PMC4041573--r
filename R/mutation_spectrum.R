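# Error-prone PCR substitution model. The spectrum is parameterised by two
# observables that mutagenesis kits report: the transversion/transition
# ratio of the substitutions they induce, and the balance between mutations
# at A/T template positions and at G/C template positions. The spectrum is
# strand-complement symmetric by construction (a substitution on one strand
# is its complement on the other), which is what pooled plasmid sequencing
# observes.

#' Build an error-prone PCR mutation spectrum
#'
#' For each template base there is one transition and two transversions. With
#' transversion/transition ratio `r`, the conditional probabilities given a
#' mutated base are `1/(1+r)` for the transition and `r/(2(1+r))` for each
#' transversion, identically for all four bases — which makes the spectrum
#' strand-complement symmetric (P(A->G) = P(T->C), and so on). The marginal
#' probability that a drawn mutation sits on an A/T versus a G/C template
#' position is controlled by `at_gc_balance` (mass on A/T divided by mass on
#' G/C; 1 means no bias).
#'
#' @param tv_ts_ratio Transversion/transition ratio (> 0). The default 0.9
#'   corresponds to a slight excess of transitions.
#' @param at_gc_balance Ratio of mutation mass at A/T template bases to mass
#'   at G/C template bases (> 0). Default 1 (no compositional bias).
#' @return An object of class `mutation_spectrum`: list with `sub_probs`
#'   (4x4 matrix of P(to | from), zero diagonal, rows sum to 1),
#'   `from_marginals` (named length-4 probability vector), and the two input
#'   parameters.
#' @export
#' @examples
#' sp <- build_spectrum(0.9, 1.0)
#' rowSums(sp$sub_probs)
build_spectrum <- function(tv_ts_ratio = 0.9, at_gc_balance = 1.0) {
  if (!is.numeric(tv_ts_ratio) || tv_ts_ratio <= 0) {
    stop("tv_ts_ratio must be > 0")
  }
  if (!is.numeric(at_gc_balance) || at_gc_balance <= 0) {
    stop("at_gc_balance must be > 0")
  }
  p_ts <- 1 / (1 + tv_ts_ratio)
  p_tv <- tv_ts_ratio / (2 * (1 + tv_ts_ratio))
  transition_of <- c(A = "G", C = "T", G = "A", T = "C")
  P <- matrix(0, 4, 4, dimnames = list(from = DNA_BASES, to = DNA_BASES))
  for (b in DNA_BASES) {
    for (to in setdiff(DNA_BASES, b)) {
      P[b, to] <- if (to == transition_of[[b]]) p_ts else p_tv
    }
  }
  w_at <- at_gc_balance / (1 + at_gc_balance)
  marg <- c(A = w_at / 2, C = (1 - w_at) / 2, G = (1 - w_at) / 2, T = w_at / 2)
  structure(list(sub_probs = P, from_marginals = marg,
                 tv_ts_ratio = tv_ts_ratio, at_gc_balance = at_gc_balance),
            class = "mutation_spectrum")
}

#' Draw substitutions from a mutation spectrum
#'
#' Samples `(from, to)` base pairs: the template base from the spectrum's
#' marginals, the substituted base from the conditional row. Used for
#' spectrum self-consistency checks; sequence mutagenesis goes through
#' [mutate_sequence()], where template bases come from the sequence itself.
#'
#' @param spectrum A `mutation_spectrum`.
#' @param n Number of draws.
#' @return Data frame with columns `from`, `to`, and logical `transition`.
#' @export
sample_substitutions <- function(spectrum, n) {
  stopifnot(inherits(spectrum, "mutation_spectrum"), n >= 1)
  from <- sample(DNA_BASES, n, replace = TRUE, prob = spectrum$from_marginals)
  to <- character(n)
  for (b in DNA_BASES) {
    i <- which(from == b)
    if (length(i)) {
      to[i] <- sample(DNA_BASES, length(i), replace = TRUE,
                      prob = spectrum$sub_probs[b, ])
    }
  }
  data.frame(from = from, to = to,
             transition = .is_transition(from, to),
             stringsAsFactors = FALSE)
}

#' Mutate a coding sequence with an error-prone PCR spectrum
#'
#' Applies `k` nucleotide substitutions, with `k` drawn uniformly from
#' `n_mut_range`, at positions drawn uniformly without replacement; each
#' substituted base is drawn from the spectrum's conditional distribution
#' given the template base at that position. This mirrors one error-prone PCR
#' amplification of the gene insert.
#'
#' @param template DNA string (the coding sequence to mutagenise).
#' @param spectrum A `mutation_spectrum`.
#' @param n_mut_range Integer interval `c(min, max)` for the number of
#'   substitutions per call; default `c(1, 6)`.
#' @return The mutated sequence (same length as the template).
#' @export
mutate_sequence <- function(template, spectrum, n_mut_range = c(1L, 6L)) {
  stopifnot(is.character(template), length(template) == 1L)
  n <- nchar(template)
  if (n == 0L) stop("empty template")
  stopifnot(inherits(spectrum, "mutation_spectrum"),
            length(n_mut_range) == 2L, n_mut_range[1] <= n_mut_range[2],
            n_mut_range[1] >= 0L, n_mut_range[2] <= n)
  k <- if (n_mut_range[1] == n_mut_range[2]) n_mut_range[1] else
    sample(seq.int(n_mut_range[1], n_mut_range[2]), 1L)
  if (k == 0L) return(template)
  pos <- sample.int(n, k)
  chars <- strsplit(template, NULL)[[1L]]
  for (p in pos) {
    chars[p] <- sample(DNA_BASES, 1L, prob = spectrum$sub_probs[chars[p], ])
  }
  paste(chars, collapse = "")
}
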