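#' Power sums of allele frequencies
#'
#' `a_k = sum(p_i^k)`, the building blocks of the exclusion polynomials.
#'
#' @param freqs a `locus_frequencies` object or numeric frequency vector.
#' @param k exponent, `k >= 1`.
#' @return `sum(p^k)`.
#' @export
power_moments <- function(freqs, k) {
  stopifnot(k >= 1)
  sum(.as_p(freqs)^k)
}

#' Probability of parentage exclusion at a locus
#'
#' The chance that a locus genetically excludes a random candidate (drawn
#' under Hardy-Weinberg from the same allele frequencies) from parentage of
#' a random offspring. Three classical cases are available:
#' * `parent_pair` (default): a random candidate couple is incompatible as
#'   the parental pair of a random offspring;
#' * `one_parent_known`: a single random candidate is incompatible as the
#'   second parent, the true first parent being known;
#' * `no_known_parent`: a single random candidate shares no allele with the
#'   offspring.
#'
#' Each case is a closed-form polynomial in the power sums
#' `a_k = sum(p_i^k)`; the polynomials are cross-checked against the exact
#' enumeration oracle [exclusion_probability_bruteforce()], which is the
#' normative definition. The default `parent_pair` case is the one combined
#' across loci into the joint exclusion probability QC.
#'
#' @param freqs a `locus_frequencies` object or numeric frequency vector.
#' @param case exclusion scenario, see Details.
#' @return Probability in `[0, 1]`; 0 for a monomorphic locus.
#' @export
exclusion_probability <- function(freqs,
                                  case = c("parent_pair", "one_parent_known",
                                           "no_known_parent")) {
  case <- match.arg(case)
  p <- .as_p(freqs)
  a <- vapply(2:6, function(k) sum(p^k), numeric(1L))
  a2 <- a[1L]; a3 <- a[2L]; a4 <- a[3L]; a5 <- a[4L]; a6 <- a[5L]
  q <- switch(case,
    parent_pair =
      1 + 4 * a4 - 4 * a5 - 3 * a6 - 8 * a2^2 + 8 * a2 * a3 + 2 * a3^2,
    one_parent_known =
      1 - 2 * a2 + a3 + 2 * a4 - 3 * a5 - 2 * a2^2 + 3 * a2 * a3,
    no_known_parent =
      1 - 4 * a2 + 4 * a3 - 3 * a4 + 2 * a2^2)
  max(0, min(1, q))
}

#' Exclusion probability by exhaustive enumeration
#'
#' Independent oracle for [exclusion_probability()]: sums, over every
#' offspring genotype (Hardy-Weinberg) and every candidate configuration,
#' the probability that the candidate is genetically incompatible.
#' Incompatibility means: for `parent_pair`, no choice of one allele from
#' each candidate of the couple reproduces the offspring genotype; for
#' `one_parent_known`, no allele of the single candidate can be the allele
#' not contributed by the known (true) parent; for `no_known_parent`, the
#' candidate shares no allele with the offspring.
#'
#' @inheritParams exclusion_probability
#' @return Probability in `[0, 1]`.
#' @export
exclusion_probability_bruteforce <- function(freqs,
                                             case = c("parent_pair",
                                                      "one_parent_known",
                                                      "no_known_parent")) {
  case <- match.arg(case)
  p <- .as_p(freqs)
  m <- length(p)
  if (m > 8L) stop("enumeration oracle is limited to 8 alleles")
  gen <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  gp <- ifelse(gen[, 1L] == gen[, 2L],
               p[gen[, 1L]]^2, 2 * p[gen[, 1L]] * p[gen[, 2L]])
  ng <- nrow(gen)
  # can parents with alleles (c1, c2) produce offspring {o1, o2}?
  couple_compat <- function(c1a, c1b, c2a, c2b, o1, o2) {
    for (a in c(c1a, c1b)) for (b in c(c2a, c2b))
      if ((a == o1 && b == o2) || (a == o2 && b == o1)) return(TRUE)
    FALSE
  }
  total <- 0
  if (case == "parent_pair") {
    for (o in seq_len(ng)) {
      excl <- 0
      for (c1 in seq_len(ng)) for (c2 in seq_len(ng))
        if (!couple_compat(gen[c1, 1L], gen[c1, 2L],
                           gen[c2, 1L], gen[c2, 2L],
                           gen[o, 1L], gen[o, 2L]))
          excl <- excl + gp[c1] * gp[c2]
      total <- total + gp[o] * excl
    }
  } else if (case == "one_parent_known") {
    # true parent ~ HWE, offspring = one parental allele + one population
    # allele; candidate excluded iff it cannot be the other parent.
    for (mo in seq_len(ng)) {
      mal <- c(gen[mo, 1L], gen[mo, 2L])
      for (pick in 1:2) for (f in seq_len(m)) {
        o1 <- min(mal[pick], f); o2 <- max(mal[pick], f)
        w <- gp[mo] * 0.5 * p[f]
        excl <- 0
        for (cc in seq_len(ng))
          if (!couple_compat(mal[1L], mal[2L],
                             gen[cc, 1L], gen[cc, 2L], o1, o2))
            excl <- excl + gp[cc]
        total <- total + w * excl
      }
    }
  } else {
    for (o in seq_len(ng)) {
      oa <- gen[o, 1L]; ob <- gen[o, 2L]
      noshare <- gen[, 1L] != oa & gen[, 1L] != ob &
                 gen[, 2L] != oa & gen[, 2L] != ob
      total <- total + gp[o] * sum(gp[noshare])
    }
  }
  total
}

#' Probability of genetic identity at a locus
#'
#' The chance that two individuals drawn at random under Hardy-Weinberg
#' carry identical genotypes:
#' `I = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`, equivalently the sum of
#' squared Hardy-Weinberg genotype probabilities (`2 a_2^2 - a_4` in power
#' sums).
#'
#' @inheritParams exclusion_probability
#' @return Probability in `[0, 1]`; 1 for a monomorphic locus.
#' @export
identity_probability <- function(freqs) {
  p <- .as_p(freqs)
  2 * sum(p^2)^2 - sum(p^4)
}

#' Combine per-locus exclusion or identity probabilities across a panel
#'
#' Assuming independent loci, the joint exclusion probability is
#' `QC = 1 - prod(1 - Q_l)` (a single excluding locus suffices) and the
#' joint identity probability is `IC = prod(I_l)` (identity must hold at
#' every locus). Adding a locus never decreases QC and never increases IC.
#'
#' @param per_locus_q,per_locus_i numeric vectors of per-locus
#'   probabilities in `[0, 1]`.
#' @return The joint probability.
#' @export
combine_exclusion <- function(per_locus_q) {
  if (any(per_locus_q < 0 | per_locus_q > 1))
    stop("per-locus Q values must lie in [0, 1]")
  1 - prod(1 - per_locus_q)
}

#' @rdname combine_exclusion
#' @export
combine_identity <- function(per_locus_i) {
  if (any(per_locus_i < 0 | per_locus_i > 1))
    stop("per-locus I values must lie in [0, 1]")
  prod(per_locus_i)
}

#' Minimal locus subset achieving a joint power criterion
#'
#' Greedy selection: loci are added in decreasing order of exclusion power Q
#' (criterion `"qc"`) or increasing order of identity probability I
#' (criterion `"ic"`) until the joint value meets the threshold. Ties are
#' broken by input order. An exhaustive mode searches all subsets (panels of
#' at most 15 loci) for the smallest subset meeting the criterion, breaking
#' size ties by the best joint value.
#'
#' @param per_locus named numeric vector: per-locus Q (for `criterion =
#'   "qc"`) or I (for `"ic"`).
#' @param criterion `"qc"` (require `QC >= threshold`) or `"ic"` (require
#'   `IC <= threshold`).
#' @param threshold the joint-power target.
#' @param exhaustive search all subsets instead of greedy.
#' @return List with `loci` (selected names in selection order) and
#'   `achieved` (the joint value of the subset).
#' @export
minimal_panel <- function(per_locus, criterion = c("qc", "ic"), threshold,
                          exhaustive = FALSE) {
  criterion <- match.arg(criterion)
  if (is.null(names(per_locus)))
    names(per_locus) <- paste0("L", seq_along(per_locus))
  joint <- if (criterion == "qc") combine_exclusion else combine_identity
  met <- function(v) if (criterion == "qc") v >= threshold else v <= threshold
  best_all <- joint(per_locus)
  if (!met(best_all))
    stop("criterion unattainable with all loci; best achievable joint ",
         toupper(criterion), " = ", signif(best_all, 6))
  if (exhaustive) {
    if (length(per_locus) > 15L)
      stop("exhaustive search is limited to 15 loci")
    best <- NULL
    for (size in seq_along(per_locus)) {
      subsets <- utils::combn(seq_along(per_locus), size, simplify = FALSE)
      vals <- vapply(subsets, function(s) joint(per_locus[s]), numeric(1L))
      ok <- vapply(vals, met, logical(1L))
      if (any(ok)) {
        pick <- which(ok)
        better <- if (criterion == "qc") which.max(vals[pick])
                  else which.min(vals[pick])
        s <- subsets[[pick[better]]]
        best <- list(loci = names(per_locus)[s], achieved = vals[pick][better])
        break
      }
    }
    return(best)
  }
  ord <- if (criterion == "qc") order(-per_locus) else order(per_locus)
  sel <- integer(0)
  for (i in ord) {
    sel <- c(sel, i)
    v <- joint(per_locus[sel])
    if (met(v))
      return(list(loci = names(per_locus)[sel], achieved = v))
  }
  stop("internal error: greedy selection failed despite attainable criterion")
}
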