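#' Observed heterozygosity at a locus
#'
#' Proportion of heterozygous genotypes among the non-missing genotypes.
#'
#' @param x a [genotype_table()].
#' @param locus locus name.
#' @return Proportion in `[0, 1]`.
#' @export
observed_heterozygosity <- function(x, locus) {
  stopifnot(inherits(x, "genotype_table"))
  if (!locus %in% x$loci) stop("locus '", locus, "' not in table")
  v1 <- x$a1[, locus]; v2 <- x$a2[, locus]
  keep <- !is.na(v1)
  if (!any(keep)) stop("locus '", locus, "' has no genotyped individuals")
  mean(v1[keep] != v2[keep])
}

#' Unbiased expected heterozygosity (Nei's gene diversity)
#'
#' Small-sample-corrected gene diversity
#' `(2n / (2n - 1)) * (1 - sum(p_i^2))` with `2n` the number of sampled
#' allele copies. Converges to `1 - sum(p_i^2)` as n grows; the correction
#' factor exceeds 1 for any finite sample.
#'
#' @param freqs a `locus_frequencies` object (needs `n_genotyped >= 2`).
#' @return Proportion in `[0, 1]`; 0 for a monomorphic locus.
#' @export
expected_heterozygosity_unbiased <- function(freqs) {
  stopifnot(inherits(freqs, "locus_frequencies"))
  n <- freqs$n_genotyped
  if (is.na(n) || n < 2L)
    stop("unbiased expected heterozygosity needs at least 2 genotyped ",
         "individuals")
  two_n <- 2 * n
  two_n / (two_n - 1) * (1 - sum(freqs$freqs^2))
}

# Observed genotype configuration at a locus: list(counts = k x k upper
# matrix of genotype counts indexed by allele rank, allele_counts).
.locus_config <- function(x, locus) {
  v1 <- x$a1[, locus]; v2 <- x$a2[, locus]
  keep <- !is.na(v1)
  alleles <- sort(unique(c(v1[keep], v2[keep])))
  k <- length(alleles)
  i <- match(v1[keep], alleles)
  j <- match(v2[keep], alleles)
  counts <- matrix(0L, k, k)
  for (g in seq_along(i)) counts[i[g], j[g]] <- counts[i[g], j[g]] + 1L
  ac <- integer(k)
  for (a in seq_len(k))
    ac[a] <- 2L * counts[a, a] + sum(counts[a, -a]) + sum(counts[-a, a])
  list(counts = counts, allele_counts = ac, n = sum(keep))
}

# Conditional log-weight of a genotype configuration given allele counts
# (constant factors shared by all configurations are dropped):
# log w = h * log 2 - sum(lfactorial(genotype counts)), h = heterozygotes.
.config_logw <- function(counts) {
  h <- sum(counts) - sum(diag(counts))
  h * log(2) - sum(lfactorial(counts))
}

# Enumerate all genotype configurations consistent with the allele counts;
# returns the vector of log-weights, or NULL when more than `cap` leaves.
.hwe_enumerate <- function(allele_counts, cap = 1e6) {
  k <- length(allele_counts)
  buf <- double(1024L); nb <- 0L; overflow <- FALSE
  push <- function(v) {
    if (nb == length(buf)) buf <<- c(buf, double(length(buf)))
    nb <<- nb + 1L
    buf[nb] <<- v
    if (nb >= cap) overflow <<- TRUE
  }
  rec <- function(i, r, h, slf) {
    if (overflow) return(invisible())
    if (i == k) {
      if (r[k] %% 2L == 0L)
        push(h * log(2) - (slf + lfactorial(r[k] %/% 2L)))
      return(invisible())
    }
    for (nii in 0:(r[i] %/% 2L))
      distribute(i, i + 1L, r[i] - 2L * nii, r, h, slf + lfactorial(nii))
    invisible()
  }
  distribute <- function(i, j, rem, r, h, slf) {
    if (overflow) return(invisible())
    if (j == k) {
      if (rem <= r[k]) {
        r[k] <- r[k] - rem
        rec(i + 1L, r, h + rem, slf + lfactorial(rem))
      }
      return(invisible())
    }
    for (nij in 0:min(rem, r[j])) {
      r2 <- r
      r2[j] <- r2[j] - nij
      distribute(i, j + 1L, rem - nij, r2, h + nij, slf + lfactorial(nij))
    }
    invisible()
  }
  if (k == 1L) return(.config_logw(matrix(allele_counts %/% 2L, 1L, 1L)))
  rec(1L, allele_counts, 0L, 0)
  if (overflow) NULL else buf[seq_len(nb)]
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test given the observed allele counts. The p-value is
#' the total conditional probability of all genotype configurations at most
#' as probable as the observed one (probability ordering). With
#' `method = "auto"` the full configuration set is enumerated when it has at
#' most `max_configs` members, otherwise a Monte-Carlo version repeatedly
#' re-pairs the pooled allele vector at random and estimates
#' `p = (b + 1) / (mc_reps + 1)` with the add-one estimator.
#'
#' @param x a [genotype_table()].
#' @param locus locus name.
#' @param method `"auto"`, `"enumeration"` or `"mc"`.
#' @param mc_reps Monte-Carlo replicates.
#' @param seed optional integer seed for the Monte-Carlo path.
#' @param max_configs enumeration size bound for `method = "auto"`.
#' @return List with `p_value`, `method` actually used (`"enumeration"`,
#'   `"mc"` or `"degenerate"`), and `degenerate` (`TRUE` for a monomorphic
#'   locus, where the test is vacuous and `p_value` is 1).
#' @export
hwe_exact_test <- function(x, locus, method = c("auto", "enumeration", "mc"),
                           mc_reps = 100000, seed = NULL,
                           max_configs = 1e6) {
  method <- match.arg(method)
  stopifnot(inherits(x, "genotype_table"))
  cfg <- .locus_config(x, locus)
  if (cfg$n < 2L)
    stop("locus '", locus, "' needs at least 2 genotyped individuals")
  if (length(cfg$allele_counts) < 2L)
    return(list(p_value = 1, method = "degenerate", degenerate = TRUE))
  logw_obs <- .config_logw(cfg$counts)
  tol <- 1e-9
  if (method %in% c("auto", "enumeration")) {
    logw <- .hwe_enumerate(cfg$allele_counts, cap = max_configs)
    if (is.null(logw) && method == "enumeration")
      stop("more than ", max_configs,
           " configurations; use method = 'mc' or raise max_configs")
    if (!is.null(logw)) {
      w <- exp(logw - max(logw))
      p <- sum(w[logw <= logw_obs + tol]) / sum(w)
      return(list(p_value = p, method = "enumeration", degenerate = FALSE))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(cfg$allele_counts)
  pool <- rep.int(seq_len(k), cfg$allele_counts)
  n <- cfg$n
  odd <- seq(1L, 2L * n, by = 2L)
  b <- 0L
  for (r in seq_len(mc_reps)) {
    perm <- sample(pool)
    i <- perm[odd]; j <- perm[odd + 1L]
    lo <- pmin(i, j); hi <- pmax(i, j)
    cnt <- tabulate(lo + k * (hi - 1L), nbins = k * k)
    h <- n - sum(cnt[seq(1L, k * k, by = k + 1L)])
    logw <- h * log(2) - sum(lfactorial(cnt[cnt > 1L]))
    if (logw <= logw_obs + tol) b <- b + 1L
  }
  list(p_value = (b + 1) / (mc_reps + 1), method = "mc", degenerate = FALSE)
}

#' Permutation test of genotypic linkage disequilibrium
#'
#' Log-likelihood-ratio statistic G of the two-locus genotype contingency
#' table, with the null distribution obtained by permuting one locus's
#' single-locus genotypes among individuals. The p-value uses the add-one
#' estimator `(b + 1) / (permutations + 1)`, so its minimum attainable value
#' is `1 / (permutations + 1)`.
#'
#' @param x a [genotype_table()].
#' @param locus_a,locus_b locus names; both need at least 2 alleles and at
#'   least 5 individuals genotyped at both.
#' @param permutations number of permutations.
#' @param seed optional integer seed.
#' @return p-value.
#' @export
ld_test <- function(x, locus_a, locus_b, permutations = 10000, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  for (l in c(locus_a, locus_b))
    if (!l %in% x$loci) stop("locus '", l, "' not in table")
  joint <- !is.na(x$a1[, locus_a]) & !is.na(x$a1[, locus_b])
  if (sum(joint) < 5L)
    stop("fewer than 5 individuals genotyped at both loci")
  ga <- paste(x$a1[joint, locus_a], x$a2[joint, locus_a])
  gb <- paste(x$a1[joint, locus_b], x$a2[joint, locus_b])
  n_alleles <- function(l)
    length(unique(c(x$a1[joint, l], x$a2[joint, l])))
  if (n_alleles(locus_a) < 2L || n_alleles(locus_b) < 2L)
    stop("both loci must be polymorphic among jointly genotyped individuals")
  ia <- as.integer(factor(ga)); ib <- as.integer(factor(gb))
  na <- max(ia); nb <- max(ib)
  gstat <- function(ib) {
    o <- tabulate(ia + na * (ib - 1L), nbins = na * nb)
    rs <- tabulate(ia, na); cs <- tabulate(ib, nb)
    e <- as.vector(outer(rs, cs)) / length(ia)
    keep <- o > 0L
    2 * sum(o[keep] * log(o[keep] / e[keep]))
  }
  g_obs <- gstat(ib)
  if (!is.null(seed)) set.seed(seed)
  b <- 0L
  for (r in seq_len(permutations))
    if (gstat(sample(ib)) >= g_obs - 1e-12) b <- b + 1L
  (b + 1) / (permutations + 1)
}

#' Bonferroni adjustment of p-values
#'
#' `adjusted_i = min(1, p_i * m)` with `m = length(pvalues)`; the
#' significance threshold therefore tightens with the total number of tests
#' performed.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "bonferroni")
}

#' Per-locus diversity summary
#'
#' Number of genotyped individuals, number of alleles, observed and unbiased
#' expected heterozygosity, and exact Hardy-Weinberg p-value for every locus,
#' plus panel means (arithmetic means of the per-locus values).
#'
#' @param x a [genotype_table()].
#' @param hwe_method,mc_reps,seed passed to [hwe_exact_test()]; when `seed`
#'   is given, locus `l` uses `seed + l`.
#' @return List of class `diversity_summary` with `per_locus` (data frame)
#'   and `panel_means` (named vector with `n_alleles`, `ho`, `he`).
#' @export
diversity_summary <- function(x, hwe_method = "auto", mc_reps = 100000,
                              seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  rows <- lapply(seq_along(x$loci), function(l) {
    locus <- x$loci[l]
    fr <- allele_frequencies(x, locus)
    hwe <- hwe_exact_test(x, locus, method = hwe_method, mc_reps = mc_reps,
                          seed = if (is.null(seed)) NULL else seed + l)
    data.frame(locus = locus,
               n = fr$n_genotyped,
               n_alleles = length(fr$alleles),
               ho = observed_heterozygosity(x, locus),
               he = expected_heterozygosity_unbiased(fr),
               p_hwe = hwe$p_value,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  structure(list(per_locus = per_locus,
                 panel_means = c(n_alleles = mean(per_locus$n_alleles),
                                 ho = mean(per_locus$ho),
                                 he = mean(per_locus$he))),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  df <- x$per_locus
  df$ho <- round(df$ho, 4); df$he <- round(df$he, 4)
  df$p_hwe <- round(df$p_hwe, 4)
  print(df, row.names = FALSE)
  cat(sprintf("panel means: N_A = %.1f, Ho = %.4f, He = %.4f\n",
              x$panel_means["n_alleles"], x$panel_means["ho"],
              x$panel_means["he"]))
  invisible(x)
}
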