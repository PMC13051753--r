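#' Canonical relationship hypotheses in IBD-coefficient space
#'
#' Each relationship is a point `(k0, k1, k2)`: the probabilities that a
#' non-inbred pair shares 0, 1 or 2 alleles identical by descent at a locus.
#' The canonical hypotheses are unrelated `U = (1, 0, 0)`, half-siblings
#' `HS = (0.5, 0.5, 0)`, full-siblings `FS = (0.25, 0.5, 0.25)` and
#' parent-offspring `PO = (0, 1, 0)`; the implied relatedness coefficient is
#' `r = k2 + k1 / 2`. The row order (least related first) is also the
#' tie-breaking preference used throughout.
#'
#' @return Data frame with columns `label`, `k0`, `k1`, `k2`.
#' @export
relationship_hypotheses <- function() {
  data.frame(label = c("U", "HS", "FS", "PO"),
             k0 = c(1, 0.5, 0.25, 0),
             k1 = c(0, 0.5, 0.5, 1),
             k2 = c(0, 0, 0.25, 0),
             stringsAsFactors = FALSE)
}

# ---- internal genotype/frequency plumbing -------------------------------

# Named list of plain frequency vectors + allele label lookup.
.freq_env <- function(freqs_per_locus) {
  stopifnot(is.list(freqs_per_locus), length(freqs_per_locus) > 0)
  loci <- names(freqs_per_locus)
  if (is.null(loci)) stop("freqs_per_locus must be a named list")
  plist <- lapply(freqs_per_locus, .as_p)
  alleles <- lapply(freqs_per_locus, function(f) {
    if (inherits(f, "locus_frequencies")) f$alleles
    else if (!is.null(names(f))) as.integer(names(f))
    else seq_along(f)
  })
  list(loci = loci, plist = plist, alleles = alleles)
}

# Coerce a 2 x L matrix of allele labels to per-locus index pairs (NA kept).
.genotype_indices <- function(g, fe) {
  g <- as.matrix(g)
  if (nrow(g) != 2L) stop("a genotype must be a 2 x L matrix of alleles")
  L <- length(fe$loci)
  if (ncol(g) != L) stop("genotype has ", ncol(g), " loci, frequencies ", L)
  i1 <- integer(L); i2 <- integer(L)
  for (l in seq_len(L)) {
    if (is.na(g[1L, l]) || is.na(g[2L, l])) {
      i1[l] <- NA_integer_; i2[l] <- NA_integer_
    } else {
      m <- match(g[, l], fe$alleles[[l]])
      if (anyNA(m))
        stop("allele ", g[which(is.na(m))[1L], l], " at locus '",
             fe$loci[l], "' absent from the supplied frequencies")
      i1[l] <- min(m); i2[l] <- max(m)
    }
  }
  list(i1 = i1, i2 = i2)
}

# Per-locus joint genotype-pair probabilities under 0/1/2 shared IBD
# alleles, vectorised over pairs. Inputs are index vectors with a1 <= a2,
# b1 <= b2; p is the locus frequency vector.
.locus_sterms <- function(a1, a2, b1, b2, p) {
  pa1 <- p[a1]; pa2 <- p[a2]; pb1 <- p[b1]; pb2 <- p[b2]
  P1 <- ifelse(a1 == a2, pa1 * pa1, 2 * pa1 * pa2)
  P2 <- ifelse(b1 == b2, pb1 * pb1, 2 * pb1 * pb2)
  hom2 <- b1 == b2
  trans <- function(t)
    ifelse(hom2, ifelse(t == b1, pb1, 0),
           (t == b1) * pb2 + (t == b2) * pb1)
  list(S0 = P1 * P2,
       S1 = P1 * 0.5 * (trans(a1) + trans(a2)),
       S2 = ifelse(a1 == b1 & a2 == b2, P1, 0))
}

# 3 x L matrix of S-terms for one observed pair (joint loci only).
.pair_sterms <- function(g1, g2, freqs_per_locus) {
  fe <- .freq_env(freqs_per_locus)
  x1 <- .genotype_indices(g1, fe)
  x2 <- .genotype_indices(g2, fe)
  joint <- which(!is.na(x1$i1) & !is.na(x2$i1))
  if (length(joint) == 0L) stop("no jointly genotyped loci for this pair")
  S <- matrix(0, 3L, length(joint))
  for (idx in seq_along(joint)) {
    l <- joint[idx]
    st <- .locus_sterms(x1$i1[l], x1$i2[l], x2$i1[l], x2$i2[l],
                        fe$plist[[l]])
    S[, idx] <- c(st$S0, st$S1, st$S2)
  }
  S
}

.as_k <- function(k) {
  if (is.character(k)) {
    hyp <- relationship_hypotheses()
    row <- match(k, hyp$label)
    if (is.na(row)) stop("unknown relationship label '", k, "'")
    k <- c(hyp$k0[row], hyp$k1[row], hyp$k2[row])
  }
  k <- as.numeric(k)
  if (length(k) != 3L || any(k < -1e-12) || abs(sum(k) - 1) > 1e-12)
    stop("k must be three non-negative IBD probabilities summing to 1")
  pmax(k, 0)
}

# ---- likelihood and ML estimation ---------------------------------------

#' Pairwise relatedness log-likelihood at given IBD coefficients
#'
#' Per locus, the joint probability of an unordered genotype pair is the
#' mixture `k0 * S0 + k1 * S1 + k2 * S2`, where `S_m` is the pair
#' probability given `m` shared IBD alleles under Hardy-Weinberg
#' frequencies; log-probabilities are summed over the jointly genotyped
#' loci (loci missing in either member are skipped). A configuration
#' impossible under `k` (e.g. no shared allele with `k1 = 1`) yields
#' `-Inf`.
#'
#' @param g1,g2 genotypes as 2 x L matrices of allele labels (rows = the
#'   two alleles, columns in the order of `freqs_per_locus`); `NA` marks a
#'   missing locus.
#' @param freqs_per_locus named list of `locus_frequencies` (or named
#'   frequency vectors), one entry per locus.
#' @param k IBD coefficients `c(k0, k1, k2)` or a canonical label
#'   (`"U"`, `"HS"`, `"FS"`, `"PO"`).
#' @return Log-likelihood (possibly `-Inf`).
#' @export
pair_likelihood <- function(g1, g2, freqs_per_locus, k) {
  k <- .as_k(k)
  S <- .pair_sterms(g1, g2, freqs_per_locus)
  mix <- as.numeric(k %*% S)
  if (any(mix == 0)) return(-Inf)
  sum(log(mix))
}

# Simplex grid ordered by (r, k2) ascending so that ties prefer the least
# related point; cached after first construction.
.msatkin_cache <- new.env(parent = emptyenv())

.kgrid <- function(step = 0.01) {
  key <- paste0("kgrid_", step)
  if (!is.null(.msatkin_cache[[key]])) return(.msatkin_cache[[key]])
  m <- round(1 / step)
  ij <- expand.grid(i = 0:m, j = 0:m)
  ij <- ij[ij$i + ij$j <= m, ]
  K <- cbind(k0 = ij$i / m, k1 = ij$j / m, k2 = 1 - (ij$i + ij$j) / m)
  r <- K[, 3L] + K[, 2L] / 2
  K <- K[order(r, K[, 3L], K[, 2L]), , drop = FALSE]
  .msatkin_cache[[key]] <- K
  K
}

.grid_best <- function(K, S) {
  lnl <- rowSums(log(K %*% S))
  best <- which.max(lnl)
  list(k = K[best, ], lnl = lnl[best])
}

#' Maximum-likelihood IBD coefficients and relatedness for a pair
#'
#' Maximises the pairwise log-likelihood over the IBD simplex
#' `{k >= 0, sum(k) = 1}` by a coarse 0.01-step grid followed by a local
#' 0.001-step refinement; boundary solutions (e.g. exactly parent-offspring)
#' are reported exactly. The relatedness coefficient is
#' `r = k2 + k1 / 2`. With a flat likelihood (all informative loci
#' monomorphic for the pair) ties resolve towards the least related point,
#' `k = (1, 0, 0)`.
#'
#' @inheritParams pair_likelihood
#' @return List with `k` (length-3 named vector), `r` and `lnl`.
#' @export
ml_relatedness <- function(g1, g2, freqs_per_locus) {
  S <- .pair_sterms(g1, g2, freqs_per_locus)
  coarse <- .grid_best(.kgrid(0.01), S)
  k <- coarse$k
  off <- seq(-0.012, 0.012, by = 0.001)
  fine <- expand.grid(k0 = k[1L] + off, k1 = k[2L] + off)
  fine$k2 <- 1 - fine$k0 - fine$k1
  ok <- fine$k0 >= 0 & fine$k1 >= 0 & fine$k2 >= -1e-12
  K2 <- as.matrix(fine[ok, c("k0", "k1", "k2")])
  K2[, 3L] <- pmax(K2[, 3L], 0)
  r2 <- K2[, 3L] + K2[, 2L] / 2
  K2 <- K2[order(r2, K2[, 3L], K2[, 2L]), , drop = FALSE]
  refined <- .grid_best(K2, S)
  best <- if (refined$lnl > coarse$lnl) refined else coarse
  k <- stats::setNames(as.numeric(best$k), c("k0", "k1", "k2"))
  list(k = k, r = unname(k[3L] + k[2L] / 2), lnl = best$lnl)
}

#' Most likely canonical relationship for a pair
#'
#' Argmax of [pair_likelihood()] over the canonical hypotheses; ties are
#' broken towards the least related hypothesis (U before HS before FS
#' before PO).
#'
#' @inheritParams pair_likelihood
#' @param candidates hypothesis table as from [relationship_hypotheses()].
#' @return The winning label, with the per-hypothesis log-likelihoods
#'   attached as attribute `"lnl"`.
#' @export
ml_relationship <- function(g1, g2, freqs_per_locus,
                            candidates = relationship_hypotheses()) {
  S <- .pair_sterms(g1, g2, freqs_per_locus)
  lnl <- .hyp_lnl(S, candidates)
  structure(candidates$label[which.max(lnl)],
            lnl = stats::setNames(lnl, candidates$label))
}

.hyp_lnl <- function(S, candidates) {
  vapply(seq_len(nrow(candidates)), function(h) {
    mix <- as.numeric(c(candidates$k0[h], candidates$k1[h],
                        candidates$k2[h]) %*% S)
    if (any(mix == 0)) -Inf else sum(log(mix))
  }, numeric(1L))
}

# ---- simulation engine shared with the simdata module -------------------

# Batch-simulate n genotype pairs under IBD coefficients k at the loci in
# plist (list of frequency vectors). Allele indices, a1 <= a2. This single
# engine backs simulate_pair(), confidence sets and LRTs.
.sim_pairs_batch <- function(plist, k, n) {
  lapply(plist, function(p) {
    m <- sample.int(3L, n, replace = TRUE, prob = k) - 1L
    a1 <- sample.int(length(p), n, replace = TRUE, prob = p)
    a2 <- sample.int(length(p), n, replace = TRUE, prob = p)
    b1 <- sample.int(length(p), n, replace = TRUE, prob = p)
    b2 <- sample.int(length(p), n, replace = TRUE, prob = p)
    pick <- stats::runif(n) < 0.5
    tr <- ifelse(pick, a1, a2)
    one <- m == 1L
    b1[one] <- tr[one]
    two <- m == 2L
    b1[two] <- a1[two]
    b2[two] <- a2[two]
    list(a1 = pmin(a1, a2), a2 = pmax(a1, a2),
         b1 = pmin(b1, b2), b2 = pmax(b1, b2))
  })
}

# n x nrow(candidates) log-likelihood matrix for a simulated batch.
.batch_lnl <- function(batch, plist, candidates) {
  n <- length(batch[[1L]]$a1)
  lnl <- matrix(0, n, nrow(candidates))
  for (l in seq_along(plist)) {
    st <- .locus_sterms(batch[[l]]$a1, batch[[l]]$a2,
                        batch[[l]]$b1, batch[[l]]$b2, plist[[l]])
    for (h in seq_len(nrow(candidates)))
      lnl[, h] <- lnl[, h] + log(candidates$k0[h] * st$S0 +
                                 candidates$k1[h] * st$S1 +
                                 candidates$k2[h] * st$S2)
  }
  lnl
}

.row_max <- function(m) Reduce(pmax, asplit(m, 2L))

# Null distribution of lambda = lnL(ML hypothesis) - lnL(R) for pairs
# simulated under hypothesis R at the given loci.
.null_lambda_ml <- function(plist, R, candidates, n_sim) {
  batch <- .sim_pairs_batch(plist, .as_k(R), n_sim)
  lnl <- .batch_lnl(batch, plist, candidates)
  .row_max(lnl) - lnl[, match(R, candidates$label)]
}

# ---- confidence sets, classification, LRTs ------------------------------

#' Simulation-based confidence set of relationships
#'
#' For each candidate hypothesis R the observed statistic is
#' `lambda_obs = lnL(best hypothesis) - lnL(R)`. `n_sim` pairs are
#' simulated under R at the observed loci (the pair's missing-data pattern
#' is preserved: only jointly genotyped loci are simulated) and
#' `lambda_sim` is computed the same way for each. R stays in the set when
#' `p_R = (#\{lambda_sim >= lambda_obs\} + 1) / (n_sim + 1) > alpha`. The
#' best hypothesis always belongs to the set (`lambda_obs = 0` there).
#'
#' @inheritParams ml_relationship
#' @param n_sim simulated pairs per candidate.
#' @param alpha significance level of the set (default 0.05 for a 95% set).
#' @param seed optional integer seed.
#' @return Character vector of retained labels, with per-candidate
#'   p-values attached as attribute `"p_values"`.
#' @export
confidence_set <- function(g1, g2, freqs_per_locus, n_sim = 100000,
                           alpha = 0.05, seed = NULL,
                           candidates = relationship_hypotheses()) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  fe <- .freq_env(freqs_per_locus)
  S <- .pair_sterms(g1, g2, freqs_per_locus)
  lnl <- .hyp_lnl(S, candidates)
  x1 <- .genotype_indices(g1, fe); x2 <- .genotype_indices(g2, fe)
  joint <- which(!is.na(x1$i1) & !is.na(x2$i1))
  plist <- fe$plist[joint]
  lnl_best <- max(lnl)
  pvals <- vapply(seq_len(nrow(candidates)), function(h) {
    lam_obs <- lnl_best - lnl[h]
    lam_sim <- .null_lambda_ml(plist, candidates$label[h], candidates, n_sim)
    (sum(lam_sim >= lam_obs - 1e-12) + 1) / (n_sim + 1)
  }, numeric(1L))
  structure(candidates$label[pvals > alpha],
            p_values = stats::setNames(pvals, candidates$label))
}

#' Conservative related / unrelated / ambiguous classification
#'
#' A pair is `related` only when the confidence set excludes the unrelated
#' category, `unrelated` only when the set contains no related category
#' (i.e. equals `{U}`), and `ambiguous` otherwise.
#'
#' @param conf_set character vector of relationship labels, as returned by
#'   [confidence_set()].
#' @return `"related"`, `"unrelated"` or `"ambiguous"`.
#' @export
classify_pair <- function(conf_set) {
  conf_set <- as.character(conf_set)
  if (length(conf_set) == 0L)
    stop("internal error: empty confidence set")
  if (!"U" %in% conf_set) return("related")
  if (all(conf_set == "U")) return("unrelated")
  "ambiguous"
}

#' Simulation likelihood-ratio test between two relationships
#'
#' Tests the null relationship against a specific alternative. The observed
#' statistic is `lambda = lnL(alt) - lnL(null)`; `n_sim` pairs are
#' simulated under the null at the observed loci and the p-value is the
#' add-one tail proportion `(#\{lambda_sim >= lambda_obs\} + 1) /
#' (n_sim + 1)`. A small p-value rejects the null in favour of the
#' alternative. A pair impossible under the null (null likelihood zero)
#' yields the minimum attainable p-value.
#'
#' @inheritParams confidence_set
#' @param null_r,alt_r distinct relationship labels.
#' @return p-value.
#' @export
lrt_specific <- function(g1, g2, freqs_per_locus, null_r, alt_r,
                         n_sim = 100000, seed = NULL,
                         candidates = relationship_hypotheses()) {
  if (identical(null_r, alt_r))
    stop("null and alternative relationship must differ")
  if (!is.null(seed)) set.seed(seed)
  fe <- .freq_env(freqs_per_locus)
  S <- .pair_sterms(g1, g2, freqs_per_locus)
  lnl <- .hyp_lnl(S, candidates)
  i_null <- match(null_r, candidates$label)
  i_alt <- match(alt_r, candidates$label)
  if (is.na(i_null) || is.na(i_alt)) stop("unknown relationship label")
  lam_obs <- if (is.infinite(lnl[i_null])) Inf else lnl[i_alt] - lnl[i_null]
  x1 <- .genotype_indices(g1, fe); x2 <- .genotype_indices(g2, fe)
  joint <- which(!is.na(x1$i1) & !is.na(x2$i1))
  plist <- fe$plist[joint]
  batch <- .sim_pairs_batch(plist, .as_k(null_r), n_sim)
  lnl_sim <- .batch_lnl(batch, plist, candidates)
  lam_sim <- lnl_sim[, i_alt] - lnl_sim[, i_null]
  (sum(lam_sim >= lam_obs - 1e-12) + 1) / (n_sim + 1)
}

# ---- whole-table analysis ----------------------------------------------

# Extract a pair's genotypes from a table as 2 x L label matrices.
#' Genotypes of one pair of individuals
#'
#' @param x a [genotype_table()].
#' @param i,j individual ids or indices.
#' @return List with `g1` and `g2`, 2 x L matrices of allele labels.
#' @export
pair_genotypes <- function(x, i, j) {
  stopifnot(inherits(x, "genotype_table"))
  idx <- function(v) if (is.character(v)) match(v, x$ids) else v
  i <- idx(i); j <- idx(j)
  if (anyNA(c(i, j))) stop("unknown individual id")
  g <- function(i) {
    m <- rbind(x$a1[i, ], x$a2[i, ])
    colnames(m) <- x$loci
    m
  }
  list(g1 = g(i), g2 = g(j))
}

#' Pairwise relatedness analysis of a genotype table
#'
#' Runs the full maximum-likelihood kinship pipeline over every unordered
#' pair of individuals (`n * (n - 1) / 2` rows): per-hypothesis
#' log-likelihoods, ML IBD coefficients and relatedness `r`, the most
#' likely relationship, the simulation confidence set, and the conservative
#' related/unrelated/ambiguous classification. Allele frequencies are
#' estimated once from the complete table (including each focal pair).
#' Null simulations are shared between pairs with the same
#' jointly-genotyped-locus pattern, so complete tables need only one batch
#' of `n_sim` simulations per hypothesis.
#'
#' @param x a [genotype_table()] (typically after [filter_missing()]).
#' @param n_sim simulated pairs per hypothesis for the confidence sets.
#' @param alpha significance level of the confidence sets.
#' @param seed optional integer seed; results are deterministic given it.
#' @param candidates hypothesis table as from [relationship_hypotheses()].
#' @return Data frame of class `pairwise_kinship` with one row per pair
#'   (`id1`, `id2`, `r`, per-hypothesis `lnl_*`, `ml_relationship`,
#'   `confidence_set` as a comma-joined string, `classification`). The
#'   symmetric relatedness matrix (unit diagonal) is attached as attribute
#'   `"r_matrix"`.
#' @export
pairwise_analysis <- function(x, n_sim = 100000, alpha = 0.05, seed = NULL,
                              candidates = relationship_hypotheses()) {
  stopifnot(inherits(x, "genotype_table"))
  n <- length(x$ids)
  if (n < 2L) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  freqs <- loci_frequencies(x)
  fe <- .freq_env(freqs)
  null_cache <- new.env(parent = emptyenv())
  pairs <- utils::combn(n, 2L)
  r_mat <- diag(1, n)
  dimnames(r_mat) <- list(x$ids, x$ids)
  rows <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    pg <- pair_genotypes(x, i, j)
    S <- .pair_sterms(pg$g1, pg$g2, freqs)
    lnl <- .hyp_lnl(S, candidates)
    mlr <- candidates$label[which.max(lnl)]
    est <- ml_relatedness(pg$g1, pg$g2, freqs)
    joint <- which(!is.na(pg$g1[1L, ]) & !is.na(pg$g2[1L, ]))
    pvals <- vapply(seq_len(nrow(candidates)), function(h) {
      key <- paste(candidates$label[h], paste(joint, collapse = "."),
                   sep = "|")
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- .null_lambda_ml(fe$plist[joint],
                                             candidates$label[h],
                                             candidates, n_sim)
      lam_obs <- max(lnl) - lnl[h]
      (sum(null_cache[[key]] >= lam_obs - 1e-12) + 1) / (n_sim + 1)
    }, numeric(1L))
    conf <- candidates$label[pvals > alpha]
    r_mat[i, j] <- r_mat[j, i] <- est$r
    lnl_cols <- as.list(stats::setNames(lnl,
                                        paste0("lnl_", candidates$label)))
    rows[[q]] <- data.frame(id1 = x$ids[i], id2 = x$ids[j], r = est$r,
                            lnl_cols,
                            ml_relationship = mlr,
                            confidence_set = paste(conf, collapse = ","),
                            classification = classify_pair(conf),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "r_matrix") <- r_mat
  class(out) <- c("pairwise_kinship", class(out))
  out
}

#' Likelihood-ratio disambiguation of ambiguous pairs
#'
#' For every pair classified `ambiguous`, tests the pair's most likely
#' relationship against each alternative in its confidence set with
#' [lrt_specific()] (null = the alternative). P-values are
#' Bonferroni-adjusted with `m` equal to the total number of tests across
#' all ambiguous pairs in the run; an alternative is eliminated when its
#' adjusted p-value falls below `alpha`. A pair becomes `related` when the
#' unrelated category is eliminated and at least one related category
#' survives, `unrelated` when every related category is eliminated, and
#' stays `ambiguous` otherwise.
#'
#' @param result a `pairwise_kinship` data frame from [pairwise_analysis()].
#' @param x the [genotype_table()] the result was computed from.
#' @param n_sim simulations per likelihood-ratio test.
#' @param alpha significance level applied to adjusted p-values.
#' @param seed optional integer seed.
#' @param m_mode `"global"` (default): Bonferroni `m` is the total number of
#'   tests across all ambiguous pairs in the run; `"per_pair"`: `m` counts
#'   only each pair's own tests. The global correction is very strict: with
#'   simulation p-values bounded below by `1 / (n_sim + 1)` and borderline
#'   pairs (the ones that are ambiguous in the first place), few
#'   eliminations survive it.
#' @param candidates hypothesis table as from [relationship_hypotheses()].
#' @return The input data frame with a `final_classification` column; the
#'   per-test table (pair, null, alternative, raw and adjusted p) is
#'   attached as attribute `"lrt_tests"`.
#' @export
resolve_ambiguous <- function(result, x, n_sim = 100000, alpha = 0.05,
                              seed = NULL, m_mode = c("global", "per_pair"),
                              candidates = relationship_hypotheses()) {
  m_mode <- match.arg(m_mode)
  stopifnot(inherits(result, "pairwise_kinship"),
            inherits(x, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  freqs <- loci_frequencies(x)
  fe <- .freq_env(freqs)
  result$final_classification <- result$classification
  amb <- which(result$classification == "ambiguous")
  tests <- data.frame(id1 = character(), id2 = character(),
                      null = character(), alt = character(),
                      p = numeric(), stringsAsFactors = FALSE)
  if (length(amb) == 0L) {
    attr(result, "lrt_tests") <- tests
    return(result)
  }
  null_cache <- new.env(parent = emptyenv())
  lam_cache_key <- function(null_r, alt_r, joint)
    paste(null_r, alt_r, paste(joint, collapse = "."), sep = "|")
  for (q in amb) {
    pg <- pair_genotypes(x, result$id1[q], result$id2[q])
    top <- result$ml_relationship[q]
    set <- strsplit(result$confidence_set[q], ",", fixed = TRUE)[[1L]]
    alts <- setdiff(set, top)
    if (length(alts) == 0L) next
    S <- .pair_sterms(pg$g1, pg$g2, freqs)
    lnl <- stats::setNames(.hyp_lnl(S, candidates), candidates$label)
    joint <- which(!is.na(pg$g1[1L, ]) & !is.na(pg$g2[1L, ]))
    for (a in alts) {
      key <- lam_cache_key(a, top, joint)
      if (is.null(null_cache[[key]])) {
        batch <- .sim_pairs_batch(fe$plist[joint], .as_k(a), n_sim)
        lnl_sim <- .batch_lnl(batch, fe$plist[joint], candidates)
        null_cache[[key]] <- lnl_sim[, match(top, candidates$label)] -
          lnl_sim[, match(a, candidates$label)]
      }
      lam_obs <- if (is.infinite(lnl[a])) Inf else lnl[top] - lnl[a]
      p <- (sum(null_cache[[key]] >= lam_obs - 1e-12) + 1) / (n_sim + 1)
      tests <- rbind(tests, data.frame(id1 = result$id1[q],
                                       id2 = result$id2[q],
                                       null = a, alt = top, p = p,
                                       stringsAsFactors = FALSE))
    }
  }
  if (m_mode == "global") {
    tests$p_adjusted <- bonferroni_adjust(tests$p)
  } else {
    tests$p_adjusted <- tests$p
    for (grp in split(seq_len(nrow(tests)),
                      paste(tests$id1, tests$id2, sep = "\r")))
      tests$p_adjusted[grp] <- bonferroni_adjust(tests$p[grp])
  }
  related_labels <- setdiff(candidates$label, "U")
  for (q in amb) {
    sel <- tests$id1 == result$id1[q] & tests$id2 == result$id2[q]
    if (!any(sel)) next
    eliminated <- tests$null[sel][tests$p_adjusted[sel] < alpha]
    set <- strsplit(result$confidence_set[q], ",", fixed = TRUE)[[1L]]
    surviving <- setdiff(set, eliminated)
    cls <- if (!"U" %in% surviving &&
               any(surviving %in% related_labels)) "related"
           else if (!any(surviving %in% related_labels)) "unrelated"
           else "ambiguous"
    result$final_classification[q] <- cls
  }
  attr(result, "lrt_tests") <- tests
  result
}
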