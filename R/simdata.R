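#' Simulate unrelated founders under Hardy-Weinberg equilibrium
#'
#' Every genotype is two independent draws from the locus allele
#' frequencies, so founders are mutually unrelated and non-inbred by
#' construction.
#'
#' @param freqs_per_locus named list of `locus_frequencies` objects or
#'   named numeric frequency vectors (names are the allele labels).
#' @param n number of founders.
#' @param seed optional integer seed.
#' @param ids individual labels (default `F01`, `F02`, ...).
#' @return A [genotype_table()].
#' @export
simulate_founders <- function(freqs_per_locus, n, seed = NULL,
                              ids = sprintf("F%02d", seq_len(n))) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  fe <- .freq_env(freqs_per_locus)
  L <- length(fe$loci)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    lab <- fe$alleles[[l]]
    a1[, l] <- lab[sample.int(length(lab), n, replace = TRUE,
                              prob = fe$plist[[l]])]
    a2[, l] <- lab[sample.int(length(lab), n, replace = TRUE,
                              prob = fe$plist[[l]])]
  }
  genotype_table(ids, fe$loci, a1, a2)
}

#' Simulate a Mendelian offspring of two genotyped parents
#'
#' Per locus the offspring receives one uniformly chosen allele from each
#' parent, so it always shares at least one allele with each parent at
#' every jointly genotyped locus; a locus missing in either parent is
#' missing in the offspring.
#'
#' @param x a [genotype_table()] containing both parents.
#' @param parent1,parent2 individual ids.
#' @param seed optional integer seed.
#' @return A 2 x L matrix of allele labels (columns = loci of `x`).
#' @export
simulate_offspring <- function(x, parent1, parent2, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (!is.null(seed)) set.seed(seed)
  pg <- pair_genotypes(x, parent1, parent2)
  L <- length(x$loci)
  pick <- function(g) {
    row <- 1L + (stats::runif(L) < 0.5)
    g[cbind(row, seq_len(L))]
  }
  o1 <- pick(pg$g1)
  o2 <- pick(pg$g2)
  miss <- is.na(o1) | is.na(o2)
  o1[miss] <- NA_integer_; o2[miss] <- NA_integer_
  out <- rbind(pmin(o1, o2), pmax(o1, o2))
  colnames(out) <- x$loci
  out
}

#' Simulate one genotype pair under given IBD coefficients
#'
#' Per locus, the number of shared IBD alleles `m` is drawn from
#' `(k0, k1, k2)`; the first genotype is Hardy-Weinberg, the second copies
#' `m` uniformly chosen alleles identically by descent and fills the rest
#' from the frequencies. This is the single sampling engine behind
#' [confidence_set()], [lrt_specific()] and [pairwise_analysis()].
#'
#' @param freqs_per_locus as in [simulate_founders()].
#' @param k IBD coefficients `c(k0, k1, k2)` or a canonical label.
#' @param seed optional integer seed.
#' @return List with `g1` and `g2`, 2 x L matrices of allele labels.
#' @export
simulate_pair <- function(freqs_per_locus, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fe <- .freq_env(freqs_per_locus)
  batch <- .sim_pairs_batch(fe$plist, .as_k(k), 1L)
  L <- length(fe$loci)
  g1 <- matrix(NA_integer_, 2L, L, dimnames = list(NULL, fe$loci))
  g2 <- g1
  for (l in seq_len(L)) {
    lab <- fe$alleles[[l]]
    g1[, l] <- lab[c(batch[[l]]$a1, batch[[l]]$a2)]
    g2[, l] <- lab[c(batch[[l]]$b1, batch[[l]]$b2)]
  }
  list(g1 = g1, g2 = g2)
}

#' Pedigree specification for the synthetic-data generator
#'
#' Founders are listed by label; each mating names two existing parents and
#' its offspring labels. Matings are processed in order and may use earlier
#' offspring as parents, so the pedigree is acyclic by construction.
#'
#' @param founders character vector of founder labels, or a founder count.
#' @param matings list of matings, each a list with `parents` (two ids) and
#'   `offspring` (one or more new ids).
#' @return An object of class `pedigree_spec` with the parent map and the
#'   derived pairwise relationship truth table (first-degree categories
#'   U/HS/FS/PO; more distant kin are labelled U).
#' @export
pedigree_spec <- function(founders, matings = list()) {
  if (is.numeric(founders))
    founders <- sprintf("F%02d", seq_len(founders))
  founders <- as.character(founders)
  if (anyDuplicated(founders)) stop("duplicate founder label")
  parents <- stats::setNames(vector("list", length(founders)), founders)
  for (m in matings) {
    if (!all(c("parents", "offspring") %in% names(m)))
      stop("each mating needs 'parents' and 'offspring'")
    if (length(m$parents) != 2L || m$parents[1L] == m$parents[2L])
      stop("a mating needs two distinct parents")
    if (!all(m$parents %in% names(parents)))
      stop("mating references undefined parent: ",
           setdiff(m$parents, names(parents))[1L])
    for (o in m$offspring) {
      if (o %in% names(parents)) stop("duplicate individual label: ", o)
      parents[[o]] <- as.character(m$parents)
    }
  }
  ids <- names(parents)
  rel <- function(a, b) {
    pa <- parents[[a]]; pb <- parents[[b]]
    if (b %in% pa || a %in% pb) return("PO")
    if (length(pa) == 2L && length(pb) == 2L) {
      shared <- length(intersect(pa, pb))
      if (shared == 2L) return("FS")
      if (shared == 1L) return("HS")
    }
    "U"
  }
  pairs <- utils::combn(ids, 2L)
  truth <- data.frame(id1 = pairs[1L, ], id2 = pairs[2L, ],
                      relationship = mapply(rel, pairs[1L, ], pairs[2L, ]),
                      stringsAsFactors = FALSE)
  structure(list(founders = founders, matings = matings,
                 parents = parents, truth = truth),
            class = "pedigree_spec")
}

#' Simulate genotypes for a pedigree
#'
#' Founders are drawn under Hardy-Weinberg with [simulate_founders()] and
#' offspring by Mendelian segregation with [simulate_offspring()], in the
#' order the matings are given.
#'
#' @param freqs_per_locus as in [simulate_founders()].
#' @param spec a [pedigree_spec()].
#' @param seed optional integer seed.
#' @return List with `table` (a [genotype_table()] over all pedigree
#'   members) and `truth` (the pairwise relationship truth table).
#' @export
simulate_pedigree <- function(freqs_per_locus, spec, seed = NULL) {
  stopifnot(inherits(spec, "pedigree_spec"))
  if (!is.null(seed)) set.seed(seed)
  x <- simulate_founders(freqs_per_locus, length(spec$founders),
                         ids = spec$founders)
  for (m in spec$matings) {
    for (o in m$offspring) {
      g <- simulate_offspring(x, m$parents[1L], m$parents[2L])
      x <- genotype_table(c(x$ids, o), x$loci,
                          rbind(x$a1, g[1L, ]), rbind(x$a2, g[2L, ]))
    }
  }
  list(table = x, truth = spec$truth)
}

#' Random frequency profile emulating the reference marker panel
#'
#' Generates 10 loci with 2-8 alleles each (skewed towards 3-5, matching
#' the panel's 2-8 range and its mean of about 4.4 alleles per locus) and
#' skewed allele-frequency vectors calibrated so that each locus's gene
#' diversity `1 - sum(p^2)` lies in roughly `[0.3, 0.6]`, putting the
#' panel-mean expected heterozygosity near 0.45 as observed for the real
#' markers. Allele labels are plausible fragment lengths (a random base
#' size plus dinucleotide steps).
#'
#' @param seed optional integer seed; the same seed yields the same profile.
#' @return Named list of `locus_frequencies` objects (with `n_genotyped`
#'   `NA`: these are generating frequencies, not estimates).
#' @export
random_panel_frequencies <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_loci <- 10L
  counts <- sample(2:8, n_loci, replace = TRUE,
                   prob = c(0.18, 0.2, 0.25, 0.15, 0.1, 0.06, 0.06))
  out <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    m <- counts[l]
    h_max <- 1 - 1 / m
    h_target <- stats::runif(1L, 0.30, min(0.60, 0.95 * h_max))
    # dominant-allele profile: mix a random simplex point with a point mass
    # on allele 1, solving the mixing weight for the target gene diversity
    base <- stats::rexp(m)
    base <- base / sum(base)
    spike <- c(1, rep(0, m - 1L))
    unif <- rep(1 / m, m)
    # pull the random simplex point towards a point mass (to lower gene
    # diversity) or towards uniform (to raise it) until it hits the target
    target_dir <- if (1 - sum(base^2) >= h_target) spike else unif
    mix <- function(s) (1 - s) * base + s * target_dir
    f <- function(s) 1 - sum(mix(s)^2) - h_target
    s <- if (abs(f(0)) < 1e-12) 0 else stats::uniroot(f, c(0, 1))$root
    p <- mix(s)
    size <- sample(120:290, 1L)
    out[[l]] <- structure(list(locus = sprintf("SL%02d", l),
                               alleles = as.integer(size + 2L * (0:(m - 1L))),
                               freqs = p,
                               n_genotyped = NA_integer_),
                          class = "locus_frequencies")
  }
  stats::setNames(out, vapply(out, `[[`, "", "locus"))
}

#' Randomly set genotypes missing
#'
#' Each genotype is independently replaced by the missing code with the
#' given probability; supports testing of the missing-data filter and of
#' pairwise locus skipping.
#'
#' @param x a [genotype_table()].
#' @param rate missing probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return A [genotype_table()].
#' @export
inject_missing <- function(x, rate, seed = NULL) {
  stopifnot(inherits(x, "genotype_table"), rate >= 0, rate < 1)
  if (rate == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  drop <- matrix(stats::runif(length(x$a1)) < rate, nrow(x$a1))
  a1 <- x$a1; a2 <- x$a2
  a1[drop] <- NA_integer_
  a2[drop] <- NA_integer_
  genotype_table(x$ids, x$loci, a1, a2)
}
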