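# Shared fixtures, all built in code.

# Single-locus table of 22 diploids: n_aa homozygotes A/A, n_ab
# heterozygotes A/B (the configurations forced by the published per-locus
# statistics of the two biallelic panel loci).
biallelic_config <- function(n_aa, n_ab, locus = "L") {
  n <- n_aa + n_ab
  genotype_table(sprintf("I%02d", seq_len(n)), locus,
                 a1 = matrix(rep(1L, n), n, 1),
                 a2 = matrix(c(rep(1L, n_aa), rep(2L, n_ab)), n, 1))
}

hha04_config <- function() biallelic_config(21L, 1L)
hha01_config <- function() biallelic_config(16L, 6L)

# Random complete genotype table from a random frequency profile.
random_table <- function(n = 8, n_loci = 5, seed = 1) {
  set.seed(seed)
  freqs <- lapply(seq_len(n_loci), function(l) {
    m <- sample(2:5, 1)
    p <- rexp(m); p <- p / sum(p)
    names(p) <- sort(sample(100:300, m))
    p
  })
  names(freqs) <- sprintf("L%02d", seq_len(n_loci))
  simulate_founders(freqs, n, ids = sprintf("I%02d", seq_len(n)))
}

# Equifrequent multi-allelic frequency profile (highly informative loci).
equifreq_profile <- function(n_loci = 10, n_alleles = 8) {
  stats::setNames(
    lapply(seq_len(n_loci), function(l)
      stats::setNames(rep(1 / n_alleles, n_alleles), seq_len(n_alleles))),
    sprintf("L%02d", seq_len(n_loci)))
}

# Published per-locus Q and I columns of the reference panel.
panel_q <- function() {
  s <- load_panel_stats()
  stats::setNames(s$q_exclusion, s$locus)
}
panel_i <- function() {
  s <- load_panel_stats()
  stats::setNames(s$i_identity, s$locus)
}

expect_tables_equal <- function(a, b) {
  expect_identical(a$ids, b$ids)
  expect_identical(a$loci, b$loci)
  expect_identical(unname(a$a1), unname(b$a1))
  expect_identical(unname(a$a2), unname(b$a2))
}
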