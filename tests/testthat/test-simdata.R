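test_that("founder simulation is HWE sampling, deterministic under seed", {
  fr <- list(L = c(0.5, 0.5))
  gt <- simulate_founders(fr, 10000, seed = 1)
  het <- observed_heterozygosity(gt, "L")
  expect_lt(abs(het - 0.5), 0.015)  # 3 binomial SE

  mono <- simulate_founders(list(L = c(1)), 20, seed = 2)
  expect_true(all(mono$a1 == mono$a2))

  expect_tables_equal(simulate_founders(fr, 50, seed = 3),
                      simulate_founders(fr, 50, seed = 3))
  t4 <- simulate_founders(equifreq_profile(5, 4), 50, seed = 4)
  t5 <- simulate_founders(equifreq_profile(5, 4), 50, seed = 5)
  expect_false(identical(t4$a1, t5$a1))
})

test_that("offspring follow Mendelian segregation", {
  # AA x BB parents force AB offspring
  gt <- genotype_table(c("P1", "P2"), "L",
                       matrix(c(1L, 2L), 2, 1), matrix(c(1L, 2L), 2, 1))
  o <- simulate_offspring(gt, "P1", "P2", seed = 6)
  expect_equal(unname(o[, 1]), c(1L, 2L))

  # AB x AB: genotype ratios 1:2:1 within 3 SE
  gt <- genotype_table(c("P1", "P2"), "L",
                       matrix(c(1L, 1L), 2, 1), matrix(c(2L, 2L), 2, 1))
  set.seed(7)
  kids <- replicate(10000, simulate_offspring(gt, "P1", "P2")[, 1])
  frac_aa <- mean(kids[1, ] == 1 & kids[2, ] == 1)
  frac_ab <- mean(kids[1, ] != kids[2, ])
  expect_lt(abs(frac_aa - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(frac_ab - 0.50), 3 * sqrt(0.5 * 0.5 / 10000))
})

test_that("offspring always share an allele with each parent", {
  fr <- equifreq_profile(8, 6)
  gt <- simulate_founders(fr, 2, seed = 8, ids = c("P1", "P2"))
  for (rep in 1:20) {
    o <- simulate_offspring(gt, "P1", "P2")
    for (l in seq_len(8)) {
      expect_true(any(o[, l] %in% c(gt$a1["P1", l], gt$a2["P1", l])))
      expect_true(any(o[, l] %in% c(gt$a1["P2", l], gt$a2["P2", l])))
    }
  }
  # a missing parental locus propagates as missing
  a1 <- gt$a1; a2 <- gt$a2
  a1[1, 1] <- NA; a2[1, 1] <- NA
  gtm <- genotype_table(gt$ids, gt$loci, a1, a2)
  o <- simulate_offspring(gtm, "P1", "P2", seed = 9)
  expect_true(is.na(o[1, 1]) && is.na(o[2, 1]))
})

test_that("simulated pairs realise the requested IBD sharing", {
  fr <- equifreq_profile(6, 5)
  pr <- simulate_pair(fr, "PO", seed = 10)
  for (l in 1:6)
    expect_true(length(intersect(pr$g1[, l], pr$g2[, l])) >= 1)
  pr <- simulate_pair(fr, c(0, 0, 1), seed = 11)
  expect_equal(pr$g1, pr$g2)
})

test_that("pair sampling matches the likelihood mixture cell by cell", {
  p <- c(0.5, 0.3, 0.2)
  n <- 200000
  gen <- which(upper.tri(diag(3), diag = TRUE), arr.ind = TRUE)
  hyp <- relationship_hypotheses()
  for (h in seq_len(nrow(hyp))) {
    k <- c(hyp$k0[h], hyp$k1[h], hyp$k2[h])
    set.seed(100 + h)
    b <- msatkin:::.sim_pairs_batch(list(p), k, n)[[1]]
    emp <- table(paste(b$a1, b$a2, b$b1, b$b2)) / n
    for (i in seq_len(nrow(gen))) for (j in seq_len(nrow(gen))) {
      st <- msatkin:::.locus_sterms(gen[i, 1], gen[i, 2],
                                    gen[j, 1], gen[j, 2], p)
      prob <- k[1] * st$S0 + k[2] * st$S1 + k[3] * st$S2
      key <- paste(gen[i, 1], gen[i, 2], gen[j, 1], gen[j, 2])
      obs <- if (key %in% names(emp)) emp[[key]] else 0
      se <- sqrt(max(prob * (1 - prob), 1e-12) / n)
      expect_lt(abs(obs - prob), 3.5 * se + 1e-6)
    }
  }
})

test_that("pedigree specs derive the correct relationship truth table", {
  # nuclear family: two founders, two joint offspring
  spec <- pedigree_spec(c("M", "F"),
                        list(list(parents = c("M", "F"),
                                  offspring = c("O1", "O2"))))
  truth <- spec$truth
  lab <- function(a, b)
    truth$relationship[(truth$id1 == a & truth$id2 == b) |
                       (truth$id1 == b & truth$id2 == a)]
  expect_equal(lab("M", "F"), "U")
  expect_equal(lab("O1", "O2"), "FS")
  for (p in c("M", "F")) for (o in c("O1", "O2"))
    expect_equal(lab(p, o), "PO")

  # half-sibs: one sire, two dams, one offspring each
  spec <- pedigree_spec(c("S", "D1", "D2"),
                        list(list(parents = c("S", "D1"), offspring = "A"),
                             list(parents = c("S", "D2"), offspring = "B")))
  expect_equal(spec$truth$relationship[spec$truth$id1 == "A" &
                                       spec$truth$id2 == "B"], "HS")

  # founders only: everything unrelated
  spec <- pedigree_spec(20)
  expect_true(all(spec$truth$relationship == "U"))
  expect_equal(nrow(spec$truth), choose(20, 2))

  expect_error(pedigree_spec("A", list(list(parents = c("A", "Z"),
                                            offspring = "B"))),
               "undefined parent")
  expect_error(pedigree_spec(c("A", "B"),
                             list(list(parents = c("A", "B"),
                                       offspring = "A"))),
               "duplicate")
})

test_that("pedigree simulation produces genotypes consistent with descent", {
  fr <- equifreq_profile(10, 6)
  spec <- pedigree_spec(c("M", "F"),
                        list(list(parents = c("M", "F"),
                                  offspring = c("O1", "O2"))))
  ped <- simulate_pedigree(fr, spec, seed = 12)
  gt <- ped$table
  expect_setequal(gt$ids, c("M", "F", "O1", "O2"))
  for (o in c("O1", "O2")) for (p in c("M", "F")) for (l in seq_len(10)) {
    shared <- intersect(c(gt$a1[o, l], gt$a2[o, l]),
                        c(gt$a1[p, l], gt$a2[p, l]))
    expect_gte(length(shared), 1L)
  }
})

test_that("the random panel profile matches the reference panel's shape", {
  for (seed in 1:20) {
    prof <- random_panel_frequencies(seed)
    expect_equal(length(prof), 10L)
    counts <- vapply(prof, function(f) length(f$alleles), integer(1))
    expect_true(all(counts >= 2 & counts <= 8))
    h <- vapply(prof, function(f) 1 - sum(f$freqs^2), numeric(1))
    expect_gte(mean(h), 0.35)
    expect_lte(mean(h), 0.55)
    expect_true(all(vapply(prof, function(f)
      abs(sum(f$freqs) - 1) < 1e-12, logical(1))))
  }
  expect_identical(random_panel_frequencies(3), random_panel_frequencies(3))
})

test_that("missing-data injection hits its target rate", {
  gt <- simulate_founders(equifreq_profile(10, 4), 1000, seed = 13)
  expect_tables_equal(inject_missing(gt, 0), gt)
  gtm <- inject_missing(gt, 0.5, seed = 14)
  expect_lt(abs(mean(is.na(gtm$a1)) - 0.5), 0.015)
  # composition with the missing-data filter
  gt2 <- simulate_founders(equifreq_profile(12, 4), 40, seed = 15)
  gtm2 <- inject_missing(gt2, 0.08, seed = 16)
  res <- filter_missing(gtm2, 0.10)
  expect_true(all(missing_fraction(res$table, "locus") <= 0.10))
  expect_true(all(missing_fraction(res$table, "individual") <= 0.10))
})

test_that("founder diversity converges to the generating heterozygosity", {
  prof <- random_panel_frequencies(17)
  gt <- simulate_founders(prof, 2000, seed = 18)
  he_theory <- vapply(prof, function(f) 1 - sum(f$freqs^2), numeric(1))
  he_obs <- vapply(gt$loci, function(l)
    expected_heterozygosity_unbiased(allele_frequencies(gt, l)), numeric(1))
  expect_lt(max(abs(he_obs - he_theory)), 0.03)
})
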