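test_that("pair likelihood follows the IBD mixture on worked examples", {
  fr <- list(L1 = c(0.5, 0.5))
  aa <- matrix(c(1, 1), 2); ab <- matrix(c(1, 2), 2); bb <- matrix(c(2, 2), 2)
  expect_equal(exp(pair_likelihood(aa, ab, fr, "U")), 0.25 * 0.5)
  expect_equal(pair_likelihood(aa, bb, fr, "PO"), -Inf)
  # S1 worked cases at a 3-allele locus
  fr3 <- list(L1 = c(0.5, 0.3, 0.2))
  expect_equal(exp(pair_likelihood(matrix(c(1, 1), 2), matrix(c(1, 1), 2),
                                   fr3, "PO")), 0.5^3)
  expect_equal(exp(pair_likelihood(matrix(c(1, 2), 2), matrix(c(1, 3), 2),
                                   fr3, "PO")), 0.5 * 0.3 * 0.2)
  expect_equal(exp(pair_likelihood(matrix(c(1, 2), 2), matrix(c(1, 2), 2),
                                   fr3, "PO")), 0.5 * 0.3 * (0.5 + 0.3))
})

test_that("joint pair probabilities sum to one under every hypothesis", {
  set.seed(7)
  for (rep in 1:3) {
    m <- sample(2:4, 1)
    p <- rexp(m); p <- p / sum(p)
    fr <- list(L1 = p)
    gen <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
    for (lab in c("U", "HS", "FS", "PO")) {
      tot <- 0
      for (i in seq_len(nrow(gen))) for (j in seq_len(nrow(gen)))
        tot <- tot + exp(pair_likelihood(matrix(gen[i, ], 2),
                                         matrix(gen[j, ], 2), fr, lab))
      expect_lt(abs(tot - 1), 1e-10)
    }
  }
})

test_that("pair statistics are symmetric in the two individuals", {
  fr <- equifreq_profile(5, 4)
  set.seed(8)
  for (rep in 1:10) {
    pr <- simulate_pair(fr, sample(c("U", "HS", "FS", "PO"), 1))
    for (lab in c("U", "HS", "FS", "PO"))
      expect_equal(pair_likelihood(pr$g1, pr$g2, fr, lab),
                   pair_likelihood(pr$g2, pr$g1, fr, lab))
    expect_equal(ml_relatedness(pr$g1, pr$g2, fr)$r,
                 ml_relatedness(pr$g2, pr$g1, fr)$r)
  }
})

test_that("alleles absent from the frequencies are an error", {
  fr <- list(L1 = c(0.5, 0.5))
  expect_error(pair_likelihood(matrix(c(1, 3), 2), matrix(c(1, 1), 2),
                               fr, "U"), "absent")
})

test_that("monomorphic loci give a flat likelihood resolved towards U", {
  fr <- list(L1 = c(1), L2 = c(1))
  g <- matrix(1, 2, 2)
  est <- ml_relatedness(g, g, fr)
  expect_equal(unname(est$k), c(1, 0, 0))
  expect_equal(est$r, 0)
})

test_that("ML relatedness recovers the simulated IBD level", {
  fr <- equifreq_profile(10, 8)
  set.seed(91)
  means <- sapply(c("U", "HS", "FS", "PO"), function(lab) {
    rs <- replicate(200, {
      pr <- simulate_pair(fr, lab)
      ml_relatedness(pr$g1, pr$g2, fr)$r
    })
    expect_true(all(rs >= 0 & rs <= 1))
    mean(rs)
  })
  # the boundary at r = 0 inflates the U mean slightly but bounds it by ~0.08
  expect_gte(means[["U"]], 0)
  expect_lte(means[["U"]], 0.08)
  expect_lt(abs(means[["HS"]] - 0.25), 0.05)
  expect_lt(abs(means[["FS"]] - 0.50), 0.05)
  expect_lt(abs(means[["PO"]] - 0.50), 0.05)
})

test_that("a pair sharing no allele at some locus can never be PO", {
  fr <- list(L1 = c(0.25, 0.25, 0.25, 0.25), L2 = c(0.5, 0.5))
  g1 <- matrix(c(1, 2, 1, 1), 2)
  g2 <- matrix(c(3, 4, 1, 2), 2)
  lab <- ml_relationship(g1, g2, fr)
  expect_true(lab != "PO")
  expect_equal(unname(attr(lab, "lnl")["PO"]), -Inf)
})

test_that("identical rare-allele heterozygotes look like full siblings", {
  # ten loci, each with rare alleles (p = 0.05); both individuals carry the
  # same heterozygous genotype everywhere: the S2 term dominates and FS
  # beats PO (which has no S2 mass) and U/HS
  p <- c(0.05, 0.05, rep(0.9 / 16, 16))
  fr <- stats::setNames(rep(list(p), 10), paste0("L", 1:10))
  g <- matrix(rep(c(1, 2), 10), 2)
  expect_equal(as.character(ml_relationship(g, g, fr)), "FS")
})

test_that("ML relationship classifies simulated pairs acceptably", {
  fr <- equifreq_profile(10, 8)
  set.seed(17)
  rate <- sapply(c("U", "PO"), function(lab) {
    hits <- replicate(200, {
      pr <- simulate_pair(fr, lab)
      as.character(ml_relationship(pr$g1, pr$g2, fr)) == lab
    })
    mean(hits)
  })
  expect_gte(rate[["U"]], 0.80)
  expect_gte(rate[["PO"]], 0.60)
})

test_that("the ML hypothesis always belongs to its confidence set", {
  fr <- equifreq_profile(6, 4)
  set.seed(23)
  for (rep in 1:5) {
    pr <- simulate_pair(fr, sample(c("U", "HS", "FS", "PO"), 1))
    cs <- confidence_set(pr$g1, pr$g2, fr, n_sim = 300)
    expect_true(as.character(ml_relationship(pr$g1, pr$g2, fr)) %in% cs)
    expect_true(all(attr(cs, "p_values") >= 0 &
                    attr(cs, "p_values") <= 1))
  }
})

test_that("informative loci exclude U from the set of most FS pairs", {
  fr <- equifreq_profile(20, 8)
  set.seed(29)
  excl <- replicate(60, {
    pr <- simulate_pair(fr, "FS")
    !"U" %in% confidence_set(pr$g1, pr$g2, fr, n_sim = 500)
  })
  expect_gt(mean(excl), 0.5)
})

test_that("classification follows the conservative rule", {
  expect_equal(classify_pair(c("FS")), "related")
  expect_equal(classify_pair(c("HS", "FS", "PO")), "related")
  expect_equal(classify_pair(c("U")), "unrelated")
  expect_equal(classify_pair(c("U", "HS")), "ambiguous")
  expect_error(classify_pair(character(0)), "empty")
})

test_that("the likelihood-ratio test rejects U for a strong FS pair", {
  fr <- equifreq_profile(20, 8)
  set.seed(37)
  pr <- simulate_pair(fr, "FS")
  p <- lrt_specific(pr$g1, pr$g2, fr, null_r = "U", alt_r = "FS",
                    n_sim = 2000)
  expect_lt(p, 0.01)
  expect_error(lrt_specific(pr$g1, pr$g2, fr, "U", "U"), "differ")
})

test_that("the likelihood-ratio test holds its size under the null", {
  fr <- equifreq_profile(10, 8)
  set.seed(41)
  pvals <- replicate(200, {
    pr <- simulate_pair(fr, "U")
    lrt_specific(pr$g1, pr$g2, fr, null_r = "U", alt_r = "FS",
                 n_sim = 400)
  })
  mc_se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * mc_se)
})

test_that("pairwise analysis enumerates all pairs deterministically", {
  fr <- equifreq_profile(6, 6)
  gt <- simulate_founders(fr, 8, seed = 51)
  res <- pairwise_analysis(gt, n_sim = 300, seed = 52)
  expect_equal(nrow(res), choose(8, 2))
  rm1 <- attr(res, "r_matrix")
  expect_equal(rm1, t(rm1))
  expect_equal(unname(diag(rm1)), rep(1, 8))
  res2 <- pairwise_analysis(gt, n_sim = 300, seed = 52)
  expect_equal(res$r, res2$r)
  expect_equal(res$confidence_set, res2$confidence_set)

  two <- gt[1:2, ]
  res3 <- pairwise_analysis(two, n_sim = 300, seed = 53)
  expect_equal(nrow(res3), 1L)
})

test_that("more loci do not inflate the related rate of true-U pairs", {
  fr <- equifreq_profile(15, 6)
  gt_small <- simulate_founders(fr[1:5], 16, seed = 61)
  gt_large <- simulate_founders(fr, 16, seed = 61)
  res_s <- pairwise_analysis(gt_small, n_sim = 300, seed = 62)
  res_l <- pairwise_analysis(gt_large, n_sim = 300, seed = 63)
  rate <- function(r) mean(r$classification == "related")
  expect_lte(rate(res_l), rate(res_s) + 0.05)
})

test_that("ambiguous pairs resolve by Bonferroni-corrected LRTs", {
  fr <- equifreq_profile(15, 8)
  set.seed(71)
  # a run of 20 true-unrelated pairs (disjoint founder pairs) and 20 true
  # full-sib pairs (one sibship per family), all in one genotype table
  founders <- simulate_founders(fr, 40, ids = sprintf("U%02d", 1:40))
  sib_rows_a1 <- NULL; sib_rows_a2 <- NULL; sib_ids <- character(0)
  for (s in 1:20) {
    ped <- simulate_pedigree(
      fr, pedigree_spec(c(sprintf("P%da", s), sprintf("P%db", s)),
                        list(list(parents = c(sprintf("P%da", s),
                                              sprintf("P%db", s)),
                                  offspring = sprintf("S%02d", 2 * s - 1:0)))))
    keep <- match(sprintf("S%02d", 2 * s - 1:0), ped$table$ids)
    sib_rows_a1 <- rbind(sib_rows_a1, ped$table$a1[keep, ])
    sib_rows_a2 <- rbind(sib_rows_a2, ped$table$a2[keep, ])
    sib_ids <- c(sib_ids, sprintf("S%02d", 2 * s - 1:0))
  }
  gt <- genotype_table(c(founders$ids, sib_ids),
                       founders$loci,
                       rbind(founders$a1, sib_rows_a1),
                       rbind(founders$a2, sib_rows_a2))
  freqs <- loci_frequencies(gt)
  pair_list <- c(lapply(1:20, function(s)
                   sprintf("U%02d", 2 * s - 1:0)),
                 lapply(1:20, function(s)
                   sprintf("S%02d", 2 * s - 1:0)))
  set.seed(72)
  rows <- lapply(pair_list, function(ids) {
    pg <- pair_genotypes(gt, ids[1], ids[2])
    cs <- confidence_set(pg$g1, pg$g2, freqs, n_sim = 400)
    mlr <- ml_relationship(pg$g1, pg$g2, freqs)
    lnl <- attr(mlr, "lnl")
    data.frame(id1 = ids[1], id2 = ids[2],
               r = ml_relatedness(pg$g1, pg$g2, freqs)$r,
               lnl_U = lnl[["U"]], lnl_HS = lnl[["HS"]],
               lnl_FS = lnl[["FS"]], lnl_PO = lnl[["PO"]],
               ml_relationship = as.character(mlr),
               confidence_set = paste(cs, collapse = ","),
               classification = classify_pair(cs),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("pairwise_kinship", class(res))
  is_fs_pair <- res$id1 %in% sib_ids

  # per-pair correction: a majority of the U-leaning ambiguities resolve
  fin <- resolve_ambiguous(res, gt, n_sim = 2000, seed = 73,
                           m_mode = "per_pair")
  amb_u <- !is_fs_pair & res$classification == "ambiguous" &
    res$ml_relationship == "U"
  expect_gt(sum(amb_u), 0)
  expect_gte(mean(fin$final_classification[amb_u] == "unrelated"), 0.5)
  # no true full-sib pair may end up unrelated
  expect_false(any(fin$final_classification[is_fs_pair] == "unrelated"))
  # untouched classifications pass through
  keep <- res$classification != "ambiguous"
  expect_equal(fin$final_classification[keep], fin$classification[keep])

  # the default run-wide correction is stricter: it can only keep pairs
  # ambiguous that the per-pair correction resolved, never the reverse
  fing <- resolve_ambiguous(res, gt, n_sim = 2000, seed = 73)
  expect_false(any(fing$final_classification[is_fs_pair] == "unrelated"))
  resolved_g <- fing$final_classification != "ambiguous"
  resolved_p <- fin$final_classification != "ambiguous"
  expect_true(all(resolved_g[res$classification == "ambiguous"] <=
                  resolved_p[res$classification == "ambiguous"]))

  # no ambiguous pairs: identity, no tests performed
  clean <- res[res$classification != "ambiguous", ]
  fin0 <- resolve_ambiguous(clean, gt, n_sim = 200, seed = 74)
  expect_equal(fin0$final_classification, fin0$classification)
  expect_equal(nrow(attr(fin0, "lrt_tests")), 0L)
})
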