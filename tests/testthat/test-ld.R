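test_that("perfect coupling gives r2 = D' = 1 with only two haplotypes", {
  set.seed(71)
  g <- rbinom(200, 2, 0.3)
  while (var(g) == 0) g <- rbinom(200, 2, 0.3)
  m <- make_matrix(cbind(g, g))
  ld <- compute_ld(m, 1, 2)
  expect_equal(ld$r2, 1, tolerance = 1e-9)
  expect_equal(ld$D_prime, 1, tolerance = 1e-9)
  expect_equal(unname(ld$hap_freqs["p01"] + ld$hap_freqs["p10"]), 0,
               tolerance = 1e-9)
})

test_that("independent loci show near-zero r2 and the D = 0 convention", {
  set.seed(72)
  m <- make_matrix(cbind(rbinom(10000, 2, 0.3), rbinom(10000, 2, 0.4)))
  ld <- compute_ld(m, 1, 2)
  expect_lt(ld$r2, 0.01)

  # exact D = 0 by construction: one double homozygote of each combination
  g <- table_to_genotypes(matrix(c(1, 0, 1, 0, 0, 0, 1, 0, 1), 3, byrow = TRUE))
  ld0 <- compute_ld(make_matrix(cbind(g$gA, g$gB)), 1, 2)
  expect_equal(ld0$D, 0, tolerance = 1e-9)
  expect_equal(ld0$D_prime, 0)
})

test_that("EM equals the likelihood-grid maximizer on small tables", {
  # hand-built 6-sample table with one double heterozygote
  tab <- matrix(c(2, 1, 0,
                  0, 1, 0,
                  0, 0, 2), 3, 3, byrow = TRUE)
  g <- table_to_genotypes(tab)
  em <- estimate_haplotype_freqs_em(g$gA, g$gB)
  grid <- ld_grid_oracle(g$gA, g$gB)
  expect_lt(min(abs(unname(em$hap_freqs["p11"]) - grid$p11)), 1e-3)
  expect_gte(em$loglik, grid$loglik - 1e-6)

  # exhaustive polymorphic tables at n = 4
  for (tab in all_two_locus_tables(4)) {
    g <- table_to_genotypes(tab)
    em <- estimate_haplotype_freqs_em(g$gA, g$gB)
    grid <- ld_grid_oracle(g$gA, g$gB)
    expect_gte(em$loglik, grid$loglik - 1e-6)
    expect_lt(min(abs(unname(em$hap_freqs["p11"]) - grid$p11)), 1e-3)
  }
})

test_that("EM log-likelihood is monotone and phase-unambiguous data exact", {
  # no double heterozygotes: haplotypes are countable directly
  tab <- matrix(c(3, 2, 0,
                  1, 0, 2,
                  0, 1, 3), 3, 3, byrow = TRUE)
  g <- table_to_genotypes(tab)
  em <- estimate_haplotype_freqs_em(g$gA, g$gB)
  n <- sum(tab)
  # direct haplotype counting: each sample splits uniquely
  c00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  c01 <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  c10 <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2]
  c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  expect_equal(unname(em$hap_freqs),
               c(c00, c01, c10, c11) / (2 * n), tolerance = 1e-9)

  # all-homozygote fixture: r2 equals the squared Pearson correlation
  set.seed(73)
  h <- rbinom(80, 1, 0.4); noise <- rbinom(80, 1, 0.15)
  k <- (h + noise) %% 2
  if (var(k) == 0) k[1] <- 1 - k[1]
  m <- make_matrix(cbind(2L * h, 2L * k))
  ld <- compute_ld(m, 1, 2)
  expect_equal(ld$r2, cor(2 * h, 2 * k)^2, tolerance = 1e-9)
})

test_that("monomorphic loci are an undefined-LD error", {
  expect_error(estimate_haplotype_freqs_em(rep(0L, 10), rbinom(10, 2, 0.5)),
               "monomorphic")
  expect_error(estimate_haplotype_freqs_em(c(0L, 1L), c(1L, NA)),
               "at least 2 samples")
})

test_that("shortlisting honors the window and the strict LD thresholds", {
  set.seed(74)
  g <- rbinom(300, 2, 0.35)
  noisy <- g; flip <- sample(300, 60)
  noisy[flip] <- rbinom(60, 2, 0.35)
  calls <- cbind(g, g, noisy, g)
  m <- genotype_matrix(
    data.frame(chrom = "6",
               pos = c(38278097L, 39278097L, 40278097L, 44778097L),
               id = c("idx", "perfect_1mb", "noisy", "far_6.5mb"),
               allele_A = "A", allele_B = "C", stringsAsFactors = FALSE),
    sprintf("s%d", 1:300), calls)
  sl <- shortlist_linked(m, "idx")
  expect_true("perfect_1mb" %in% sl$id)
  expect_false("far_6.5mb" %in% sl$id)     # outside the 5 Mb window
  expect_true(all(sl$r2 > 0.8 & sl$dprime > 0.9))
  # descending r2 ordering
  expect_true(all(diff(sl$r2) <= 1e-12))

  # strictness: a partner exactly at the threshold is excluded
  r2_noisy <- compute_ld(m, 1, 3)$r2
  cfg <- ld_config(r2_min = min(r2_noisy, 0.999), dprime_min = 0.1)
  sl2 <- shortlist_linked(m, "idx", cfg)
  expect_false("noisy" %in% sl2$id)

  # invariance to variant storage order: same shortlist from permuted input
  perm <- c(3, 1, 4, 2)
  m2 <- genotype_matrix(m$variants[perm, ], m$samples,
                        m$calls[, perm], NULL)
  sl3 <- shortlist_linked(m2, "idx")
  expect_equal(sl3$id, sl$id)
  expect_equal(sl3$r2, sl$r2, tolerance = 1e-12)
})

test_that("a marker recombined off the lethal background shows decayed LD", {
  cfg <- lethal_sim_config(n_samples = 500, q_pre = 0.21,
                           recomb_fraction = 0.1, n_generations = 20,
                           n_pop = 600, seed = 75)
  sim <- simulate_lethal_population(cfg)
  j_causal <- sim$truth$lethal_idx[1]
  j_marker <- match("linked_marker", sim$matrix$variants$id)
  ld <- compute_ld(sim$matrix, j_causal, j_marker)
  expect_gt(ld$r2, 0)
  expect_lt(ld$r2, 1)
})
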