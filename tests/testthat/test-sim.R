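test_that("survivor carrier fraction follows 2q/(1+q)", {
  expect_equal(survivor_carrier_fraction(0)$het_fraction, 0)
  expect_equal(survivor_carrier_fraction(0.2121)$het_fraction,
               2 * 0.2121 / 1.2121)
  expect_equal(survivor_carrier_fraction(0.35 / 1.65)$het_fraction, 0.35)
  # survivor allele frequency is always half the carrier fraction
  for (q in c(0.05, 0.2, 0.45))
    expect_equal(survivor_carrier_fraction(q)$allele_frequency,
                 survivor_carrier_fraction(q)$het_fraction / 2)
})

test_that("emitted survivors carry no minor homozygotes at lethal markers", {
  for (seed in c(81, 82)) {
    sim <- simulate_lethal_population(lethal_sim_config(
      n_samples = 400, q_pre = 0.3, n_neutral = 10, seed = seed))
    lethal <- sim$matrix$calls[, sim$truth$lethal_idx, drop = FALSE]
    expect_true(all(lethal %in% 0:1))
    # every minor allele sits in a heterozygote: het fraction = 2 * freq
    expect_equal(sim$truth$carrier_fraction,
                 2 * sim$truth$allele_frequency)
    # the lethal block is in perfect coupling
    expect_equal(lethal[, 1], lethal[, 2])
  }

  sim0 <- simulate_lethal_population(lethal_sim_config(
    n_samples = 100, q_pre = 0, seed = 83))
  expect_true(all(sim0$matrix$calls[, sim0$truth$lethal_idx] == 0L))
})

test_that("identical config and seed reproduce identical output", {
  cfg <- lethal_sim_config(n_samples = 150, q_pre = 0.25, n_neutral = 40,
                           recomb_fraction = 0.05, seed = 84)
  s1 <- simulate_lethal_population(cfg)
  s2 <- simulate_lethal_population(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth$carrier_fraction, s2$truth$carrier_fraction)
})

test_that("neutral SNPs sit at Hardy-Weinberg equilibrium", {
  sim <- simulate_lethal_population(lethal_sim_config(
    n_samples = 500, q_pre = 0, n_lethal_snps = 1, n_neutral = 1500,
    seed = 85))
  res <- scan_deficit(sim$matrix)
  neutral <- grepl("neutral", res$id) & res$tested
  # the exact test is conservative: at most the nominal rate (+ MC slack)
  expect_lte(mean(res$p_hwe[neutral] < 0.05), 0.05 + 0.015)
})

test_that("fully coupled marker mirrors the lethal block; c=0.5 decouples", {
  cfg0 <- lethal_sim_config(n_samples = 400, q_pre = 0.21,
                            recomb_fraction = 1e-9, n_generations = 20,
                            n_pop = 500, seed = 86)
  lm0 <- lethscan:::with_seed(86, simulate_linked_marker(cfg0))
  expect_equal(lm0$truth$marker_minor_hom, 0)
  expect_true(all(lm0$causal_genotypes %in% 0:1))

  # free recombination: the marker escapes selection and shows homozygotes
  homs <- p_unif <- numeric(25)
  for (r in 1:25) {
    cfg5 <- lethal_sim_config(n_samples = 641, q_pre = 0.21,
                              recomb_fraction = 0.5, n_generations = 20,
                              n_pop = 800, seed = 860 + r)
    lm5 <- lethscan:::with_seed(cfg5$seed, simulate_linked_marker(cfg5))
    homs[r] <- lm5$truth$marker_minor_hom
    g <- lm5$genotypes
    p_unif[r] <- hwe_exact_test(c(sum(g == 2), sum(g == 1), sum(g == 0)))
  }
  expect_gt(mean(homs > 0), 0.9)
  # deficit signal gone: p-values no longer concentrated near 0
  expect_gt(median(p_unif), 0.2)
})

test_that("weak recombination yields a few marker homozygotes, causal none", {
  # the published 22-homozygote companion-marker pattern, qualitatively
  reps <- 12; some_homs <- 0
  for (r in seq_len(reps)) {
    cfg <- lethal_sim_config(n_samples = 641, q_pre = 0.21,
                             recomb_fraction = 0.01, n_generations = 20,
                             n_pop = 800, seed = 900 + r)
    lm <- lethscan:::with_seed(cfg$seed, simulate_linked_marker(cfg))
    expect_true(all(lm$causal_genotypes %in% 0:1))
    some_homs <- some_homs + (lm$truth$marker_minor_hom > 0)
  }
  expect_gte(some_homs / reps, 0.5)
})

test_that("injected miscalls are recorded and absent at rate zero", {
  set.seed(87)
  g <- rbinom(150, 2, 0.4)
  cfg <- lethal_sim_config(seed = 88)
  si0 <- simulate_intensities(g, cfg)
  expect_equal(length(si0$truth$miscalled), 0)
  expect_equal(si0$called, as.integer(g))

  cfg$intensity$miscall_rate <- 0.2
  si <- simulate_intensities(g, cfg)
  expect_gt(length(si$truth$miscalled), 0)
  expect_true(all(si$called[si$truth$miscalled] !=
                    g[si$truth$miscalled]))
  expect_equal(si$called[-si$truth$miscalled],
               as.integer(g[-si$truth$miscalled]))
})
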