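#' Configuration of the synthetic lethal-haplotype population
#'
#' Parameterises the forward generative model used to validate the scan: a
#' biallelic haplotype that is embryonic-lethal when homozygous, segregating
#' at pre-selection frequency \code{q_pre}, observed only through its
#' survivors; a panel of neutral background SNPs at Hardy-Weinberg
#' equilibrium; an optional marker partially linked to the causal locus; and
#' a two-channel intensity model for the array signal. The default regime
#' (n = 526 survivors, q_pre = 0.21) matches a pooled Thoroughbred-scale
#' sample in which roughly 35% of survivors are carriers.
#'
#' @param n_samples survivors to emit (default 526).
#' @param q_pre pre-selection lethal-haplotype frequency in [0, 0.5]
#'   (default 0.21).
#' @param n_lethal_snps markers on the lethal haplotype in perfect coupling
#'   (default 2).
#' @param n_neutral neutral background SNP count (default 0).
#' @param neutral_maf_range range of the uniform law for neutral minor-allele
#'   frequencies (default c(0.01, 0.5)).
#' @param recomb_fraction per-meiosis recombination fraction c between the
#'   causal locus and the optional linked marker (default 0 = fully coupled).
#' @param n_generations generations of random mating applied to the linked
#'   marker (default 20).
#' @param n_pop breeding-population size for the linked-marker forward
#'   simulation (default 1000).
#' @param intensity list: theta_means (per-genotype cluster centres on the
#'   contrast coordinate for codes 0/1/2), theta_sd, r_mean, r_sd (signal
#'   radius), miscall_rate.
#' @param seed integer master seed.
#' @export
lethal_sim_config <- function(n_samples = 526, q_pre = 0.21,
                              n_lethal_snps = 2, n_neutral = 0,
                              neutral_maf_range = c(0.01, 0.5),
                              recomb_fraction = 0, n_generations = 20,
                              n_pop = 1000,
                              intensity = list(theta_means = c(0.1, 0.5, 0.9),
                                               theta_sd = 0.03, r_mean = 1,
                                               r_sd = 0.05, miscall_rate = 0),
                              seed = 1) {
  stopifnot(n_samples >= 1, q_pre >= 0, q_pre <= 0.5,
            recomb_fraction >= 0, recomb_fraction <= 0.5,
            n_generations >= 0, n_lethal_snps >= 1, n_neutral >= 0)
  if (q_pre == 0.5 && n_samples < 50)
    warning("q_pre = 0.5 with tiny n: survivor het fraction approaches 2/3")
  structure(list(n_samples = as.integer(n_samples), q_pre = q_pre,
                 n_lethal_snps = as.integer(n_lethal_snps),
                 n_neutral = as.integer(n_neutral),
                 neutral_maf_range = neutral_maf_range,
                 recomb_fraction = recomb_fraction,
                 n_generations = as.integer(n_generations),
                 n_pop = as.integer(n_pop), intensity = intensity,
                 seed = as.integer(seed)),
            class = "lethal_sim_config")
}

#' Closed-form survivor carrier fraction under a recessive lethal
#'
#' With pre-selection allele frequency q, zygotes are formed at
#' Hardy-Weinberg proportions and homozygotes die, so among survivors the
#' heterozygote (carrier) fraction is 2q/(1+q) and the allele frequency is
#' q/(1+q) -- exactly half the carrier fraction, since every surviving copy
#' of the allele sits in a heterozygote.
#'
#' @param q_pre pre-selection lethal-allele frequency in [0, 1).
#' @return List: \code{het_fraction}, \code{allele_frequency}.
#' @export
survivor_carrier_fraction <- function(q_pre) {
  stopifnot(q_pre >= 0, q_pre < 1)
  list(het_fraction = 2 * q_pre / (1 + q_pre),
       allele_frequency = q_pre / (1 + q_pre))
}

#' Simulate survivor genotypes under a recessive embryonic-lethal haplotype
#'
#' Survivors are drawn from the conditional zygote distribution given
#' survival: heterozygote with probability 2pq/(1-q^2) = 2q/(1+q), major
#' homozygote otherwise (minor homozygotes never survive, so every lethal
#' marker shows exactly zero minor homozygotes by construction). All
#' \code{n_lethal_snps} markers carry identical survivor genotypes (perfect
#' coupling) at adjacent positions on chromosome "6"; neutral SNPs are drawn
#' independently at Hardy-Weinberg equilibrium with minor-allele frequencies
#' from the configured uniform law, on chromosome "1". When
#' \code{recomb_fraction} is set, a partially linked marker (see
#' \code{\link{simulate_linked_marker}}) is appended downstream of the lethal
#' block, and the block carries the forward simulation's causal genotypes so
#' that block and marker are genuinely in LD.
#'
#' @param config a \code{\link{lethal_sim_config}}.
#' @return List: \code{matrix} (a \code{\link{genotype_matrix}}) and
#'   \code{truth} (lethal/linked variant ids and indices, realized survivor
#'   carrier fraction and allele frequency, neutral MAFs, config echo).
#' @export
simulate_lethal_population <- function(config = lethal_sim_config()) {
  with_seed(config$seed, {
    n <- config$n_samples
    q <- config$q_pre
    # with a linked marker, the lethal block must carry the forward
    # simulation's causal genotypes so that marker and block are actually
    # in LD; otherwise draw survivors from the conditional law directly
    linked <- NULL
    if (config$recomb_fraction > 0) {
      linked <- simulate_linked_marker(config)
      lethal_g <- linked$causal_genotypes     # in {0, 1} by viability
    } else {
      p_het <- if (q > 0) 2 * q / (1 + q) else 0
      lethal_g <- stats::rbinom(n, 1, p_het)  # 0 = major hom, 1 = het
    }

    lethal_pos <- 38278097L + cumsum(c(0L, rep(777L, config$n_lethal_snps - 1)))
    blocks <- list()
    vars <- list()
    vars$lethal <- data.frame(
      chrom = "6", pos = lethal_pos,
      id = sprintf("lethal_%d", seq_len(config$n_lethal_snps)),
      allele_A = "A", allele_B = "G", stringsAsFactors = FALSE)
    blocks$lethal <- matrix(rep(lethal_g, config$n_lethal_snps), nrow = n)

    mafs <- NULL
    if (config$n_neutral > 0) {
      mafs <- stats::runif(config$n_neutral, config$neutral_maf_range[1],
                           config$neutral_maf_range[2])
      blocks$neutral <- vapply(mafs, function(f) stats::rbinom(n, 2, f),
                               integer(n))
      vars$neutral <- data.frame(
        chrom = "1", pos = 10000L * seq_len(config$n_neutral),
        id = sprintf("neutral_%d", seq_len(config$n_neutral)),
        allele_A = "A", allele_B = "C", stringsAsFactors = FALSE)
    }

    linked_truth <- NULL
    if (!is.null(linked)) {
      blocks$linked <- matrix(linked$genotypes, nrow = n)
      vars$linked <- data.frame(
        chrom = "6", pos = max(lethal_pos) + 50000L, id = "linked_marker",
        allele_A = "A", allele_B = "T", stringsAsFactors = FALSE)
      linked_truth <- linked$truth
    }

    variants <- do.call(rbind, vars)
    calls <- do.call(cbind, blocks)
    storage.mode(calls) <- "integer"
    samples <- sprintf("sim_%05d", seq_len(n))
    mat <- genotype_matrix(variants, samples, calls)

    truth <- list(
      lethal_ids = vars$lethal$id,
      lethal_idx = match(vars$lethal$id, mat$variants$id),
      linked_id = if (!is.null(linked_truth)) "linked_marker" else NULL,
      carrier_fraction = mean(lethal_g),
      allele_frequency = mean(lethal_g) / 2,
      neutral_mafs = mafs,
      linked = linked_truth,
      config = config)
    list(matrix = mat, truth = truth)
  })
}

#' Forward-simulate a marker partially linked to the lethal locus
#'
#' Discrete non-overlapping generations of random mating in a population of
#' \code{n_pop} diploids. Haplotypes carry (causal allele, marker allele);
#' generation 0 starts in perfect coupling at frequency \code{q_pre}. Each
#' gamete recombines the two loci with probability \code{recomb_fraction};
#' causal-homozygote zygotes die and are re-drawn. The pre-selection zygote
#' frequency of the causal allele is held at \code{q_pre} every generation
#' (gametes are drawn stratified on the causal allele), modelling a haplotype
#' maintained at its observed frequency over the recent past -- complete
#' lethal selection alone would otherwise drive the frequency down as
#' q/(1+q) per generation and extinguish the signal the simulator exists to
#' exhibit. Because recombination moves the marker allele onto wild-type
#' causal backgrounds, the emitted marker column can show minor homozygotes
#' even though the causal column never does.
#'
#' @param config a \code{\link{lethal_sim_config}} (uses q_pre,
#'   recomb_fraction, n_generations, n_pop, n_samples; the caller controls
#'   the RNG state).
#' @return List: \code{genotypes} (marker codes for n_samples survivors),
#'   \code{causal_genotypes}, \code{truth} (marker minor-homozygote count,
#'   marker allele frequency, realized generations).
#' @export
simulate_linked_marker <- function(config) {
  N <- max(config$n_pop, config$n_samples)
  q <- config$q_pre
  cfrac <- config$recomb_fraction
  draw_hap <- function(k) {
    lethal <- stats::rbinom(k, 1, q)
    rbind(causal = lethal, marker = lethal)  # perfect coupling at g0
  }
  h1 <- draw_hap(N); h2 <- draw_hap(N)
  dead <- h1["causal", ] == 1 & h2["causal", ] == 1
  while (any(dead)) {
    k <- sum(dead)
    h1[, dead] <- draw_hap(k); h2[, dead] <- draw_hap(k)
    dead <- h1["causal", ] == 1 & h2["causal", ] == 1
  }
  # one gamete from each of k random parents, with recombination
  gamete_batch <- function(k) {
    idx <- sample.int(N, k, replace = TRUE)
    pick1 <- stats::rbinom(k, 1, 0.5) == 1
    rec <- stats::rbinom(k, 1, cfrac) == 1
    causal <- ifelse(pick1, h1["causal", idx], h2["causal", idx])
    marker_same <- ifelse(pick1, h1["marker", idx], h2["marker", idx])
    marker_other <- ifelse(pick1, h2["marker", idx], h1["marker", idx])
    rbind(causal = causal, marker = ifelse(rec, marker_other, marker_same))
  }
  # draw `k` gametes whose causal allele equals `s` by rejection
  gamete_stratum <- function(k, s) {
    out <- matrix(0L, 2, 0)
    tries <- 0
    while (ncol(out) < k) {
      tries <- tries + 1
      if (tries > 1000)
        stop("causal allele lost from the breeding population")
      g <- gamete_batch(max(2L * k, 64L))
      out <- cbind(out, g[, g["causal", ] == s, drop = FALSE])
    }
    out[, seq_len(k), drop = FALSE]
  }
  for (gen in seq_len(config$n_generations)) {
    # zygote causal genotypes at HWE with frequency q, conditioned viable
    z1 <- stats::rbinom(N, 1, q); z2 <- stats::rbinom(N, 1, q)
    both <- z1 == 1 & z2 == 1
    while (any(both)) {
      k <- sum(both)
      z1[both] <- stats::rbinom(k, 1, q); z2[both] <- stats::rbinom(k, 1, q)
      both <- z1 == 1 & z2 == 1
    }
    pool1 <- if (any(c(z1, z2) == 1))
      gamete_stratum(sum(z1) + sum(z2), 1L) else matrix(0L, 2, 0)
    pool0 <- gamete_stratum(sum(z1 == 0) + sum(z2 == 0), 0L)
    new1 <- matrix(0L, 2, N, dimnames = list(c("causal", "marker"), NULL))
    new2 <- new1
    new1[, z1 == 1] <- pool1[, seq_len(sum(z1)), drop = FALSE]
    new2[, z2 == 1] <- pool1[, sum(z1) + seq_len(sum(z2)), drop = FALSE]
    new1[, z1 == 0] <- pool0[, seq_len(sum(z1 == 0)), drop = FALSE]
    new2[, z2 == 0] <- pool0[, sum(z1 == 0) + seq_len(sum(z2 == 0)),
                             drop = FALSE]
    h1 <- new1; h2 <- new2
  }
  idx <- sample.int(N, config$n_samples, replace = config$n_samples > N)
  marker_g <- h1["marker", idx] + h2["marker", idx]
  causal_g <- h1["causal", idx] + h2["causal", idx]
  list(genotypes = as.integer(marker_g),
       causal_genotypes = as.integer(causal_g),
       truth = list(marker_minor_hom = sum(marker_g == 2L),
                    marker_allele_freq = mean(marker_g) / 2,
                    n_generations = config$n_generations))
}

#' Simulate two-channel array intensities for given genotype calls
#'
#' Each sample's (x, y) is drawn from its genotype's intensity cluster: the
#' contrast coordinate theta from a Gaussian around the per-genotype centre,
#' the signal radius r around \code{r_mean}, then x = r cos(theta pi/2),
#' y = r sin(theta pi/2) (truncated at 0). A \code{miscall_rate} fraction of
#' samples additionally get their *call* corrupted to a different genotype,
#' so the returned called genotypes disagree with the intensity cluster for
#' exactly those samples; the truth records which.
#'
#' @param genotypes integer true genotype codes 0/1/2 (no NA).
#' @param config a \code{\link{lethal_sim_config}} (intensity model + seed).
#' @param variant optional one-row variant data.frame (defaults to the first
#'   lethal marker definition).
#' @return List: \code{panel} (an \code{\link{intensity_panel}}),
#'   \code{called} (genotype codes with miscalls injected), \code{truth}
#'   (true codes, miscalled sample indices).
#' @export
simulate_intensities <- function(genotypes, config = lethal_sim_config(),
                                 variant = NULL) {
  stopifnot(all(genotypes %in% 0:2))
  im <- config$intensity
  if (is.null(variant))
    variant <- data.frame(chrom = "6", pos = 38278097L, id = "lethal_1",
                          allele_A = "A", allele_B = "G",
                          stringsAsFactors = FALSE)
  with_seed(config$seed + 104729L, {
    n <- length(genotypes)
    # truncated normal on [0, 1]: rejection keeps the clusters Gaussian
    # without a point mass at the boundaries
    theta <- stats::rnorm(n, im$theta_means[genotypes + 1L], im$theta_sd)
    bad <- which(theta < 0 | theta > 1)
    while (length(bad) > 0) {
      theta[bad] <- stats::rnorm(length(bad),
                                 im$theta_means[genotypes[bad] + 1L],
                                 im$theta_sd)
      bad <- bad[theta[bad] < 0 | theta[bad] > 1]
    }
    r <- pmax(stats::rnorm(n, im$r_mean, im$r_sd), 1e-3)
    x <- r * cos(theta * pi / 2)
    y <- r * sin(theta * pi / 2)
    called <- genotypes
    miscalled <- integer()
    if (im$miscall_rate > 0) {
      miscalled <- which(stats::runif(n) < im$miscall_rate)
      for (i in miscalled)
        called[i] <- sample(setdiff(0:2, genotypes[i]), 1)
    }
    list(panel = intensity_panel(variant,
                                 sprintf("sim_%05d", seq_len(n)), x, y),
         called = as.integer(called),
         truth = list(true_genotypes = as.integer(genotypes),
                      miscalled = miscalled))
  })
}

#' Monte-Carlo power of the deficit scan against a planted lethal block
#'
#' Replicates the full scan-and-cluster analysis on simulated survivor
#' cohorts: each replicate plants a two-SNP lethal block (pre-selection
#' frequency \code{q_pre}) among \code{n_neutral} neutral SNPs, runs
#' \code{\link{scan_deficit}} + \code{\link{cluster_adjacent}}, and records
#' whether a block containing all planted markers was found. The per-variant
#' neutral false-positive rate is the fraction of neutral SNPs with raw exact
#' p < alpha. Binomial standard errors are reported for both rates.
#'
#' @param n survivors per replicate.
#' @param q_pre pre-selection lethal-haplotype frequency.
#' @param alpha significance level.
#' @param n_reps number of replicates (>= 100).
#' @param seed master seed; replicate r uses seed + r.
#' @param n_neutral neutral SNPs per replicate (default 5000).
#' @param config scan configuration (alpha is overridden).
#' @return List: power, power_se, fp_rate, fp_se, n_reps.
#' @export
power_estimate <- function(n, q_pre, alpha = 0.05, n_reps = 200, seed = 1,
                           n_neutral = 5000, config = NULL) {
  stopifnot(n_reps >= 100)
  if (is.null(config)) config <- scan_config(alpha = alpha)
  hits <- logical(n_reps)
  fp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_lethal_population(lethal_sim_config(
      n_samples = n, q_pre = q_pre, n_neutral = n_neutral,
      seed = seed + r))
    res <- scan_deficit(sim$matrix, config)
    blocks <- cluster_adjacent(res, config)
    planted <- sim$truth$lethal_ids
    hits[r] <- any(vapply(strsplit(blocks$member_ids, ","), function(ids)
      all(planted %in% ids), TRUE))
    neutral <- grepl("^neutral_", res$id) & res$tested
    fp[r] <- if (any(neutral)) mean(res$p_hwe[neutral] < alpha) else 0
  }
  power <- mean(hits)
  fp_rate <- mean(fp)
  list(power = power,
       power_se = sqrt(power * (1 - power) / n_reps),
       fp_rate = fp_rate,
       fp_se = stats::sd(fp) / sqrt(n_reps),
       n_reps = n_reps)
}
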