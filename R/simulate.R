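#' Configuration for the two-population synthetic study
#'
#' The generator emulates the structure the RA theory assumes: two
#' populations diverged by a target Hudson F_ST, within-population LD
#' decaying with distance and differing between populations, MAF spectra
#' differing between populations, causal effects with
#' `var(beta) ~ [2 p (1 - p)]^S` per population and cross-population
#' correlation `rho_b`, and phenotypes `y = g + e` with unit variance
#' and per-population heritability.
#'
#' Genotypes are drawn from a two-stage block-mosaic model. Stage 1
#' draws, for each block, a pool of `pool_size` ancestral haplotypes
#' whose alleles follow a first-order Markov chain along variants
#' (adjacent-variant correlation `pool_step_r`), giving plateau-like
#' within-block LD. Stage 2 creates each population by Balding-Nichols
#' drift of the block haplotype-pool frequencies (Dirichlet, drift
#' parameter calibrated to `target_fst`) and by a population-specific
#' mosaic switch rate: each individual haplotype is a mosaic of pool
#' haplotypes with per-step switch probability `switch_rate` in
#' population 1 and `switch_rate * (1 + ld_divergence * target_fst)` in
#' population 2, so both MAF and LD divergence are controlled by the
#' single `target_fst` knob and vanish together at `target_fst = 0`.
#'
#' @param n_variants total number of variants M.
#' @param n_blocks number of independent LD blocks (M divisible by it).
#' @param block_span_kb physical span of each block in kb.
#' @param target_fst target Hudson F_ST between the two populations.
#' @param n_discovery discovery (GWAS) sample size, population 1.
#' @param n_targets named integer vector of additional cohort sizes.
#' @param target_ancestry named integer vector (1 or 2) giving, for each
#'   cohort in `n_targets`, the population whose parameters it is drawn
#'   from. Cohorts of ancestry 1 are independent same-ancestry samples
#'   (validation / reference); ancestry 2 is the transfer target.
#' @param m_causal number of causal variants M_C.
#' @param h2 heritability per population; scalar or named
#'   `c(pop1 = , pop2 = )`.
#' @param S selection exponent per population (`var(beta)` proportional
#'   to `[2p(1-p)]^S`); scalar or named vector. `S = -1` gives each
#'   causal variant equal expected explained variance.
#' @param rho_b cross-population correlation of causal effect sizes.
#' @param maf_floor minimum per-population MAF retained after
#'   simulation.
#' @param pool_size number of ancestral haplotypes per block.
#' @param pool_step_r Markov correlation between adjacent variants
#'   within a pool haplotype.
#' @param switch_rate per-variant-step mosaic switch (recombination)
#'   probability in population 1.
#' @param ld_divergence coupling of LD divergence to `target_fst` (see
#'   Details).
#' @param ancestral_maf_range range of the uniform ancestral allele
#'   frequency.
#' @param seed integer seed; identical configs give identical output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 10000L,
                       n_blocks = 100L,
                       block_span_kb = 500,
                       target_fst = 0.10,
                       n_discovery = 10000L,
                       n_targets = c(validation = 2000L, target = 2000L),
                       target_ancestry = c(validation = 1L, target = 2L),
                       m_causal = 200L,
                       h2 = 0.5,
                       S = -1,
                       rho_b = 1,
                       maf_floor = 0.01,
                       pool_size = 20L,
                       pool_step_r = 0.97,
                       switch_rate = 0.06,
                       ld_divergence = 7,
                       ancestral_maf_range = c(0.05, 0.5),
                       seed = 1L) {
  if (length(h2) == 1) h2 <- c(pop1 = unname(h2), pop2 = unname(h2))
  if (length(S) == 1) S <- c(pop1 = unname(S), pop2 = unname(S))
  stopifnot(
    n_variants %% n_blocks == 0,
    all(h2 > 0), all(h2 <= 1),
    abs(rho_b) <= 1,
    m_causal < n_variants,
    maf_floor >= 0,
    pool_size >= 2,
    pool_step_r >= 0, pool_step_r < 1,
    switch_rate > 0, switch_rate <= 1
  )
  if (target_fst < 0 || target_fst >= 0.5) {
    stop("target_fst must be in [0, 0.5): Balding-Nichols drift of ",
         target_fst, " is not attainable with this block structure")
  }
  if (is.null(names(n_targets)) || is.null(names(target_ancestry)) ||
      !setequal(names(n_targets), names(target_ancestry))) {
    stop("n_targets and target_ancestry must share the same cohort names")
  }
  if (!all(target_ancestry %in% c(1L, 2L))) stop("target_ancestry values must be 1 or 2")
  structure(
    list(n_variants = as.integer(n_variants), n_blocks = as.integer(n_blocks),
         block_span_kb = block_span_kb, target_fst = target_fst,
         n_discovery = as.integer(n_discovery),
         n_targets = n_targets, target_ancestry = target_ancestry,
         m_causal = as.integer(m_causal), h2 = h2, S = S, rho_b = rho_b,
         maf_floor = maf_floor, pool_size = as.integer(pool_size),
         pool_step_r = pool_step_r, switch_rate = switch_rate,
         ld_divergence = ld_divergence,
         ancestral_maf_range = ancestral_maf_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation config from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("n_targets", "target_ancestry", "h2", "S")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(sim_config, args)
}

# Fixed drift calibration: the MAF floor preferentially removes
# high-divergence variants, slightly attenuating realized F_ST at the
# default floor; the Balding-Nichols parameter is inflated accordingly.
FST_DRIFT_CALIBRATION <- 1.02

# Population haplotype-pool parameters shared by all cohorts of a
# replicate: the ancestral pool, per-population pool weights (drifted)
# and per-population mosaic switch rates.
sim_population_params <- function(config) {
  m <- config$n_variants
  H <- config$pool_size
  per_block <- m %/% config$n_blocks
  # ancestral frequency is a block-level quantity (variants on one
  # haplotype background share it); variant-level MAF spread arises
  # from finite-pool sampling and from drift of the pool weights
  q <- rep(stats::runif(config$n_blocks, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2]), each = per_block)

  # Stage 1: ancestral pool haplotypes, first-order Markov along each
  # block with marginal q_j and adjacent correlation pool_step_r
  pool <- matrix(0L, nrow = H, ncol = m)
  rho <- config$pool_step_r
  for (j in seq_len(m)) {
    first <- (j - 1L) %% per_block == 0L
    if (first) {
      pool[, j] <- as.integer(stats::runif(H) < q[j])
    } else {
      q0 <- q[j - 1]; q1 <- q[j]
      cv <- rho * sqrt(q0 * (1 - q0) * q1 * (1 - q1))
      p_on <- pmin(pmax(q1 + cv / q0, 0), 1)
      p_off <- pmin(pmax(q1 - cv / (1 - q0), 0), 1)
      cond <- ifelse(pool[, j - 1] == 1L, p_on, p_off)
      pool[, j] <- as.integer(stats::runif(H) < cond)
    }
  }

  # Stage 2: Balding-Nichols drift of pool weights per block
  f <- config$target_fst * FST_DRIFT_CALIBRATION
  draw_weights <- function() {
    if (f == 0) return(matrix(1 / H, nrow = H, ncol = config$n_blocks))
    alpha <- (1 - f) / f / H
    w <- matrix(stats::rgamma(H * config$n_blocks, shape = alpha), nrow = H)
    sweep(w, 2, colSums(w), "/")
  }
  w1 <- draw_weights()
  w2 <- draw_weights()

  s1 <- config$switch_rate
  s2 <- min(1, s1 * (1 + config$ld_divergence * config$target_fst))
  list(pool = pool,
       weights = list(pop1 = w1, pop2 = w2),
       switch_rate = c(pop1 = s1, pop2 = s2))
}

# Variant map: blocks laid head-to-tail on one chromosome with 10x
# block-span gaps, positions 1-based and evenly spaced within blocks.
sim_variant_map <- function(config) {
  m <- config$n_variants
  per_block <- m %/% config$n_blocks
  span_bp <- round(config$block_span_kb * 1000)
  gap_bp <- 10 * span_bp
  step <- if (per_block > 1) span_bp / (per_block - 1) else 0
  block <- rep(seq_len(config$n_blocks), each = per_block)
  within <- rep(seq_len(per_block) - 1, times = config$n_blocks)
  bp <- as.integer(round((block - 1) * (span_bp + gap_bp) + 1 + within * step))
  tibble::tibble(
    variant_id = sprintf("snp_%05d", seq_len(m)),
    chromosome = "1",
    bp = bp,
    counted_allele = "A",
    other_allele = "B",
    block = block
  )
}

sim_panel_from_params <- function(n, params, pop, variant_map, label) {
  switch_prob <- rep(params$switch_rate[[pop]], nrow(variant_map))
  switch_prob[variant_map$within_first] <- 2  # forced restart at block starts
  wcum <- apply(params$weights[[pop]], 2, cumsum)
  geno <- sim_mosaic_genotypes(n, params$pool, wcum, switch_prob,
                               variant_map$block)
  genotype_panel(geno,
                 variant_map[, c("variant_id", "chromosome", "bp",
                                 "counted_allele", "other_allele")],
                 sample_ids = sprintf("%s_%d", label, seq_len(n)),
                 population_label = label, validate = FALSE)
}

#' Simulate the two-population genotype study
#'
#' Draws one replicate of the synthetic study: population frequency and
#' LD parameters, then a discovery cohort from population 1 and one
#' cohort per entry of `config$n_targets` from the population given by
#' `config$target_ancestry`. Variants failing the per-population MAF
#' floor (in any emitted cohort) are removed from all panels, and all
#' panels are oriented so the counted allele is the minor allele in the
#' discovery cohort.
#'
#' @param config a [sim_config()].
#' @return A named list of [genotype_panel()]s (`discovery` first), with
#'   attribute `true_freqs` holding the per-population parameter
#'   frequencies of the retained variants.
#' @export
simulate_two_populations <- function(config) {
  set.seed(config$seed)
  params <- sim_population_params(config)
  vmap <- sim_variant_map(config)
  vmap$within_first <- c(TRUE, diff(vmap$block) != 0)

  panels <- list()
  panels$discovery <- sim_panel_from_params(
    config$n_discovery, params, "pop1", vmap, "discovery")
  for (nm in names(config$n_targets)) {
    anc <- if (config$target_ancestry[[nm]] == 1L) "pop1" else "pop2"
    panels[[nm]] <- sim_panel_from_params(
      config$n_targets[[nm]], params, anc, vmap, nm)
  }

  # per-population MAF floor over every emitted cohort
  raw_freqs <- lapply(panels, function(panel) col_freqs(panel$genotypes))
  keep <- rep(TRUE, config$n_variants)
  for (cf in raw_freqs) {
    keep <- keep & !is.na(cf$p) & pmin(cf$p, 1 - cf$p) >= config$maf_floor
  }
  if (!any(keep)) {
    stop("no variants pass the MAF floor of ", config$maf_floor,
         "; target_fst = ", config$target_fst,
         " may be unattainable with this block structure")
  }
  keep_idx <- which(keep)

  # orient every panel to the discovery minor allele; filter and flip
  # in a single pass per panel
  flip <- raw_freqs$discovery$p[keep_idx] > 0.5
  panels <- purrr::imap(panels, function(panel, nm) {
    panel$genotypes <- subset_flip(panel$genotypes, keep_idx, flip)
    panel$variants <- panel$variants[keep_idx, ]
    tmp <- panel$variants$counted_allele[flip]
    panel$variants$counted_allele[flip] <- panel$variants$other_allele[flip]
    panel$variants$other_allele[flip] <- tmp
    dimnames(panel$genotypes) <- list(panel$sample_ids, panel$variants$variant_id)
    p <- raw_freqs[[nm]]$p[keep_idx]
    p <- ifelse(flip, 1 - p, p)
    attr(panel, "freqs") <- tibble::tibble(
      variant_id = panel$variants$variant_id,
      p = p,
      het = 2 * p * (1 - p),
      n_obs = raw_freqs[[nm]]$n_obs[keep_idx]
    )
    panel
  })

  pop_freq <- function(pop) {
    w <- params$weights[[pop]]
    vapply(keep_idx, function(j) {
      sum(w[, vmap$block[j]] * params$pool[, j])
    }, numeric(1))
  }
  p1 <- pop_freq("pop1"); p2 <- pop_freq("pop2")
  tf <- tibble::tibble(
    variant_id = vmap$variant_id[keep_idx],
    p_pop1 = ifelse(flip, 1 - p1, p1),
    p_pop2 = ifelse(flip, 1 - p2, p2)
  )
  attr(panels, "true_freqs") <- tf
  panels
}

#' Sample causal effect sizes under the selection model
#'
#' Draws `m_causal` causal variants (uniformly among variants passing
#' the MAF floor in both populations) and per-population effects from a
#' bivariate normal with correlation `rho_b` and marginal variance
#' `sigma_l^2 [2 p_jl (1 - p_jl)]^(S_l)`, where `sigma_l^2` is set so
#' the expected total explained variance `sum_j 2 p_jl (1-p_jl)
#' beta_jl^2` equals `h_l^2`. At `S = -1` this is the
#' equal-variance-per-causal model `var(beta) = h^2 / (2 p (1-p) M_C)`.
#'
#' @param freqs1,freqs2 tibbles with `variant_id` and `p` (counted-allele
#'   frequency) in populations 1 and 2, e.g. from
#'   [allele_frequencies()]; rows define the candidate causal pool.
#' @param config a [sim_config()] (uses `m_causal`, `h2`, `S`, `rho_b`,
#'   `maf_floor`).
#' @return A tibble with columns `variant_id`, `beta1`, `beta2`, `p1`,
#'   `p2` (effects in trait-SD units per counted allele).
#' @export
sample_causal_effects <- function(freqs1, freqs2, config) {
  pool <- dplyr::inner_join(
    dplyr::select(freqs1, "variant_id", p1 = "p"),
    dplyr::select(freqs2, "variant_id", p2 = "p"),
    by = "variant_id"
  )
  pool <- dplyr::filter(
    pool,
    pmin(.data$p1, 1 - .data$p1) >= config$maf_floor,
    pmin(.data$p2, 1 - .data$p2) >= config$maf_floor
  )
  if (nrow(pool) < config$m_causal) {
    stop("only ", nrow(pool), " variants polymorphic in both populations; ",
         config$m_causal, " causal variants requested")
  }
  causal <- pool[sort(sample.int(nrow(pool), config$m_causal)), ]

  het1 <- 2 * causal$p1 * (1 - causal$p1)
  het2 <- 2 * causal$p2 * (1 - causal$p2)
  s1 <- config$S[["pop1"]]
  s2 <- config$S[["pop2"]]
  sigma1 <- config$h2[["pop1"]] / sum(het1^(s1 + 1))
  sigma2 <- config$h2[["pop2"]] / sum(het2^(s2 + 1))
  sd1 <- sqrt(sigma1 * het1^s1)
  sd2 <- sqrt(sigma2 * het2^s2)

  z1 <- stats::rnorm(config$m_causal)
  rho <- config$rho_b
  z2 <- if (abs(rho) == 1) sign(rho) * z1
        else rho * z1 + sqrt(1 - rho^2) * stats::rnorm(config$m_causal)
  tibble::tibble(
    variant_id = causal$variant_id,
    beta1 = sd1 * z1,
    beta2 = sd2 * z2,
    p1 = causal$p1,
    p2 = causal$p2
  )
}

#' Simulate a phenotype from a panel and causal effects
#'
#' `y = g + e` with `g = sum_j x_j beta_j` over the causal variants and
#' `e ~ N(0, 1 - h2)`, so `var(y)` is approximately 1 and
#' `var(g)/var(y)` approximately `h2`.
#'
#' @param panel a [genotype_panel()].
#' @param effects effect table from [sample_causal_effects()].
#' @param beta_col which effect column applies to this panel's
#'   population (`"beta1"` or `"beta2"`).
#' @param h2 heritability in `(0, 1]`.
#' @param seed integer seed for the environmental draw.
#' @return A tibble with columns `sample_id`, `y`, `g`,
#'   `population_label`.
#' @export
simulate_phenotype <- function(panel, effects, beta_col = "beta1", h2, seed) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  idx <- variant_index(panel, effects$variant_id)
  x <- panel$genotypes[, idx, drop = FALSE]
  g <- as.vector(x %*% effects[[beta_col]])
  set.seed(seed)
  e <- if (h2 == 1) numeric(length(g))
       else stats::rnorm(length(g), 0, sqrt(1 - h2))
  tibble::tibble(
    sample_id = panel$sample_ids,
    y = g + e,
    g = g,
    population_label = panel$population_label
  )
}
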