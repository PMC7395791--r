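# Build a small panel from a dosage matrix (samples x variants),
# evenly spaced on one chromosome unless bp is given.
make_panel <- function(genotypes, bp = NULL, chromosome = NULL,
                       counted = NULL, other = NULL, label = "test",
                       ids = NULL) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  if (is.null(chromosome)) chromosome <- rep("1", m)
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(m))
  if (is.null(counted)) counted <- rep("A", m)
  if (is.null(other)) other <- rep("B", m)
  genotype_panel(
    genotypes,
    tibble::tibble(variant_id = ids, chromosome = chromosome, bp = as.integer(bp),
                   counted_allele = counted, other_allele = other),
    population_label = label
  )
}

# Random polymorphic panel for property-style tests.
random_panel <- function(n, m, seed, maf = 0.3, label = "rand") {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2, maf), nrow = n)
  # ensure polymorphic columns
  for (j in seq_len(m)) {
    if (length(unique(g[, j])) == 1) g[1, j] <- (g[1, j] + 1L) %% 3L
  }
  make_panel(g, label = label)
}

# Small-scale study config used across pipeline tests: enough power for
# tens of GWS SNPs in seconds.
small_study_config <- function(seed = 1, ...) {
  args <- list(
    n_variants = 2000L, n_blocks = 20L, block_span_kb = 500,
    target_fst = 0.10, n_discovery = 4000L,
    n_targets = c(validation = 1000L, target = 1000L),
    target_ancestry = c(validation = 1L, target = 2L),
    m_causal = 50L, h2 = 0.5, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

expect_tibble_cols <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% names(x)))
}
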