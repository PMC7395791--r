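#' Discovery GWAS by per-variant simple linear regression
#'
#' Ordinary least squares of the phenotype on the counted-allele dosage
#' (with intercept), one variant at a time: `beta_hat = cov(x, y) /
#' var(x)`, standard error and two-sided p-value from the t statistic
#' with `n - 2` degrees of freedom. Variants listed in `exclude_ids`
#' (e.g. the true causal variants in simulations) are left out of the
#' output; monomorphic variants are skipped with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param pheno phenotype tibble from [simulate_phenotype()] (or any
#'   table with `sample_id`, `y`) aligned to the panel samples.
#' @param exclude_ids variant ids to exclude from testing.
#' @return Summary-statistics tibble with columns `variant_id`,
#'   `chromosome`, `bp`, `counted_allele`, `other_allele`, `beta_hat`,
#'   `se`, `p_value`, `n`.
#' @export
run_gwas <- function(panel, pheno, exclude_ids = character()) {
  idx <- match(panel$sample_ids, pheno$sample_id)
  if (anyNA(idx)) stop("phenotype is missing sample(s) present in the panel")
  y <- pheno$y[idx]
  bad_excl <- setdiff(exclude_ids, panel$variants$variant_id)
  if (length(bad_excl) > 0) {
    stop("exclude_ids not in panel: ", paste(bad_excl, collapse = ", "))
  }
  keep <- !(panel$variants$variant_id %in% exclude_ids)
  fit <- gwas_ols(panel$genotypes[, keep, drop = FALSE], y)
  out <- dplyr::bind_cols(
    panel$variants[keep, c("variant_id", "chromosome", "bp",
                           "counted_allele", "other_allele")],
    tibble::tibble(
      beta_hat = fit$beta,
      se = fit$se,
      p_value = 2 * stats::pt(-abs(fit$t), df = fit$df),
      n = fit$df + 2L
    )
  )
  mono <- is.na(out$beta_hat)
  if (any(mono)) {
    warning("skipping ", sum(mono), " monomorphic variant(s)")
    out <- out[!mono, ]
  }
  out
}

#' Clumping parameters
#'
#' Defaults follow the stringent genome-wide-significance clumping used
#' for defining quasi-independent PGS SNPs: index and secondary p-value
#' thresholds 5e-8, 2000 kb window, r-squared ceiling 0.01.
#'
#' @param p1 index-SNP p-value threshold.
#' @param p2 secondary p-value threshold (`p1 <= p2`).
#' @param window_kb physical clumping window, kb.
#' @param r2_max LD r-squared above which a secondary SNP is absorbed.
#' @return A `clump_params` list.
#' @export
clump_params <- function(p1 = 5e-8, p2 = 5e-8, window_kb = 2000, r2_max = 0.01) {
  stopifnot(p1 <= p2, r2_max > 0, r2_max < 1, window_kb > 0)
  structure(list(p1 = p1, p2 = p2, window_kb = window_kb, r2_max = r2_max),
            class = "clump_params")
}

#' Greedy PLINK-style LD clumping
#'
#' Repeatedly takes the smallest-p remaining variant with `p <= p1` as
#' an index SNP and removes all remaining variants with `p <= p2`,
#' within `window_kb` on the same chromosome, and LD `r^2 > r2_max` with
#' it (r computed in `ld_panel`, the discovery panel). Ties on p-value
#' are broken by (chromosome, bp) order, so the output is invariant to
#' input row order. The result is the PGS SNP set: index SNPs with
#' their discovery weights.
#'
#' @param sumstats summary statistics from [run_gwas()].
#' @param ld_panel [genotype_panel()] used as LD reference.
#' @param params a [clump_params()].
#' @return Tibble of index SNPs in selection order, columns
#'   `variant_id`, `chromosome`, `bp`, `counted_allele`, `beta_hat`,
#'   `p_value`; possibly zero rows.
#' @export
clump <- function(sumstats, ld_panel, params = clump_params()) {
  missing_ids <- setdiff(sumstats$variant_id, ld_panel$variants$variant_id)
  if (length(missing_ids) > 0) {
    stop("sumstats variant(s) absent from LD panel: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  cand <- sumstats[sumstats$p_value <= params$p2, ]
  cand <- cand[order(cand$p_value, cand$chromosome, cand$bp), ]
  out <- list()
  while (nrow(cand) > 0) {
    if (cand$p_value[1] > params$p1) break
    index <- cand[1, ]
    out[[length(out) + 1]] <- index
    cand <- cand[-1, ]
    if (nrow(cand) == 0) break
    near <- cand$chromosome == index$chromosome &
      abs(cand$bp - index$bp) <= params$window_kb * 1000
    if (any(near)) {
      xi <- ld_panel$genotypes[, variant_index(ld_panel, index$variant_id)]
      xn <- ld_panel$genotypes[, variant_index(ld_panel, cand$variant_id[near]),
                               drop = FALSE]
      r <- suppressWarnings(
        as.vector(stats::cor(xi, xn, use = "pairwise.complete.obs")))
      drop <- rep(FALSE, nrow(cand))
      drop[near] <- !is.na(r) & r^2 > params$r2_max
      cand <- cand[!drop, ]
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(variant_id = character(), chromosome = character(),
                          bp = integer(), counted_allele = character(),
                          beta_hat = numeric(), p_value = numeric()))
  }
  res <- dplyr::bind_rows(out)
  res[, c("variant_id", "chromosome", "bp", "counted_allele",
          "beta_hat", "p_value")]
}
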