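#' Score a PGS in a genotype panel
#'
#' `score_i = sum_k x_ik beta_hat_k` over the PGS SNPs, after aligning
#' each SNP's counted allele to the panel orientation (a SNP whose
#' counted allele is the panel's other allele contributes
#' `(2 - x) beta_hat`). Missing genotypes are imputed as twice the panel
#' frequency of the scored allele, keeping score variance comparable
#' across samples. Every PGS SNP must be present in the panel.
#'
#' @param panel a [genotype_panel()].
#' @param pgs PGS SNP set from [clump()] (needs `variant_id`,
#'   `counted_allele`, `beta_hat`).
#' @return A tibble with columns `sample_id`, `score`.
#' @export
score_pgs <- function(panel, pgs) {
  missing_ids <- setdiff(pgs$variant_id, panel$variants$variant_id)
  if (length(missing_ids) > 0) {
    stop("PGS SNP(s) absent from panel: ", paste(missing_ids, collapse = ", "))
  }
  idx <- variant_index(panel, pgs$variant_id)
  pv <- panel$variants[idx, ]
  aligned <- pv$counted_allele == pgs$counted_allele
  swapped <- pv$other_allele == pgs$counted_allele
  if (any(!aligned & !swapped)) {
    stop("allele mismatch (no strand resolution) for: ",
         paste(pgs$variant_id[!aligned & !swapped], collapse = ", "))
  }
  x <- panel$genotypes[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  if (any(swapped)) x[, swapped] <- 2 - x[, swapped]
  if (anyNA(x)) {
    pfreq <- colMeans(x, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- 2 * pfreq[j]
    }
  }
  tibble::tibble(
    sample_id = panel$sample_ids,
    score = as.vector(x %*% pgs$beta_hat)
  )
}

#' Observed prediction accuracy: squared correlation of score and trait
#'
#' @param scores score tibble from [score_pgs()] (or numeric vector).
#' @param pheno phenotype tibble with `sample_id`, `y` (or numeric
#'   vector in the same order as `scores`).
#' @return Squared Pearson correlation.
#' @export
observed_r2 <- function(scores, pheno) {
  if (is.data.frame(scores)) {
    if (is.data.frame(pheno)) {
      idx <- match(scores$sample_id, pheno$sample_id)
      if (anyNA(idx)) stop("phenotype missing for some scored samples")
      y <- pheno$y[idx]
    } else {
      y <- pheno
    }
    s <- scores$score
  } else {
    s <- scores
    y <- if (is.data.frame(pheno)) pheno$y else pheno
  }
  if (length(s) < 3) stop("need at least 3 samples")
  if (stats::var(s) == 0) stop("scores are constant; R^2 undefined")
  stats::cor(s, y)^2
}

#' Observed- to liability-scale R-squared (Lee transformation)
#'
#' With population prevalence `K` and sample case proportion `P`:
#' `t = qnorm(1 - K)`, `z = dnorm(t)`, `m = z / K`,
#' `C = K^2 (1 - K)^2 / (z^2 P (1 - P))`,
#' `theta = m (P - K)/(1 - K) * (m (P - K)/(1 - K) - t)`;
#' the liability-scale value is `r2 * C / (1 + r2 * theta)`. For a
#' population-based sample (`P = K`) this reduces to
#' `r2 * K (1 - K) / z^2`.
#'
#' @param r2_obs observed-scale R-squared.
#' @param K population prevalence, in (0, 1).
#' @param P sample case proportion, in (0, 1); defaults to `K`.
#' @return Liability-scale R-squared.
#' @export
liability_r2 <- function(r2_obs, K, P = K) {
  if (K <= 0 || K >= 1) stop("K must be in (0, 1)")
  if (P <= 0 || P >= 1) stop("P must be in (0, 1)")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  u <- m * (P - K) / (1 - K)
  theta <- u * (u - t)
  r2_obs * C / (1 + r2_obs * theta)
}

#' Observed relative accuracy with bootstrap standard error
#'
#' `RA = R2_target / R2_ref`, the ratio of the PGS accuracy in the
#' target-ancestry sample over that in an independent sample of the
#' discovery ancestry. The standard error is a nonparametric bootstrap
#' over individuals, resampling the two cohorts independently and
#' recomputing the ratio of squared correlations.
#'
#' @param target,ref data frames with columns `score` and `y`, one row
#'   per individual, for the target and reference cohorts.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param scale `"observed"` or `"liability"`; for `"liability"` supply
#'   `K_target`, `K_ref` (prevalences; case proportions are taken from
#'   the binary `y`).
#' @param K_target,K_ref population prevalences for the liability scale.
#' @return An `ra_observation`: fields `r2_ref`, `r2_target`, `ra`,
#'   `se_ra`, `scale`.
#' @export
relative_accuracy <- function(target, ref, n_boot = 1000, seed = 1,
                              scale = c("observed", "liability"),
                              K_target = NULL, K_ref = NULL) {
  scale <- match.arg(scale)
  one_r2 <- function(df, K) {
    r2 <- observed_r2(df$score, df$y)
    if (scale == "liability") {
      r2 <- liability_r2(r2, K = K, P = mean(df$y))
    }
    r2
  }
  r2_t <- one_r2(target, K_target)
  r2_r <- one_r2(ref, K_ref)
  if (r2_r <= 0) stop("reference R^2 is zero; RA undefined")
  ra <- r2_t / r2_r

  set.seed(seed)
  n_t <- nrow(target)
  n_r <- nrow(ref)
  boots <- vapply(seq_len(n_boot), function(b) {
    bt <- target[sample.int(n_t, replace = TRUE), ]
    br <- ref[sample.int(n_r, replace = TRUE), ]
    denom <- tryCatch(one_r2(br, K_ref), error = function(e) NA_real_)
    numer <- tryCatch(one_r2(bt, K_target), error = function(e) NA_real_)
    if (is.na(denom) || is.na(numer) || denom <= 0) NA_real_ else numer / denom
  }, numeric(1))
  structure(
    list(r2_ref = r2_r, r2_target = r2_t, ra = ra,
         se_ra = stats::sd(boots, na.rm = TRUE), scale = scale,
         n_boot = n_boot),
    class = "ra_observation"
  )
}

#' @export
#' @method print ra_observation
print.ra_observation <- function(x, ...) {
  cat(sprintf("<ra_observation> RA = %.4f (SE %.4f), %s scale; R2_ref = %.4f, R2_target = %.4f\n",
              x$ra, x$se_ra, x$scale, x$r2_ref, x$r2_target))
  invisible(x)
}

#' Loss of accuracy and the proportion explained by LD and MAF
#'
#' `LOA = (1 - RA) x 100%`; the proportion of the observed loss
#' explained by the prediction is `LOA_pred / LOA_obs`. When bootstrap
#' cohorts are supplied (`target`, `ref` as in [relative_accuracy()]),
#' the SE of the proportion is propagated by resampling the observed RA
#' with the prediction held fixed.
#'
#' @param ra_obs observed relative accuracy (scalar or
#'   `ra_observation`).
#' @param ra_pred predicted relative accuracy (scalar or
#'   `ra_prediction`).
#' @param target,ref optional cohort data frames (`score`, `y`) for the
#'   bootstrap SE.
#' @param n_boot bootstrap replicates.
#' @param seed resampling seed.
#' @return A `loa_report` tibble row: `ra_obs`, `ra_pred`, `loa_obs`,
#'   `loa_pred`, `prop_explained` (percent, `NA` when `ra_obs >= 1`),
#'   `se_prop`.
#' @export
loa_explained <- function(ra_obs, ra_pred, target = NULL, ref = NULL,
                          n_boot = 1000, seed = 1) {
  if (inherits(ra_obs, "ra_observation")) ra_obs <- ra_obs$ra
  if (inherits(ra_pred, "ra_prediction")) ra_pred <- ra_pred$ra
  loa_obs <- (1 - ra_obs) * 100
  loa_pred <- (1 - ra_pred) * 100
  prop <- if (ra_obs < 1) 100 * (1 - ra_pred) / (1 - ra_obs) else NA_real_
  se_prop <- NA_real_
  if (!is.null(target) && !is.null(ref) && ra_obs < 1) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      bt <- target[sample.int(nrow(target), replace = TRUE), ]
      br <- ref[sample.int(nrow(ref), replace = TRUE), ]
      r2r <- tryCatch(observed_r2(br$score, br$y), error = function(e) NA_real_)
      r2t <- tryCatch(observed_r2(bt$score, bt$y), error = function(e) NA_real_)
      if (is.na(r2r) || is.na(r2t) || r2r <= 0) return(NA_real_)
      rb <- r2t / r2r
      if (rb >= 1) NA_real_ else 100 * (1 - ra_pred) / (1 - rb)
    }, numeric(1))
    se_prop <- stats::sd(boots, na.rm = TRUE)
  }
  tibble::new_tibble(
    tibble::tibble(ra_obs = ra_obs, ra_pred = ra_pred,
                   loa_obs = loa_obs, loa_pred = loa_pred,
                   prop_explained = prop, se_prop = se_prop),
    class = "loa_report"
  )
}
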