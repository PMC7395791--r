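new_candidate_causal_map <- function(pairs, mode) {
  summary <- pairs |>
    dplyr::group_by(.data$pgs_id) |>
    dplyr::summarise(
      n_candidates = dplyr::n(),
      sum_r1_sq = sum(.data$r1^2),
      sum_r1r2 = sum(.data$r1 * .data$r2),
      mean_r1_sq = mean(.data$r1^2),
      mean_r1r2 = mean(.data$r1 * .data$r2),
      fallback = all(.data$fallback),
      .groups = "drop"
    )
  structure(list(pairs = pairs, summary = summary, mode = mode),
            class = "candidate_causal_map")
}

#' @export
#' @method print candidate_causal_map
print.candidate_causal_map <- function(x, ...) {
  cat("<candidate_causal_map> mode =", x$mode, ";",
      nrow(x$summary), "PGS-SNPs,", nrow(x$pairs), "pairs",
      sprintf("(%d fallback)\n", sum(x$summary$fallback)))
  invisible(x)
}

pair_ld_both_panels <- function(pgs_id, cand_ids, ref1, ref2) {
  x1 <- ref1$genotypes[, variant_index(ref1, pgs_id)]
  x2 <- ref2$genotypes[, variant_index(ref2, pgs_id)]
  c1 <- ref1$genotypes[, variant_index(ref1, cand_ids), drop = FALSE]
  c2 <- ref2$genotypes[, variant_index(ref2, cand_ids), drop = FALSE]
  list(
    r1 = suppressWarnings(as.vector(stats::cor(x1, c1, use = "pairwise.complete.obs"))),
    r2 = suppressWarnings(as.vector(stats::cor(x2, c2, use = "pairwise.complete.obs")))
  )
}

#' Identify candidate causal variants for each PGS SNP
#'
#' In heuristic mode the unknown causal variant behind each PGS SNP is
#' stood in for by every reference variant within `window_kb` of it
#' whose LD r-squared with it exceeds `r2_min` in the identification
#' panel (`ref1`, the discovery-ancestry reference — GWS SNPs arise from
#' discovery LD). For the identified pairs the LD is then also computed
#' in the target-ancestry panel (`ref2`). A PGS SNP with no qualifying
#' neighbour falls back to itself as its own candidate (`r = 1` in both
#' panels).
#'
#' @param pgs_snps PGS SNP set from [clump()].
#' @param ref1 identification / discovery-ancestry reference panel.
#' @param ref2 target-ancestry reference panel.
#' @param window_kb physical half-window, kb (closed interval).
#' @param r2_min LD r-squared threshold for candidacy.
#' @return A `candidate_causal_map`.
#' @export
find_candidate_causals <- function(pgs_snps, ref1, ref2,
                                   window_kb = 100, r2_min = 0.45) {
  check_pgs_present(pgs_snps, ref1, ref2)
  pairs <- purrr::map_dfr(pgs_snps$variant_id, function(id) {
    w <- ld_window(ref1, id, window_kb, include_index = FALSE)
    w <- w[w$r^2 > r2_min, ]
    if (nrow(w) == 0) {
      return(tibble::tibble(pgs_id = id, causal_id = id, r1 = 1, r2 = 1,
                            dbp = 0, fallback = TRUE))
    }
    ld <- pair_ld_both_panels(id, w$id_b, ref1, ref2)
    tibble::tibble(pgs_id = id, causal_id = w$id_b,
                   r1 = w$r, r2 = ld$r2, dbp = w$dbp, fallback = FALSE)
  })
  new_candidate_causal_map(pairs, mode = "heuristic")
}

#' Map PGS SNPs to known causal variants (simulation mode)
#'
#' When the true causal variants are known, each PGS SNP is paired with
#' every causal variant within `window_kb` of it (no r-squared filter),
#' with LD computed in both reference panels. A PGS SNP with no causal
#' variant in its window falls back to itself with a warning.
#'
#' @inheritParams find_candidate_causals
#' @param causal_ids ids of the true causal variants.
#' @return A `candidate_causal_map`.
#' @export
build_known_causal_map <- function(pgs_snps, causal_ids, ref1, ref2,
                                   window_kb = 100) {
  check_pgs_present(pgs_snps, ref1, ref2)
  v <- ref1$variants
  causal <- v[v$variant_id %in% causal_ids, ]
  n_fallback <- 0L
  pairs <- purrr::map_dfr(seq_len(nrow(pgs_snps)), function(i) {
    id <- pgs_snps$variant_id[i]
    vi <- v[v$variant_id == id, ]
    near <- causal[causal$chromosome == vi$chromosome &
                   abs(causal$bp - vi$bp) <= window_kb * 1000, ]
    if (nrow(near) == 0) {
      n_fallback <<- n_fallback + 1L
      return(tibble::tibble(pgs_id = id, causal_id = id, r1 = 1, r2 = 1,
                            dbp = 0, fallback = TRUE))
    }
    ld <- pair_ld_both_panels(id, near$variant_id, ref1, ref2)
    tibble::tibble(pgs_id = id, causal_id = near$variant_id,
                   r1 = ld$r1, r2 = ld$r2,
                   dbp = as.numeric(near$bp - vi$bp), fallback = FALSE)
  })
  if (n_fallback > 0) {
    warning(n_fallback, " PGS SNP(s) had no causal variant within ",
            window_kb, " kb; using the SNP itself as its candidate")
  }
  new_candidate_causal_map(pairs, mode = "known")
}

check_pgs_present <- function(pgs_snps, ref1, ref2) {
  for (ref in list(ref1, ref2)) {
    missing_ids <- setdiff(pgs_snps$variant_id, ref$variants$variant_id)
    if (length(missing_ids) > 0) {
      stop("PGS SNP(s) absent from reference panel '", ref$population_label,
           "': ", paste(utils::head(missing_ids, 5), collapse = ", "))
    }
  }
}

#' Predict the relative accuracy of a transferred PGS
#'
#' Evaluates the deterministic relative accuracy `RA = R2^2 / R1^2` of a
#' PGS built in population 1 and applied in population 2:
#'
#' `RA = (rho_b^2 h2_2 / h2_1)
#'   x ( sum_k m_k sqrt(p_k2 (1-p_k2) / (p_k1 (1-p_k1))) / sum_k v_k )^2
#'   x ( sum_k p_k1 (1-p_k1) beta_k^2 / sum_k p_k2 (1-p_k2) beta_k^2 )`
#'
#' where in `known` mode `m_k` and `v_k` are the per-SNP sums of
#' `r1 * r2` and `r1^2` over its causal pairs, in `heuristic` mode the
#' per-SNP means over its candidate pairs, and in `naive` mode both are
#' 1 (the PGS SNPs are treated as the causal variants, leaving only the
#' heterozygosity ratio). The PGS-variance term is computed from the
#' closed form `sum_k p(1-p) beta_hat^2` in every mode, so predictions
#' need only reference panels and summary statistics.
#'
#' @param pgs_snps PGS SNP set from [clump()] (needs `variant_id`,
#'   `beta_hat`).
#' @param cmap a `candidate_causal_map` (`known`/`heuristic` mode;
#'   ignored in `naive` mode).
#' @param stats1,stats2 per-variant frequency tables from
#'   [allele_frequencies()] on the population-1 and population-2
#'   reference panels.
#' @param rho_b cross-population correlation of causal effects
#'   (default 1: quantifies the LD+MAF fraction of the RA only).
#' @param h2_1,h2_2 heritability in populations 1 and 2 (default 1).
#' @param mode `"known"`, `"heuristic"` or `"naive"`.
#' @return An `ra_prediction` with fields `ra`, `mode`, `term_effect`,
#'   `term_ldmaf`, `term_varpgs` and `inputs_summary`; `ra` is exactly
#'   the product of the three terms.
#' @export
predict_relative_accuracy <- function(pgs_snps, cmap = NULL, stats1, stats2,
                                      rho_b = 1, h2_1 = 1, h2_2 = 1,
                                      mode = c("heuristic", "known", "naive")) {
  mode <- match.arg(mode)
  if (nrow(pgs_snps) == 0) stop("empty PGS SNP set")
  i1 <- match(pgs_snps$variant_id, stats1$variant_id)
  i2 <- match(pgs_snps$variant_id, stats2$variant_id)
  if (anyNA(i1) || anyNA(i2)) {
    stop("frequencies unavailable for PGS SNP(s): ",
         paste(pgs_snps$variant_id[is.na(i1) | is.na(i2)], collapse = ", "))
  }
  p1 <- stats1$p[i1]
  p2 <- stats2$p[i2]
  degenerate <- p1 <= 0 | p1 >= 1 | p2 <= 0 | p2 >= 1
  if (any(degenerate)) {
    stop("allele frequency 0 or 1 (heterozygosity ratio undefined) for: ",
         paste(pgs_snps$variant_id[degenerate], collapse = ", "))
  }
  het1 <- p1 * (1 - p1)
  het2 <- p2 * (1 - p2)

  if (mode == "naive") {
    m_k <- rep(1, nrow(pgs_snps))
    v_k <- rep(1, nrow(pgs_snps))
    n_cand <- integer(0)
  } else {
    if (is.null(cmap) || !inherits(cmap, "candidate_causal_map")) {
      stop("mode '", mode, "' requires a candidate_causal_map")
    }
    if (cmap$mode != mode) {
      stop("candidate map was built in '", cmap$mode,
           "' mode but prediction requested '", mode, "'")
    }
    j <- match(pgs_snps$variant_id, cmap$summary$pgs_id)
    if (anyNA(j)) {
      stop("candidate map is missing PGS SNP(s): ",
           paste(pgs_snps$variant_id[is.na(j)], collapse = ", "))
    }
    if (mode == "known") {
      m_k <- cmap$summary$sum_r1r2[j]
      v_k <- cmap$summary$sum_r1_sq[j]
    } else {
      m_k <- cmap$summary$mean_r1r2[j]
      v_k <- cmap$summary$mean_r1_sq[j]
    }
    n_cand <- cmap$summary$n_candidates[j]
  }

  beta2 <- pgs_snps$beta_hat^2
  term_effect <- rho_b^2 * h2_2 / h2_1
  term_ldmaf <- (sum(m_k * sqrt(het2 / het1)) / sum(v_k))^2
  term_varpgs <- sum(het1 * beta2) / sum(het2 * beta2)
  structure(
    list(ra = term_effect * term_ldmaf * term_varpgs,
         mode = mode,
         term_effect = term_effect,
         term_ldmaf = term_ldmaf,
         term_varpgs = term_varpgs,
         inputs_summary = list(m_t = nrow(pgs_snps), n_candidates = n_cand)),
    class = "ra_prediction"
  )
}

#' @export
#' @method print ra_prediction
print.ra_prediction <- function(x, ...) {
  cat("<ra_prediction> mode =", x$mode, "\n")
  cat(sprintf("  RA = %.4f = %.4f (effect) x %.4f (LD+MAF) x %.4f (var PGS)\n",
              x$ra, x$term_effect, x$term_ldmaf, x$term_varpgs))
  cat("  M_T =", x$inputs_summary$m_t, "PGS SNPs\n")
  invisible(x)
}
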