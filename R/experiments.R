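#' Run a replicated two-population RA study
#'
#' For each replicate: simulate the discovery, validation and target
#' cohorts; draw causal effects and phenotypes; run the discovery GWAS
#' with the causal variants left out; clump to the PGS SNP set; score
#' the PGS in the validation and target cohorts; compute the observed
#' RA (`R2_target / R2_validation`); and evaluate the three
#' deterministic predictions (known-causal, heuristic and naive) with
#' the discovery cohort as the population-1 reference and the target
#' cohort as the population-2 reference. Replicate seeds are
#' `config$seed + replicate - 1` for auditability.
#'
#' The cohort named `validation` in `config$n_targets` is the held-out
#' same-ancestry sample; every other cohort is treated as a transfer
#' target and yields one record per replicate.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of replicates.
#' @param clumping a [clump_params()].
#' @param window_kb candidate window, kb.
#' @param r2_min candidate LD r-squared threshold.
#' @param scenario_id label stored on the records.
#' @param verbose print per-replicate progress to stderr.
#' @return A tibble of replicate records: `scenario_id`, `replicate`,
#'   `seed`, `population_pair`, `m_t`, `r2_ref`, `r2_target`, `ra_obs`,
#'   `ra_pred_known`, `ra_pred_heuristic`, `ra_pred_naive`,
#'   `realized_fst`. Replicates with no genome-wide significant SNP are
#'   recorded with `m_t = 0` and `NA` accuracies.
#' @export
run_scenario <- function(config, n_replicates,
                         clumping = clump_params(),
                         window_kb = 100, r2_min = 0.45,
                         scenario_id = "scenario", verbose = FALSE) {
  check_study_config(config)
  purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    rep_seed <- config$seed + rep_i - 1L
    rep_config <- config
    rep_config$seed <- rep_seed
    study <- simulate_study(rep_config)
    rec <- eval_replicate(study, rep_config, clumping, window_kb, r2_min,
                          scenario_id, rep_i, effect_seed = trait_seed(rep_seed, 0L))
    if (verbose) {
      message(sprintf("replicate %d: M_T = %d, ra_obs = %s", rep_i, rec$m_t[1],
                      paste(round(rec$ra_obs, 3), collapse = ", ")))
    }
    rec
  })
}

#' Run a scenario grid sharing genotype panels across trait cells
#'
#' Runs [run_scenario()]-style replicates for several trait
#' architectures (cells varying e.g. `h2` and `m_causal`) that share
#' the same genotype configuration. Genotype panels depend only on the
#' replicate seed, so each replicate's cohorts are simulated once and
#' reused across cells; causal effects and phenotypes are re-drawn per
#' cell from a cell-specific seed.
#'
#' @param config base [sim_config()].
#' @param cells data frame with one row per cell; columns may override
#'   `h2` (scalar), `m_causal` and `rho_b`, plus an optional
#'   `scenario_id` column.
#' @inheritParams run_scenario
#' @return Combined replicate-record tibble (see [run_scenario()]).
#' @export
run_grid <- function(config, cells, n_replicates,
                     clumping = clump_params(),
                     window_kb = 100, r2_min = 0.45, verbose = FALSE) {
  check_study_config(config)
  cells <- tibble::as_tibble(cells)
  if (!("scenario_id" %in% names(cells))) {
    cells$scenario_id <- sprintf("cell_%d", seq_len(nrow(cells)))
  }
  purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    rep_seed <- config$seed + rep_i - 1L
    rep_config <- config
    rep_config$seed <- rep_seed
    study <- simulate_study(rep_config)
    purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
      cell_config <- rep_config
      for (field in intersect(c("h2", "m_causal", "rho_b"), names(cells))) {
        value <- cells[[field]][ci]
        if (field == "h2") value <- c(pop1 = value, pop2 = value)
        if (field == "m_causal") value <- as.integer(value)
        cell_config[[field]] <- value
      }
      rec <- eval_replicate(study, cell_config, clumping, window_kb, r2_min,
                            cells$scenario_id[ci], rep_i,
                            effect_seed = trait_seed(rep_seed, ci))
      if (verbose) {
        message(sprintf("replicate %d cell %s: M_T = %d", rep_i,
                        cells$scenario_id[ci], rec$m_t[1]))
      }
      rec
    })
  })
}

check_study_config <- function(config) {
  if (!("validation" %in% names(config$n_targets)) ||
      config$target_ancestry[["validation"]] != 1L) {
    stop("config must include an ancestry-1 cohort named 'validation'")
  }
  if (length(setdiff(names(config$n_targets), "validation")) == 0) {
    stop("config defines no target cohort")
  }
}

# seed for the trait layer (effects + phenotypes) of one replicate/cell;
# kept well under 2^31
trait_seed <- function(rep_seed, cell_index) {
  (rep_seed * 1009L + cell_index * 97L) %% 2000000000L
}

# genotype layer of one replicate: panels, their frequency tables and
# realized F_ST per target cohort
simulate_study <- function(config) {
  panels <- simulate_two_populations(config)
  freqs <- lapply(panels, allele_frequencies)
  target_names <- setdiff(names(panels), c("discovery", "validation"))
  fst <- vapply(target_names, function(nm) {
    hudson_fst(panels$discovery, panels[[nm]])
  }, numeric(1))
  list(panels = panels, freqs = freqs, target_names = target_names, fst = fst)
}

# trait layer: effects, phenotypes, GWAS, clumping, scoring and the
# three deterministic predictions, for one replicate of one scenario
eval_replicate <- function(study, config, clumping, window_kb, r2_min,
                           scenario_id, rep_i, effect_seed) {
  panels <- study$panels
  freqs <- study$freqs
  rep_seed <- config$seed

  pop2_name <- study$target_names[
    config$target_ancestry[study$target_names] == 2L][1]
  freqs2 <- if (is.na(pop2_name)) freqs$discovery else freqs[[pop2_name]]
  set.seed(effect_seed)
  effects <- sample_causal_effects(freqs$discovery, freqs2, config)
  # per-cohort phenotype seeds drawn from the stream itself: nearby
  # integer seeds give correlated Mersenne-Twister streams, which would
  # couple GWAS noise to target-cohort noise and bias the observed RA
  cohort_seeds <- sample.int(.Machine$integer.max - 1L, length(panels))

  cohort_beta <- function(nm) {
    if (nm == "discovery" || config$target_ancestry[[nm]] == 1L) "beta1" else "beta2"
  }
  cohort_h2 <- function(nm) {
    if (nm == "discovery" || config$target_ancestry[[nm]] == 1L)
      config$h2[["pop1"]] else config$h2[["pop2"]]
  }
  phenos <- purrr::imap(panels, function(panel, nm) {
    k <- match(nm, names(panels))
    simulate_phenotype(panel, effects, beta_col = cohort_beta(nm),
                       h2 = cohort_h2(nm), seed = cohort_seeds[k])
  })

  sumstats <- run_gwas(panels$discovery, phenos$discovery,
                       exclude_ids = effects$variant_id)
  pgs <- clump(sumstats, panels$discovery, clumping)
  m_t <- nrow(pgs)

  if (m_t == 0) {
    return(tibble::tibble(
      scenario_id = scenario_id, replicate = rep_i, seed = rep_seed,
      population_pair = paste0("discovery->", study$target_names),
      m_t = 0L, r2_ref = NA_real_, r2_target = NA_real_,
      ra_obs = NA_real_, ra_pred_known = NA_real_,
      ra_pred_heuristic = NA_real_, ra_pred_naive = NA_real_,
      realized_fst = unname(study$fst)
    ))
  }

  val_scores <- score_pgs(panels$validation, pgs)
  r2_ref <- observed_r2(val_scores, phenos$validation)
  stats1 <- freqs$discovery

  purrr::map_dfr(study$target_names, function(nm) {
    tgt_scores <- score_pgs(panels[[nm]], pgs)
    r2_tgt <- observed_r2(tgt_scores, phenos[[nm]])
    stats2 <- freqs[[nm]]
    h2_1 <- config$h2[["pop1"]]
    h2_2 <- cohort_h2(nm)

    known_map <- suppressWarnings(
      build_known_causal_map(pgs, effects$variant_id,
                             panels$discovery, panels[[nm]], window_kb))
    heur_map <- find_candidate_causals(pgs, panels$discovery, panels[[nm]],
                                       window_kb, r2_min)
    pred <- function(mode, cmap = NULL) {
      predict_relative_accuracy(pgs, cmap, stats1, stats2,
                                rho_b = config$rho_b, h2_1 = h2_1, h2_2 = h2_2,
                                mode = mode)$ra
    }
    tibble::tibble(
      scenario_id = scenario_id, replicate = rep_i, seed = rep_seed,
      population_pair = paste0("discovery->", nm),
      m_t = m_t, r2_ref = r2_ref, r2_target = r2_tgt,
      ra_obs = r2_tgt / r2_ref,
      ra_pred_known = pred("known", known_map),
      ra_pred_heuristic = pred("heuristic", heur_map),
      ra_pred_naive = pred("naive"),
      realized_fst = unname(study$fst[nm])
    )
  })
}

#' Summarise prediction bias over replicates
#'
#' For each scenario, population pair and prediction mode: the mean
#' observed and predicted RA over valid replicates (those with at least
#' one GWS SNP), the signed relative bias
#' `100 * (mean_pred - mean_obs) / mean_obs`, and its
#' leave-one-replicate-out jackknife standard error.
#'
#' @param records replicate records from [run_scenario()].
#' @return A tibble with one row per (scenario, population pair, mode).
#' @export
summarize_bias <- function(records) {
  valid <- records[records$m_t > 0 & !is.na(records$ra_obs), ]
  n_dropped <- nrow(records) - nrow(valid)
  if (n_dropped > 0) {
    message("excluding ", n_dropped, " replicate record(s) with no GWS SNP")
  }
  if (nrow(valid) == 0) stop("no valid replicates")

  long <- tidyr::pivot_longer(
    valid,
    cols = c("ra_pred_known", "ra_pred_heuristic", "ra_pred_naive"),
    names_to = "mode", names_prefix = "ra_pred_", values_to = "ra_pred"
  )
  long |>
    dplyr::group_by(.data$scenario_id, .data$population_pair, .data$mode) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) stop("need at least 2 valid replicates per scenario/mode")
      bias_of <- function(obs, pred) 100 * (mean(pred) - mean(obs)) / mean(obs)
      bias <- bias_of(df$ra_obs, df$ra_pred)
      n <- nrow(df)
      jack <- vapply(seq_len(n), function(i) {
        bias_of(df$ra_obs[-i], df$ra_pred[-i])
      }, numeric(1))
      tibble::tibble(
        n_replicates = n,
        mean_ra_obs = mean(df$ra_obs),
        mean_ra_pred = mean(df$ra_pred),
        signed_bias_pct = bias,
        jackknife_se = sqrt((n - 1) / n * sum((jack - mean(jack))^2))
      )
    }) |>
    dplyr::ungroup()
}
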