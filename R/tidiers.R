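#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an RA prediction into its multiplicative terms
#'
#' @param x an `ra_prediction`.
#' @param ... unused.
#' @return A tibble with one row per decomposition term
#'   (`effect_correlation_heritability`, `ld_maf`, `var_pgs_ratio`) and
#'   the resulting `ra` row.
#' @export
tidy.ra_prediction <- function(x, ...) {
  tibble::tibble(
    term = c("effect_correlation_heritability", "ld_maf", "var_pgs_ratio", "ra"),
    estimate = c(x$term_effect, x$term_ldmaf, x$term_varpgs, x$ra)
  )
}

#' @rdname tidy.ra_prediction
#' @export
glance.ra_prediction <- function(x, ...) {
  tibble::tibble(
    ra = x$ra, mode = x$mode,
    term_effect = x$term_effect, term_ldmaf = x$term_ldmaf,
    term_varpgs = x$term_varpgs, m_t = x$inputs_summary$m_t
  )
}

#' Tidy an observed RA
#'
#' @param x an `ra_observation`.
#' @param ... unused.
#' @return One-row tibble (`tidy`) / one-row tibble with cohort R-squared
#'   values (`glance`).
#' @export
tidy.ra_observation <- function(x, ...) {
  tibble::tibble(
    term = c("r2_ref", "r2_target", "ra"),
    estimate = c(x$r2_ref, x$r2_target, x$ra),
    std.error = c(NA_real_, NA_real_, x$se_ra)
  )
}

#' @rdname tidy.ra_observation
#' @export
glance.ra_observation <- function(x, ...) {
  tibble::tibble(ra = x$ra, se_ra = x$se_ra, r2_ref = x$r2_ref,
                 r2_target = x$r2_target, scale = x$scale,
                 n_boot = x$n_boot)
}
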