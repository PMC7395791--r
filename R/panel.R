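#' Construct a genotype panel
#'
#' A genotype panel is the unit over which allele frequencies, LD, F_ST,
#' GWAS and PGS scoring are computed: a samples-by-variants matrix of
#' counted-allele dosages (0, 1, 2 or `NA` for missing) together with a
#' variant map. By convention the counted allele is the minor allele
#' within the panel that defined the orientation (for panels read from
#' disk, the panel itself; simulated panels are oriented to the
#' discovery population).
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   values in `{0, 1, 2, NA}`.
#' @param variants data frame with columns `variant_id`, `chromosome`,
#'   `bp` (1-based position), `counted_allele`, `other_allele`; one row
#'   per column of `genotypes`, ordered by (chromosome, bp).
#' @param sample_ids character vector, one per row of `genotypes`.
#' @param population_label single string naming the population.
#' @param validate run invariant checks (dosage range, duplicate ids,
#'   position ordering). Internal callers that construct panels from
#'   already-validated pieces may skip them.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, variants, sample_ids = NULL,
                           population_label = "pop", validate = TRUE) {
  variants <- tibble::as_tibble(variants)
  required <- c("variant_id", "chromosome", "bp", "counted_allele", "other_allele")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (ncol(genotypes) != nrow(variants)) {
    stop("genotype matrix has ", ncol(genotypes), " columns but variant table has ",
         nrow(variants), " rows")
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(genotypes))) rownames(genotypes)
                  else sprintf("sample_%d", seq_len(nrow(genotypes)))
  }
  if (length(sample_ids) != nrow(genotypes)) {
    stop("sample_ids length does not match genotype rows")
  }
  if (validate) {
  rng <- suppressWarnings(range(genotypes, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L)) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicated variant id(s): ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]), collapse = ", "))
  }
  if (any(variants$counted_allele == variants$other_allele)) {
    stop("counted_allele equals other_allele for variant(s): ",
         paste(variants$variant_id[variants$counted_allele == variants$other_allele],
               collapse = ", "))
  }
  ord_ok <- all(unlist(lapply(
    split(variants$bp, variants$chromosome),
    function(x) all(diff(x) > 0)
  )))
  if (!ord_ok) stop("bp must be strictly increasing within each chromosome")
  }
  dimnames(genotypes) <- list(sample_ids, variants$variant_id)
  structure(
    list(population_label = population_label,
         sample_ids = as.character(sample_ids),
         variants = variants,
         genotypes = genotypes),
    class = "genotype_panel"
  )
}

#' @export
#' @method print genotype_panel
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", x$population_label, ": ",
      nrow(x$genotypes), " samples x ", ncol(x$genotypes), " variants\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

n_samples <- function(panel) nrow(panel$genotypes)
n_variants <- function(panel) ncol(panel$genotypes)

variant_index <- function(panel, ids) {
  idx <- match(ids, panel$variants$variant_id)
  if (anyNA(idx)) {
    stop("variant id(s) not in panel: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Recode a panel so that the counted allele is the panel minor allele
#'
#' Variants whose counted-allele frequency exceeds 0.5 have their dosages
#' flipped to `2 - x` and their allele labels swapped. Ties (frequency
#' exactly 0.5) are left as-is.
#'
#' @param panel a [genotype_panel()].
#' @return The recoded panel.
#' @export
recode_minor <- function(panel) {
  p <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    panel$genotypes[, flip] <- 2L - panel$genotypes[, flip]
    tmp <- panel$variants$counted_allele[flip]
    panel$variants$counted_allele[flip] <- panel$variants$other_allele[flip]
    panel$variants$other_allele[flip] <- tmp
  }
  panel
}

#' Per-variant allele frequencies and heterozygosity
#'
#' Frequency of the counted allele, computed as `mean(dosage) / 2` over
#' non-missing genotypes. Variants with no non-missing genotypes are
#' flagged (`p = NA`) so callers can exclude them.
#'
#' @param panel a [genotype_panel()].
#' @return A tibble with columns `variant_id`, `p`, `het` (`2 p (1 - p)`)
#'   and `n_obs` (non-missing sample count).
#' @export
allele_frequencies <- function(panel) {
  if (n_variants(panel) == 0) stop("panel has no variants")
  cached <- attr(panel, "freqs")
  if (!is.null(cached)) return(cached)
  cf <- col_freqs(panel$genotypes)
  tibble::tibble(
    variant_id = panel$variants$variant_id,
    p = cf$p,
    het = 2 * cf$p * (1 - cf$p),
    n_obs = cf$n_obs
  )
}

#' Signed LD correlation between two variants
#'
#' Pearson correlation of counted-allele dosages over samples non-missing
#' at both variants. The sign follows the counted-allele orientation:
#' flipping the coding of one variant negates `r`.
#'
#' @param panel a [genotype_panel()].
#' @param id_a,id_b variant ids.
#' @return A one-row tibble with columns `id_a`, `id_b`, `r`,
#'   `population_label`.
#' @export
ld_r <- function(panel, id_a, id_b) {
  ia <- variant_index(panel, id_a)
  ib <- variant_index(panel, id_b)
  xa <- panel$genotypes[, ia]
  xb <- panel$genotypes[, ib]
  keep <- !is.na(xa) & !is.na(xb)
  xa <- xa[keep]; xb <- xb[keep]
  if (length(xa) < 2 || stats::var(xa) == 0 || stats::var(xb) == 0) {
    stop("LD undefined: variant ", if (length(xa) < 2 || stats::var(xa) == 0) id_a else id_b,
         " is monomorphic over the pairwise-complete samples")
  }
  tibble::tibble(
    id_a = id_a, id_b = id_b,
    r = stats::cor(xa, xb),
    population_label = panel$population_label
  )
}

#' LD of one variant with all neighbours in a physical window
#'
#' Returns the signed LD correlation between an index variant and every
#' panel variant on the same chromosome with `|bp - bp_index| <=
#' window_kb * 1000` (closed interval). Monomorphic neighbours are
#' dropped.
#'
#' @param panel a [genotype_panel()].
#' @param index_id index variant id.
#' @param window_kb half-window in kb.
#' @param include_index include the index variant itself (`r = 1`)?
#' @return A tibble with columns `id_a` (index), `id_b`, `r`, `dbp`
#'   (signed bp offset), `population_label`.
#' @export
ld_window <- function(panel, index_id, window_kb, include_index = FALSE) {
  ii <- variant_index(panel, index_id)
  v <- panel$variants
  sel <- which(v$chromosome == v$chromosome[ii] &
               abs(v$bp - v$bp[ii]) <= window_kb * 1000)
  if (!include_index) sel <- setdiff(sel, ii)
  if (length(sel) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          r = numeric(), dbp = numeric(),
                          population_label = character()))
  }
  x0 <- panel$genotypes[, ii]
  r <- suppressWarnings(
    as.vector(stats::cor(x0, panel$genotypes[, sel, drop = FALSE],
                         use = "pairwise.complete.obs"))
  )
  keep <- !is.na(r)
  tibble::tibble(
    id_a = index_id,
    id_b = v$variant_id[sel][keep],
    r = r[keep],
    dbp = as.numeric(v$bp[sel][keep] - v$bp[ii]),
    population_label = panel$population_label
  )
}

#' Hudson's F_ST between two panels
#'
#' Ratio-of-averages Hudson estimator: per-variant numerator
#' `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)` and
#' denominator `p1 (1 - p2) + p2 (1 - p1)`, with `n_l` the number of
#' sampled allele copies (twice the non-missing sample count); the
#' estimate is the ratio of the numerator and denominator sums. Panels
#' are aligned on counted-allele orientation before comparison.
#'
#' @param panel1,panel2 [genotype_panel()] objects.
#' @param variant_ids variants to use; default the intersection.
#' @return Hudson F_ST (numeric scalar).
#' @export
hudson_fst <- function(panel1, panel2, variant_ids = NULL) {
  if (is.null(variant_ids)) {
    variant_ids <- intersect(panel1$variants$variant_id, panel2$variants$variant_id)
  }
  if (length(variant_ids) == 0) stop("no shared variants")
  i1 <- variant_index(panel1, variant_ids)
  i2 <- variant_index(panel2, variant_ids)

  f1 <- allele_frequencies(panel1)[i1, ]
  f2 <- allele_frequencies(panel2)[i2, ]
  # align orientation: flip p2 where allele coding is swapped
  a1 <- panel1$variants[i1, ]
  a2 <- panel2$variants[i2, ]
  swapped <- a1$counted_allele == a2$other_allele & a1$other_allele == a2$counted_allele
  mismatch <- !swapped & (a1$counted_allele != a2$counted_allele |
                          a1$other_allele != a2$other_allele)
  if (any(mismatch)) {
    warning("dropping ", sum(mismatch), " variant(s) with incompatible alleles")
  }
  p1 <- f1$p
  p2 <- ifelse(swapped, 1 - f2$p, f2$p)
  n1 <- 2 * f1$n_obs
  n2 <- 2 * f2$n_obs

  keep <- !mismatch & !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  if (any(!mismatch & (n1 < 2 | n2 < 2))) {
    warning("excluding ", sum(!mismatch & (n1 < 2 | n2 < 2)),
            " variant(s) with fewer than two sampled alleles")
  }
  # polymorphic in the union of panels
  poly <- (p1 > 0 | p2 > 0) & (p1 < 1 | p2 < 1)
  keep <- keep & poly
  if (!any(keep)) stop("no usable variants for F_ST")

  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
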