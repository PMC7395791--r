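# Correlated dosage columns: target correlation rho with base column.
correlated_col <- function(base, rho, maf = 0.4) {
  n <- length(base)
  out <- base
  swap <- runif(n) > rho
  out[swap] <- rbinom(sum(swap), 2, maf)
  out
}

# Two panels (identification and target) with a controlled layout:
# X index at 1.00 Mb; Y at 1.05 Mb in strong LD with X; Z at 1.15 Mb in
# very strong LD but outside a 100 kb window; W isolated at 5 Mb.
candidate_fixture <- function(seed = 71) {
  set.seed(seed)
  n <- 600
  x <- rbinom(n, 2, 0.4)
  y <- correlated_col(x, 0.9)
  z <- correlated_col(x, 0.97)
  w <- rbinom(n, 2, 0.4)
  bp <- c(1e6, 1.05e6, 1.15e6, 5e6)
  ids <- c("X", "Y", "Z", "W")
  ref1 <- make_panel(cbind(x, y, z, w), bp = bp, ids = ids, label = "ref1")
  x2 <- rbinom(n, 2, 0.3)
  ref2 <- make_panel(cbind(x2, correlated_col(x2, 0.6, 0.3),
                           correlated_col(x2, 0.6, 0.3), rbinom(n, 2, 0.3)),
                     bp = bp, ids = ids, label = "ref2")
  list(ref1 = ref1, ref2 = ref2)
}

pgs_row <- function(id, beta = 0.1, allele = "A") {
  tibble::tibble(variant_id = id, chromosome = "1", bp = NA_integer_,
                 counted_allele = allele, beta_hat = beta, p_value = 1e-9)
}

test_that("candidate identification applies the r2 and distance rules", {
  fx <- candidate_fixture()
  r2_xy <- cor(fx$ref1$genotypes[, "X"], fx$ref1$genotypes[, "Y"])^2
  r2_xz <- cor(fx$ref1$genotypes[, "X"], fx$ref1$genotypes[, "Z"])^2
  expect_gt(r2_xy, 0.45)
  expect_gt(r2_xz, 0.45)
  cmap <- find_candidate_causals(pgs_row("X"), fx$ref1, fx$ref2)
  # Y qualifies; Z is excluded by the 100 kb window despite higher r2
  expect_equal(cmap$pairs$causal_id, "Y")
  expect_false(cmap$summary$fallback)
  # r values come from the right panels
  expect_equal(cmap$pairs$r1,
               cor(fx$ref1$genotypes[, "X"], fx$ref1$genotypes[, "Y"]))
  expect_equal(cmap$pairs$r2,
               cor(fx$ref2$genotypes[, "X"], fx$ref2$genotypes[, "Y"]))
})

test_that("an isolated PGS SNP falls back to itself", {
  fx <- candidate_fixture()
  cmap <- find_candidate_causals(pgs_row("W"), fx$ref1, fx$ref2)
  expect_equal(cmap$pairs$causal_id, "W")
  expect_true(cmap$summary$fallback)
  expect_equal(cmap$summary$mean_r1_sq, 1)
  expect_equal(cmap$summary$mean_r1r2, 1)
})

test_that("known-causal mapping uses the closed window and both panels", {
  fx <- candidate_fixture()
  # causal exactly 100 kb away: include Z by moving it to 1.1 Mb
  fx$ref1$variants$bp[3] <- as.integer(1.1e6)
  fx$ref2$variants$bp[3] <- as.integer(1.1e6)
  cmap <- build_known_causal_map(pgs_row("X"), causal_ids = c("Y", "Z", "W"),
                                 fx$ref1, fx$ref2)
  expect_setequal(cmap$pairs$causal_id, c("Y", "Z"))
  expect_equal(cmap$summary$n_candidates, 2L)
  # mean over both pairs
  r1 <- sapply(c("Y", "Z"), function(v)
    cor(fx$ref1$genotypes[, "X"], fx$ref1$genotypes[, v]))
  r2 <- sapply(c("Y", "Z"), function(v)
    cor(fx$ref2$genotypes[, "X"], fx$ref2$genotypes[, v]))
  expect_equal(cmap$summary$mean_r1r2, mean(r1 * r2))
  expect_equal(cmap$summary$sum_r1_sq, sum(r1^2))
  # no causal in window -> fallback with warning
  expect_warning(
    fb <- build_known_causal_map(pgs_row("W"), causal_ids = "Y",
                                 fx$ref1, fx$ref2),
    "no causal variant")
  expect_true(fb$summary$fallback)
  # missing PGS SNP -> error naming it
  expect_error(build_known_causal_map(pgs_row("nope"), "Y", fx$ref1, fx$ref2),
               "nope")
})

make_cmap <- function(pgs_ids, causal_ids, r1, r2, mode = "heuristic") {
  pairs <- tibble::tibble(pgs_id = pgs_ids, causal_id = causal_ids,
                          r1 = r1, r2 = r2, dbp = 0, fallback = FALSE)
  pgsra:::new_candidate_causal_map(pairs, mode = mode)
}

stats_tbl <- function(ids, p) {
  tibble::tibble(variant_id = ids, p = p, het = 2 * p * (1 - p),
                 n_obs = 1000L)
}

test_that("single-pair worked example reproduces the closed-form value", {
  pgs <- pgs_row("k1", beta = 0.2)
  cmap <- make_cmap("k1", "j1", r1 = 0.9, r2 = 0.6)
  s1 <- stats_tbl("k1", 0.3)
  s2 <- stats_tbl("k1", 0.2)
  pred <- predict_relative_accuracy(pgs, cmap, s1, s2, mode = "heuristic")
  expect_equal(pred$term_ldmaf, (0.54 * sqrt(0.16 / 0.21) / 0.81)^2,
               tolerance = 1e-12)
  expect_equal(pred$term_varpgs, 0.21 / 0.16, tolerance = 1e-12)
  expect_equal(pred$term_effect, 1)
  expect_equal(pred$ra, 0.4446, tolerance = 1e-3)
  expect_equal(pred$ra, pred$term_effect * pred$term_ldmaf * pred$term_varpgs)
})

test_that("identical populations give predicted RA of exactly 1", {
  set.seed(73)
  ids <- sprintf("k%d", 1:4)
  pgs <- tibble::tibble(variant_id = ids, chromosome = "1", bp = NA_integer_,
                        counted_allele = "A",
                        beta_hat = rnorm(4), p_value = 1e-9)
  s <- stats_tbl(ids, runif(4, 0.1, 0.5))
  r1 <- runif(4, 0.5, 0.9)
  cmap <- make_cmap(ids, sprintf("j%d", 1:4), r1 = r1, r2 = r1)
  pred <- predict_relative_accuracy(pgs, cmap, s, s, rho_b = 1,
                                    h2_1 = 0.5, h2_2 = 0.5, mode = "heuristic")
  expect_equal(pred$ra, 1)
  # naive mode with equal frequencies: ra = rho^2 h2_2 / h2_1 exactly
  naive <- predict_relative_accuracy(pgs, NULL, s, s, rho_b = 0.8,
                                     h2_1 = 0.5, h2_2 = 0.4, mode = "naive")
  expect_equal(naive$ra, 0.8^2 * 0.4 / 0.5)
  expect_equal(naive$term_ldmaf, 1)
  expect_equal(naive$term_varpgs, 1)
})

test_that("known-mode evaluation matches a brute-force transcription", {
  # 5 PGS SNPs, 10 causals, uneven pair sets: the estimator must agree
  # with a direct loop evaluation of the closed-form ratio to 1e-12
  set.seed(79)
  k_ids <- sprintf("k%d", 1:5)
  j_ids <- sprintf("j%d", 1:10)
  pair_sets <- list(
    k1 = c("j1", "j2"), k2 = c("j3"), k3 = c("j4", "j5", "j6"),
    k4 = c("j7", "j8"), k5 = c("j9", "j10"))
  pairs <- purrr::imap_dfr(pair_sets, function(js, k) {
    tibble::tibble(pgs_id = k, causal_id = js,
                   r1 = runif(length(js), 0.3, 0.95),
                   r2 = runif(length(js), 0.1, 0.9),
                   dbp = 0, fallback = FALSE)
  })
  cmap <- pgsra:::new_candidate_causal_map(pairs, mode = "known")
  p1 <- runif(5, 0.1, 0.5); p2 <- runif(5, 0.1, 0.5)
  beta <- rnorm(5, 0, 0.2)
  pgs <- tibble::tibble(variant_id = k_ids, chromosome = "1",
                        bp = NA_integer_, counted_allele = "A",
                        beta_hat = beta, p_value = 1e-9)
  rho_b <- 0.9; h2_1 <- 0.5; h2_2 <- 0.4

  # brute force, written directly from the formula
  num_mid <- 0; den_mid <- 0; num_var <- 0; den_var <- 0
  for (k in seq_along(k_ids)) {
    js <- pair_sets[[k_ids[k]]]
    rows <- pairs[pairs$pgs_id == k_ids[k], ]
    num_mid <- num_mid +
      sqrt((p2[k] * (1 - p2[k])) / (p1[k] * (1 - p1[k]))) * sum(rows$r1 * rows$r2)
    den_mid <- den_mid + sum(rows$r1^2)
    num_var <- num_var + p1[k] * (1 - p1[k]) * beta[k]^2
    den_var <- den_var + p2[k] * (1 - p2[k]) * beta[k]^2
  }
  brute <- (rho_b^2 * h2_2 / h2_1) * (num_mid / den_mid)^2 * (num_var / den_var)

  pred <- predict_relative_accuracy(pgs, cmap, stats_tbl(k_ids, p1),
                                    stats_tbl(k_ids, p2), rho_b = rho_b,
                                    h2_1 = h2_1, h2_2 = h2_2, mode = "known")
  expect_equal(pred$ra, brute, tolerance = 1e-12)
})

test_that("known and heuristic modes coincide on identical singleton pair sets", {
  set.seed(83)
  ids <- sprintf("k%d", 1:6)
  r1 <- runif(6, 0.4, 0.95); r2 <- runif(6, 0.2, 0.9)
  pgs <- tibble::tibble(variant_id = ids, chromosome = "1", bp = NA_integer_,
                        counted_allele = "A", beta_hat = rnorm(6),
                        p_value = 1e-9)
  s1 <- stats_tbl(ids, runif(6, 0.1, 0.5))
  s2 <- stats_tbl(ids, runif(6, 0.1, 0.5))
  known <- predict_relative_accuracy(
    pgs, make_cmap(ids, sprintf("j%d", 1:6), r1, r2, mode = "known"),
    s1, s2, mode = "known")
  heur <- predict_relative_accuracy(
    pgs, make_cmap(ids, sprintf("j%d", 1:6), r1, r2, mode = "heuristic"),
    s1, s2, mode = "heuristic")
  expect_identical(known$ra, heur$ra)
})

test_that("predicted RA is invariant under allele flips", {
  set.seed(89)
  ids <- sprintf("k%d", 1:5)
  pgs <- tibble::tibble(variant_id = ids, chromosome = "1", bp = NA_integer_,
                        counted_allele = "A", beta_hat = rnorm(5),
                        p_value = 1e-9)
  p1 <- runif(5, 0.1, 0.9); p2 <- runif(5, 0.1, 0.9)
  r1 <- runif(5, 0.3, 0.9); r2 <- runif(5, 0.1, 0.9)
  base <- predict_relative_accuracy(
    pgs, make_cmap(ids, sprintf("j%d", 1:5), r1, r2),
    stats_tbl(ids, p1), stats_tbl(ids, p2), mode = "heuristic")
  # flip the coding of PGS SNP 2: p -> 1 - p in both populations, and
  # both of its LD correlations change sign
  p1f <- p1; p2f <- p2; r1f <- r1; r2f <- r2
  p1f[2] <- 1 - p1[2]; p2f[2] <- 1 - p2[2]
  r1f[2] <- -r1[2]; r2f[2] <- -r2[2]
  flipped <- predict_relative_accuracy(
    pgs, make_cmap(ids, sprintf("j%d", 1:5), r1f, r2f),
    stats_tbl(ids, p1f), stats_tbl(ids, p2f), mode = "heuristic")
  expect_equal(flipped$ra, base$ra, tolerance = 1e-12)
})

test_that("shrinking target-population LD drives the LD+MAF term to zero", {
  set.seed(97)
  ids <- sprintf("k%d", 1:5)
  pgs <- tibble::tibble(variant_id = ids, chromosome = "1", bp = NA_integer_,
                        counted_allele = "A", beta_hat = rnorm(5),
                        p_value = 1e-9)
  s1 <- stats_tbl(ids, runif(5, 0.1, 0.5))
  s2 <- stats_tbl(ids, runif(5, 0.1, 0.5))
  r1 <- runif(5, 0.5, 0.9); r2 <- runif(5, 0.3, 0.8)
  lam <- c(1, 0.5, 0.1, 0.01)
  terms <- vapply(lam, function(l) {
    predict_relative_accuracy(pgs, make_cmap(ids, sprintf("j%d", 1:5),
                                             r1, l * r2),
                              s1, s2, mode = "heuristic")$term_ldmaf
  }, numeric(1))
  expect_true(all(diff(terms) < 0))
  expect_lt(terms[4], 1e-3 * terms[1])
})

test_that("degenerate frequencies and mode mismatches raise errors", {
  pgs <- pgs_row("k1")
  cmap <- make_cmap("k1", "j1", 0.9, 0.6)
  expect_error(predict_relative_accuracy(pgs, cmap, stats_tbl("k1", 0),
                                         stats_tbl("k1", 0.2)), "k1")
  expect_error(predict_relative_accuracy(pgs, cmap, stats_tbl("k1", 0.3),
                                         stats_tbl("k1", 0.2), mode = "known"),
               "mode")
  expect_error(predict_relative_accuracy(pgs, NULL, stats_tbl("k1", 0.3),
                                         stats_tbl("k1", 0.2),
                                         mode = "heuristic"),
               "candidate_causal_map")
})
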