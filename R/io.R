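#' Read a genotype panel from PLINK or VCF files
#'
#' For `format = "plink"`, `path` is the file-set prefix (`.bed`, `.bim`
#' and `.fam` are appended). For `format = "vcf"`, `path` is a VCF file
#' and only the GT field is used; half-missing or fully missing calls
#' (`./.`) become `NA`. After reading, the panel is recoded so the
#' counted allele is the minor allele within the panel and variants are
#' ordered by genomic coordinates.
#'
#' @param path file path (PLINK prefix or VCF file).
#' @param format `"plink"` or `"vcf"`.
#' @param population_label label stored on the panel.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path, format = c("plink", "vcf"), population_label = "pop") {
  format <- match.arg(format)
  panel <- switch(format,
    plink = read_plink_panel(path, population_label),
    vcf = read_vcf_panel(path, population_label)
  )
  # order by genomic coordinates, then recode to panel minor allele
  ord <- order(panel$variants$chromosome, panel$variants$bp)
  panel$variants <- panel$variants[ord, ]
  panel$genotypes <- panel$genotypes[, ord, drop = FALSE]
  recode_minor(panel)
}

read_plink_panel <- function(prefix, population_label) {
  bed_file <- paste0(prefix, ".bed")
  bim_file <- paste0(prefix, ".bim")
  fam_file <- paste0(prefix, ".fam")
  for (f in c(bed_file, bim_file, fam_file)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  bim <- utils::read.table(bim_file, header = FALSE, colClasses = "character",
                           col.names = c("chromosome", "variant_id", "cm",
                                         "bp", "a1", "a2"))
  if (anyDuplicated(bim$variant_id)) {
    stop("duplicated variant id in ", bim_file, ": ",
         paste(unique(bim$variant_id[duplicated(bim$variant_id)]), collapse = ", "))
  }
  fam <- utils::read.table(fam_file, header = FALSE, colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_file, what = "raw", n = file.size(bed_file))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("malformed PLINK BED file (bad magic number): ", bed_file)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major PLINK BED files are supported: ", bed_file)
  }
  bytes_per_variant <- ceiling(n / 4)
  expected <- 3 + bytes_per_variant * m
  if (length(raw) != expected) {
    stop("PLINK BED size mismatch in ", bed_file, ": expected ", expected,
         " bytes, found ", length(raw))
  }
  body <- as.integer(raw[-(1:3)])
  # decode 2-bit codes: 00 -> 2 copies of A1, 01 -> missing, 10 -> 1, 11 -> 0
  code_to_dosage <- c(2L, NA_integer_, 1L, 0L)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  shifts <- c(1L, 4L, 16L, 64L)
  for (k in 1:4) {
    rows <- seq(k, 4 * bytes_per_variant, by = 4)
    rows <- rows[rows <= n]
    if (length(rows) == 0) next
    byte_idx <- ((rows - 1L) %/% 4L) + 1L
    codes <- (matrix(body, nrow = bytes_per_variant)[byte_idx, , drop = FALSE] %/%
                shifts[k]) %% 4L
    geno[rows, ] <- code_to_dosage[codes + 1L]
  }
  variants <- tibble::tibble(
    variant_id = bim$variant_id,
    chromosome = bim$chromosome,
    bp = as.integer(bim$bp),
    counted_allele = bim$a1,
    other_allele = bim$a2
  )
  genotype_panel(geno, variants, sample_ids = fam[[2]],
                 population_label = population_label)
}

read_vcf_panel <- function(path, population_label) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  if (anyDuplicated(ids)) {
    stop("duplicated variant id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic record(s) not supported: ",
         paste(ids[multi], collapse = ", "))
  }
  # count ALT alleles from the GT strings; any missing allele -> NA
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  hit <- match(clean, names(known))
  dosage[] <- known[hit]
  unparsed <- !is.na(clean) & is.na(hit) & !clean %in% c("./.", ".", "./0", "0/.", "./1", "1/.")
  if (any(unparsed)) {
    first_bad <- which(unparsed)[1]
    stop("unparseable GT value(s), e.g. '", clean[first_bad],
         "' at variant ", ids[(first_bad - 1L) %% nrow(gt) + 1L])
  }
  variants <- tibble::tibble(
    variant_id = unname(ids),
    chromosome = unname(fix[, "CHROM"]),
    bp = as.integer(fix[, "POS"]),
    counted_allele = unname(fix[, "ALT"]),
    other_allele = unname(fix[, "REF"])
  )
  genotype_panel(t(dosage), variants, sample_ids = colnames(gt),
                 population_label = population_label)
}

#' Write a genotype panel as a PLINK BED/BIM/FAM file set
#'
#' The counted allele is written as A1, so a round trip through
#' [read_panel()] recovers the same dosages (up to minor-allele
#' recoding).
#'
#' @param panel a [genotype_panel()].
#' @param prefix output file-set prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_panel <- function(panel, prefix) {
  n <- n_samples(panel)
  m <- n_variants(panel)
  bim <- data.frame(
    chromosome = panel$variants$chromosome,
    variant_id = panel$variants$variant_id,
    cm = 0,
    bp = panel$variants$bp,
    a1 = panel$variants$counted_allele,
    a2 = panel$variants$other_allele
  )
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = panel$sample_ids, iid = panel$sample_ids,
                    pat = 0, mat = 0, sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  bytes_per_variant <- ceiling(n / 4)
  n_pad <- bytes_per_variant * 4
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  dosage_to_code <- function(x) {
    code <- integer(length(x))
    code[is.na(x)] <- 1L
    code[!is.na(x) & x == 1L] <- 2L
    code[!is.na(x) & x == 0L] <- 3L
    code
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  shifts <- c(1L, 4L, 16L, 64L)
  codes <- matrix(0L, nrow = n_pad, ncol = m)
  codes[1:n, ] <- apply(panel$genotypes, 2, dosage_to_code)
  bytes <- matrix(0L, nrow = bytes_per_variant, ncol = m)
  for (k in 1:4) {
    bytes <- bytes + codes[seq(k, n_pad, by = 4), , drop = FALSE] * shifts[k]
  }
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read / write GWAS summary statistics as TSV
#'
#' Tab-separated with header columns `variant_id`, `chromosome`, `bp`,
#' `counted_allele`, `other_allele`, `beta_hat`, `se`, `p_value`, `n`.
#'
#' @param path file path.
#' @return [read_sumstats()]: a tibble. [write_sumstats()]: `path`,
#'   invisibly.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(variant_id = "character",
                                         chromosome = "character",
                                         counted_allele = "character",
                                         other_allele = "character"))
  tibble::as_tibble(df)
}

#' @rdname read_sumstats
#' @param sumstats summary-statistics tibble.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
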