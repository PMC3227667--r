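# Core containers are deliberately plain base R objects:
#   - genotype matrix: integer matrix, rows = samples, cols = variants,
#     entries in {0, 1, 2, NA}; NA is a real state, never silently imputed.
#   - variant table / sample table: data.frames keyed by id columns.

#' Functional classes recognised in variant annotations
#'
#' The five mutually exclusive categories used throughout: flanking
#' non-coding, nonsynonymous, synonymous, premature truncation and
#' frameshift.
#'
#' @export
functional_classes <- c(
  "non_coding", "nonsynonymous", "synonymous", "truncation", "frameshift"
)

#' @keywords internal
#' @noRd
validate_genotype_matrix <- function(m) {
  if (!is.matrix(m)) stop("genotype matrix must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("genotype matrix must carry sample-id rownames and variant-id colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids in genotype matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate variant ids in genotype matrix")
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("non-missing dosages must be 0, 1 or 2")
  invisible(m)
}

#' @keywords internal
#' @noRd
validate_variant_table <- function(v) {
  need <- c("variant_id", "gene", "functional_class")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("variant table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(v$variant_id)) stop("duplicate variant_id in variant table")
  bad <- setdiff(unique(v$functional_class), functional_classes)
  if (length(bad))
    stop("unknown functional_class token(s): ", paste(bad, collapse = ", "),
         " (offending rows: ",
         paste(v$variant_id[v$functional_class %in% bad], collapse = ", "), ")")
  invisible(v)
}

#' @keywords internal
#' @noRd
validate_sample_table <- function(s) {
  need <- c("sample_id", "status", "stratum")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("sample table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id in sample table")
  if (!all(s$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (any(is.na(s$stratum) | !nzchar(s$stratum)))
    stop("stratum labels must be non-empty")
  invisible(s)
}

#' Read a genotype dosage matrix plus its variant annotation
#'
#' Accepts either a VCF (v4.x, `GT` field, parsed with \pkg{vcfR}) or the
#' package's TSV dosage dialect: header row of variant ids, first column
#' `sample_id`, cells in `{0, 1, 2, NA}`. Dosages are raw alt-allele counts;
#' minor-allele orientation is applied later by [orient_to_minor_allele()].
#' Multi-allelic VCF sites are split into one biallelic record per alt
#' allele (ids suffixed `_altN` when needed).
#'
#' @param genotype_source path to a VCF or dosage TSV.
#' @param annotation_source path to a variant annotation TSV with columns
#'   `variant_id`, `gene`, `functional_class`, and optionally `ref`, `alt`,
#'   `pos`. Every genotype column must have an annotation row.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @return list with `genotypes` (sample x variant integer matrix) and
#'   `variants` (annotation data.frame, ordered as the matrix columns).
#' @export
read_genotypes <- function(genotype_source, annotation_source,
                           format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", genotype_source, ignore.case = TRUE))
      "vcf" else "dosage"
  }
  m <- if (format == "vcf") read_vcf_dosages(genotype_source)
       else read_dosage_table(genotype_source)
  v <- read_variant_annotation(annotation_source)
  missing_ann <- setdiff(colnames(m), v$variant_id)
  if (length(missing_ann))
    stop("variants present in genotypes but absent from annotation: ",
         paste(missing_ann, collapse = ", "))
  v <- v[match(colnames(m), v$variant_id), , drop = FALSE]
  rownames(v) <- NULL
  validate_genotype_matrix(m)
  list(genotypes = m, variants = v)
}

#' Read the TSV dosage dialect
#'
#' @param path dosage TSV: header = `sample_id` then variant ids; cells in
#'   `{0,1,2,NA}`.
#' @return integer matrix, samples x variants.
#' @export
read_dosage_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (names(d)[1] != "sample_id") stop("first column must be 'sample_id'")
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(d$sample_id)
  validate_genotype_matrix(m)
  m
}

#' Write a dosage matrix to the TSV dialect
#'
#' @param m genotype matrix.
#' @param path output path.
#' @export
write_dosage_table <- function(m, path) {
  validate_genotype_matrix(m)
  d <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- fix[, "ID"]
  auto <- is.na(ids) | ids == "."
  ids[auto] <- paste0(fix[auto, "CHROM"], "_", fix[auto, "POS"])
  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  cols <- list(); col_ids <- character(0)
  for (i in seq_along(alts)) {
    n_alt <- length(alts[[i]])
    # split multi-allelic sites: one biallelic dosage column per alt allele
    for (a in seq_len(max(n_alt, 1L))) {
      gtv <- gt[i, ]
      alleles <- strsplit(ifelse(is.na(gtv), "", gtv), "[/|]")
      dos <- vapply(alleles, function(x) {
        if (!length(x) || any(x == ".")) return(NA_integer_)
        sum(x == as.character(a))
      }, integer(1))
      cols[[length(cols) + 1L]] <- dos
      col_ids <- c(col_ids,
                   if (n_alt > 1L) paste0(ids[i], "_alt", a) else ids[i])
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- col_ids
  rownames(m) <- colnames(gt)
  storage.mode(m) <- "integer"
  validate_genotype_matrix(m)
  m
}

#' Read a variant annotation table
#'
#' @param path TSV with columns `variant_id`, `gene`, `functional_class`
#'   (one of [functional_classes]) and optionally `ref`, `alt`, `pos`.
#' @return validated data.frame.
#' @export
read_variant_annotation <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_variant_table(v)
  v
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `status` (`case`|`control`),
#'   `stratum`, plus optional covariate columns.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(s)
  s
}

#' @keywords internal
#' @noRd
stratum_rows <- function(samples, stratum) {
  if (identical(stratum, "all")) rep(TRUE, nrow(samples))
  else {
    if (!stratum %in% samples$stratum)
      stop("stratum '", stratum, "' not present in sample table")
    samples$stratum == stratum
  }
}

#' Orient dosages to the minor allele of a stratum
#'
#' The identity of the minor allele is frequency-dependent and can differ
#' between race-ethnicity strata (a coding variant can be the minor allele
#' in one population and the major allele in another), so orientation is
#' computed within the analysis stratum, cases and controls pooled. A
#' variant whose alt-allele frequency among non-missing genotypes exceeds
#' 0.5 has every dosage flipped `g -> 2 - g`; frequency exactly 0.5 keeps
#' the alt allele as minor (documented tie-break). Variants with no
#' non-missing genotype in the stratum are flagged and left unflipped.
#'
#' @param m genotype matrix (raw alt dosages, or already oriented —
#'   the operation is idempotent).
#' @param samples sample table aligned with `rownames(m)`.
#' @param stratum stratum label, or `"all"` for the whole cohort.
#' @return genotype matrix with attributes `flipped` (named logical),
#'   `orientation_undefined` (named logical) and `orientation_stratum`.
#' @export
orient_to_minor_allele <- function(m, samples, stratum = "all") {
  validate_genotype_matrix(m)
  samples <- samples[match(rownames(m), samples$sample_id), , drop = FALSE]
  keep <- stratum_rows(samples, stratum)
  sub <- m[keep, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  freq <- colSums(sub, na.rm = TRUE) / (2 * n_obs)
  undefined <- n_obs == 0L
  flip <- !undefined & freq > 0.5
  out <- m
  if (any(flip)) out[, flip] <- 2L - out[, flip, drop = FALSE]
  structure(out,
            flipped = stats::setNames(flip, colnames(m)),
            orientation_undefined = stats::setNames(undefined, colnames(m)),
            orientation_stratum = stratum)
}

#' Per-variant minor allele frequency within a stratum
#'
#' `MAF_j = sum(dosages) / (2 * n_nonmissing)` over the stratum's
#' non-missing genotypes. On a matrix oriented for the same stratum the
#' result is at most 0.5. Variants with no non-missing genotype get `NA`.
#'
#' @inheritParams orient_to_minor_allele
#' @return named numeric vector of frequencies.
#' @export
compute_maf <- function(m, samples, stratum = "all") {
  validate_genotype_matrix(m)
  samples <- samples[match(rownames(m), samples$sample_id), , drop = FALSE]
  keep <- stratum_rows(samples, stratum)
  sub <- m[keep, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  maf <- colSums(sub, na.rm = TRUE) / (2 * n_obs)
  maf[n_obs == 0L] <- NA_real_
  stats::setNames(maf, colnames(m))
}

#' Analysis configuration
#'
#' Bundles the thresholds and permutation settings used across the
#' pipeline: the common/rare MAF boundary (default 2.5%, applied within
#' the analysis stratum, boundary value classed common), the LD pruning
#' R-squared threshold (default 0.8, strict `>`), the missingness QC
#' threshold (default 25%, strict `>`), the number of label permutations,
#' and the RNG seed.
#'
#' @param maf_threshold common/rare MAF boundary in (0,1).
#' @param ld_r2_threshold LD pruning threshold in (0,1).
#' @param missingness_threshold QC missingness threshold in (0,1).
#' @param n_permutations Monte-Carlo permutation count (>= 1).
#' @param rng_seed integer seed.
#' @param variant_subsets list of `list(class_filter=, maf_bin=)` pairs
#'   defining the analysis grid columns.
#' @param strata_to_analyze stratum labels (plus `"all"`) to analyse;
#'   `NULL` = `"all"` and every stratum in the sample sheet.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(maf_threshold = 0.025,
                            ld_r2_threshold = 0.8,
                            missingness_threshold = 0.25,
                            n_permutations = 1000L,
                            rng_seed = 1L,
                            variant_subsets = list(
                              list(class_filter = "nonsynonymous", maf_bin = "common"),
                              list(class_filter = "nonsynonymous", maf_bin = "rare"),
                              list(class_filter = "non_coding",    maf_bin = "common"),
                              list(class_filter = "non_coding",    maf_bin = "rare")
                            ),
                            strata_to_analyze = NULL) {
  for (x in c(maf_threshold, ld_r2_threshold, missingness_threshold))
    if (!is.numeric(x) || x <= 0 || x >= 1)
      stop("thresholds must lie strictly in (0, 1)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(maf_threshold = maf_threshold,
                 ld_r2_threshold = ld_r2_threshold,
                 missingness_threshold = missingness_threshold,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed),
                 variant_subsets = variant_subsets,
                 strata_to_analyze = strata_to_analyze),
            class = "analysis_config")
}
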