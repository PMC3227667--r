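# Missingness QC, frequency-based imputation and LD pruning.

#' Drop samples and variants with excessive missingness
#'
#' Individuals whose missing fraction is strictly greater than `threshold`
#' are removed first; variants are then filtered on their missing fraction
#' computed over the retained individuals (order configurable). A value at
#' exactly the threshold is retained — the rule is "more than".
#'
#' @param m genotype matrix.
#' @param threshold missing-fraction threshold in (0,1); default 0.25.
#' @param order `"samples_first"` (default) or `"variants_first"`.
#' @return list with `genotypes` (filtered matrix) and `report`, a
#'   `qc_report` recording dropped ids and pre/post missing fractions.
#' @export
filter_missing <- function(m, threshold = 0.25,
                           order = c("samples_first", "variants_first")) {
  order <- match.arg(order)
  validate_genotype_matrix(m)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pre_missing <- mean(is.na(m))
  drop_rows <- function(x) rowMeans(is.na(x)) > threshold
  drop_cols <- function(x) colMeans(is.na(x)) > threshold
  if (order == "samples_first") {
    bad_s <- drop_rows(m)
    m1 <- m[!bad_s, , drop = FALSE]
    if (nrow(m1) == 0L) stop("all individuals exceeded the missingness threshold")
    bad_v <- drop_cols(m1)
    out <- m1[, !bad_v, drop = FALSE]
  } else {
    bad_v <- drop_cols(m)
    m1 <- m[, !bad_v, drop = FALSE]
    bad_s <- drop_rows(m1)
    if (all(bad_s)) stop("all individuals exceeded the missingness threshold")
    out <- m1[!bad_s, , drop = FALSE]
  }
  report <- structure(list(
    dropped_samples = rownames(m)[rownames(m) %in% setdiff(rownames(m), rownames(out))],
    dropped_variants = colnames(m)[colnames(m) %in% setdiff(colnames(m), colnames(out))],
    n_dropped_samples = nrow(m) - nrow(out),
    n_dropped_variants = ncol(m) - ncol(out),
    threshold = threshold, order = order,
    pre_missing_fraction = pre_missing,
    post_missing_fraction = mean(is.na(out))), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "Missingness QC (> %.0f%%): dropped %d sample(s), %d variant(s); missing %.2f%% -> %.2f%%\n",
    100 * x$threshold, x$n_dropped_samples, x$n_dropped_variants,
    100 * x$pre_missing_fraction, 100 * x$post_missing_fraction))
  invisible(x)
}

#' Impute missing genotypes from stratum genotype frequencies
#'
#' Each missing cell is drawn from the empirical distribution of the
#' non-missing genotypes (0/1/2) at that variant within the individual's
#' stratum; a stratum with no non-missing genotype at a variant falls back
#' to the cohort-wide distribution. This is a single stochastic draw, not a
#' haplotype-model imputation, and is reproducible under `seed`.
#' Non-missing cells are never touched.
#'
#' @param m genotype matrix.
#' @param samples sample table aligned with `rownames(m)`.
#' @param seed integer seed (NULL leaves the RNG stream alone).
#' @return complete genotype matrix.
#' @export
impute_missing <- function(m, samples, seed = NULL) {
  validate_genotype_matrix(m)
  if (!anyNA(m)) return(m)
  if (!is.null(seed)) set.seed(seed)
  samples <- samples[match(rownames(m), samples$sample_id), , drop = FALSE]
  all_missing <- colSums(!is.na(m)) == 0L
  if (any(all_missing))
    stop("variant(s) entirely missing, cannot impute: ",
         paste(colnames(m)[all_missing], collapse = ", "))
  strata <- samples$stratum
  out <- m
  for (s in unique(strata)) {
    rows <- which(strata == s)
    sub <- m[rows, , drop = FALSE]
    need <- which(colSums(is.na(sub)) > 0L)
    for (j in need) {
      obs <- sub[, j]
      obs <- obs[!is.na(obs)]
      if (!length(obs)) obs <- m[, j][!is.na(m[, j])]  # cohort-wide fallback
      k <- which(is.na(sub[, j]))
      out[rows[k], j] <- sample(obs, length(k), replace = TRUE)
    }
  }
  out
}

#' Genotypic (composite) LD between two dosage vectors
#'
#' Squared Pearson correlation over complete pairs. If either vector is
#' constant over the complete pairs the correlation is undefined and `NA`
#' is returned (pruning treats it as 0).
#'
#' @param a,b aligned dosage vectors.
#' @return R-squared in \[0, 1\], or `NA` when undefined.
#' @export
pairwise_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(NA_real_)
  stats::cor(a, b)^2
}

#' Greedy LD pruning to one representative per LD group
#'
#' Variants are scanned in column (coordinate) order. Each not-yet-assigned
#' variant seeds a group and absorbs every later unassigned variant whose
#' R-squared with the seed is strictly greater than `threshold`; the seed
#' is the group's retained representative. Retained set = seeds plus
#' ungrouped singletons. Deterministic given the column order.
#'
#' @param m genotype matrix (oriented/QC'd; complete matrices use a fast
#'   BLAS correlation path).
#' @param threshold R-squared threshold, default 0.8 (strict `>`).
#' @return list with `retained` (variant ids) and `groups` (list of
#'   `ld_group`s: `representative`, `members`, `r2` to representative).
#' @export
ld_prune <- function(m, threshold = 0.8) {
  validate_genotype_matrix(m)
  V <- ncol(m)
  ids <- colnames(m)
  if (V == 0L) return(list(retained = character(0), groups = list()))
  complete <- !anyNA(m)
  if (complete) {
    sds <- apply(m, 2, stats::sd)
  }
  assigned <- rep(FALSE, V)
  groups <- vector("list", 0L)
  for (i in seq_len(V)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    later <- which(!assigned)
    if (length(later)) {
      if (complete) {
        r2 <- rep(NA_real_, length(later))
        if (sds[i] > 0) {
          ok <- sds[later] > 0
          if (any(ok))
            r2[ok] <- as.vector(stats::cor(m[, i], m[, later[ok], drop = FALSE]))^2
        }
      } else {
        r2 <- vapply(later, function(j) pairwise_r2(m[, i], m[, j]), numeric(1))
      }
      hit <- later[!is.na(r2) & r2 > threshold]
      hit_r2 <- r2[!is.na(r2) & r2 > threshold]
    } else {
      hit <- integer(0); hit_r2 <- numeric(0)
    }
    assigned[hit] <- TRUE
    groups[[length(groups) + 1L]] <- structure(
      list(representative = ids[i],
           members = ids[c(i, hit)],
           r2 = stats::setNames(c(1, hit_r2), ids[c(i, hit)])),
      class = "ld_group")
  }
  reps <- vapply(groups, `[[`, character(1), "representative")
  list(retained = ids[ids %in% reps], groups = groups)
}
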