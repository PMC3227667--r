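# Seeded case-control genotype simulator. The defaults emulate the
# structure of a 480-member candidate-gene resequencing cohort: 31
# folate-pathway genes, 1,441 variants with a heavily rare-shifted
# frequency spectrum (singleton point mass plus a low tail), the observed
# functional-class mix, race-ethnicity strata with stratum-specific
# allele frequencies, block LD induced by allele copying, and ~6% MCAR
# missingness. An optional planted effect ties case status to a signed
# pathway score through a logistic model.

#' Default gene panel with per-gene variant counts
#'
#' The 31-gene folate/one-carbon panel used by the simulator defaults,
#' with `total_variants` split as evenly as possible across genes.
#'
#' @param total_variants total variant count to distribute (default 1441).
#' @return named integer vector, gene -> variant count.
#' @export
default_gene_counts <- function(total_variants = 1441L) {
  genes <- c("MTHFD1", "MTHFD2", "MTHFR", "MTR", "MTRR", "MAT1A", "MAT2A",
             "SHMT1", "SHMT2", "ATIC", "GART", "ALDH1L1", "ALDH1L2",
             "MTFMT", "AMT", "SARDH", "DMGDH", "BHMT", "BHMT2", "CBS",
             "CTH", "TYMS", "DHFR", "FOLH1", "FOLR1", "FOLR2", "SLC19A1",
             "FPGS", "GGH", "MTHFS", "FTCD")
  base <- total_variants %/% length(genes)
  counts <- rep(base, length(genes))
  extra <- total_variants - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  stats::setNames(as.integer(counts), genes)
}

#' Cohort simulation settings
#'
#' The defaults are the study conditions the package emulates: 239 cases /
#' 241 controls, strata 65% Hispanic / 21% non-Hispanic white / 14% other,
#' 31 genes carrying 1,441 variants in the class mix 1050 non-coding : 211
#' nonsynonymous : 171 synonymous : 4 truncation : 5 frameshift, a
#' frequency spectrum with 614/1441 singleton mass and 1096/1441 total
#' rare (MAF < 2.5%) mass, LD blocks of 5 consecutive within-gene variants
#' with allele-copying probability 0.3, and 6% missing genotypes.
#'
#' @param n_cases,n_controls group sizes.
#' @param strata_proportions named fractions summing to 1.
#' @param genes named integer vector: variants per gene.
#' @param class_proportions named fractions over [functional_classes],
#'   summing to 1.
#' @param singleton_mass fraction of variants that are exact singletons
#'   (one carrier in the whole cohort).
#' @param rare_mass fraction of variants that are rare but not singleton
#'   (base MAF uniform between `1/(2n)` and `maf_threshold`).
#'   The remaining mass is common (base MAF uniform on
#'   `[maf_threshold, 0.5]`).
#' @param maf_threshold the rare/common boundary used by the spectrum.
#' @param stratum_maf_sd logit-scale SD of the per-stratum deviation of a
#'   variant's MAF from its base value (0 = identical across strata).
#' @param ld_block_size consecutive within-gene variants per LD block.
#' @param ld_rho latent (Gaussian-copula) correlation shared by the
#'   variants of a block; 0 = linkage equilibrium, values near 1 give
#'   dosage R-squared high enough to form pruning groups. The copula
#'   leaves every variant's marginal stratum MAF untouched.
#' @param missing_rate MCAR missingness fraction.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 239L, n_controls = 241L,
                        strata_proportions = c(Hispanic = 0.65,
                                               White = 0.21,
                                               Other = 0.14),
                        genes = default_gene_counts(),
                        class_proportions = c(non_coding = 1050,
                                              nonsynonymous = 211,
                                              synonymous = 171,
                                              truncation = 4,
                                              frameshift = 5) / 1441,
                        singleton_mass = 614 / 1441,
                        rare_mass = 482 / 1441,
                        maf_threshold = 0.025,
                        stratum_maf_sd = 0.3,
                        ld_block_size = 5L,
                        ld_rho = 0.3,
                        missing_rate = 0.06) {
  n <- n_cases + n_controls
  if (n_cases < 1L || n_controls < 1L) stop("group sizes must be positive")
  if (abs(sum(strata_proportions) - 1) > 1e-9)
    stop("strata_proportions must sum to 1")
  if (is.null(names(strata_proportions))) stop("strata_proportions must be named")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (!setequal(names(class_proportions), functional_classes))
    stop("class_proportions must be named by the five functional classes")
  if (any(genes < 1L)) stop("per-gene variant counts must be positive")
  if (singleton_mass + rare_mass > 1 + 1e-9)
    stop("singleton_mass + rare_mass must be at most 1")
  if (singleton_mass > 0 && n < 1L)
    stop("spec infeasible: singletons need at least one individual")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 strata_proportions = strata_proportions,
                 genes = genes, class_proportions = class_proportions,
                 singleton_mass = singleton_mass, rare_mass = rare_mass,
                 maf_threshold = maf_threshold,
                 stratum_maf_sd = stratum_maf_sd,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 missing_rate = missing_rate),
            class = "cohort_spec")
}

#' Simulate a stratified case-control genotype cohort
#'
#' Per-individual strata are assigned by largest-remainder rounding of the
#' target proportions (so every stratum is realized) and shuffled; case
#' status is assigned to a random subset of individuals, independent of
#' genotype — the null model. Each variant gets a base MAF from the
#' singleton / rare / common mixture and per-stratum MAFs by logit-normal
#' jitter around it; genotypes are Hardy-Weinberg binomial draws at the
#' stratum MAF, except singletons, which place one heterozygote in a
#' random individual. Within each gene, consecutive variants form LD
#' blocks sharing a latent Gaussian factor with correlation `ld_rho`:
#' each non-singleton dosage is the binomial quantile of the individual's
#' correlated uniform, so block members are correlated while marginal
#' stratum MAFs stay exactly on target. Missing cells are injected
#' completely at random. Fully reproducible under `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return list with `genotypes` (raw alt-dosage matrix), `variants`
#'   (annotation incl. `pos`, LD `block`, and per-stratum `target_maf_*`
#'   columns), `samples`, and the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_cases + spec$n_controls
  strata_names <- names(spec$strata_proportions)

  # samples: largest-remainder stratum counts, shuffled; random case subset
  raw <- spec$strata_proportions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  stratum <- sample(rep(strata_names, times = cnt))
  status <- rep("control", n)
  status[sample.int(n, spec$n_cases)] <- "case"
  samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                        status = status, stratum = stratum,
                        stringsAsFactors = FALSE)

  # variants: classes, positions, frequency spectrum
  gene <- rep(names(spec$genes), times = spec$genes)
  V <- length(gene)
  pos <- unlist(lapply(spec$genes, function(k) sort(sample.int(50000L, k))),
                use.names = FALSE)
  variant_id <- paste0(gene, "_", pos)
  fclass <- sample(names(spec$class_proportions), V, replace = TRUE,
                   prob = spec$class_proportions)
  kind <- sample(c("singleton", "rare", "common"), V, replace = TRUE,
                 prob = c(spec$singleton_mass, spec$rare_mass,
                          1 - spec$singleton_mass - spec$rare_mass))
  floor_maf <- 1 / (2 * n)
  base_maf <- numeric(V)
  base_maf[kind == "singleton"] <- floor_maf
  base_maf[kind == "rare"] <- stats::runif(sum(kind == "rare"),
                                           floor_maf, spec$maf_threshold)
  base_maf[kind == "common"] <- stats::runif(sum(kind == "common"),
                                             spec$maf_threshold, 0.5)
  target <- matrix(base_maf, V, length(strata_names),
                   dimnames = list(variant_id, strata_names))
  jitter_rows <- kind != "singleton"
  if (spec$stratum_maf_sd > 0 && any(jitter_rows)) {
    for (s in strata_names) {
      t_s <- stats::plogis(stats::qlogis(base_maf[jitter_rows]) +
                             stats::rnorm(sum(jitter_rows), 0, spec$stratum_maf_sd))
      target[jitter_rows, s] <- pmin(t_s, 0.5)
    }
  }

  # within-gene LD blocks
  block <- unlist(lapply(spec$genes, function(k)
    ceiling(seq_len(k) / spec$ld_block_size)), use.names = FALSE)
  block_id <- paste0(gene, "_b", block)

  p_of_sample <- target[, match(stratum, strata_names), drop = FALSE]
  # p_of_sample is V x n: row j holds each individual's stratum MAF
  m <- matrix(0L, n, V, dimnames = list(samples$sample_id, variant_id))
  z_block <- NULL; current_block <- ""
  rho <- min(max(spec$ld_rho, 0), 1 - 1e-12)
  for (j in seq_len(V)) {
    if (!identical(block_id[j], current_block)) {
      z_block <- stats::rnorm(n)       # latent factor shared by the block
      current_block <- block_id[j]
    }
    if (kind[j] == "singleton") {
      dos <- integer(n)
      dos[sample.int(n, 1L)] <- 1L
    } else {
      u <- stats::pnorm(sqrt(rho) * z_block +
                          sqrt(1 - rho) * stats::rnorm(n))
      dos <- stats::qbinom(u, 2L, p_of_sample[j, ])
    }
    m[, j] <- as.integer(dos)
  }
  if (spec$missing_rate > 0)
    m[stats::runif(length(m)) < spec$missing_rate] <- NA_integer_

  variants <- data.frame(variant_id = variant_id, gene = gene,
                         functional_class = fclass, ref = "A", alt = "G",
                         is_indel = FALSE, pos = pos, block = block_id,
                         stringsAsFactors = FALSE)
  for (s in strata_names) variants[[paste0("target_maf_", s)]] <- target[, s]
  validate_genotype_matrix(m)
  list(genotypes = m, variants = variants, samples = samples, spec = spec)
}

#' Planted-effect settings
#'
#' @param metabolite metabolite whose signed score drives case status.
#' @param class_filter,maf_bin variant subset the score is built on.
#' @param compartment compartment restriction for the score.
#' @param beta log-odds of case status per score unit (negative reproduces
#'   a "cases have lower scores" signature).
#' @param baseline_prevalence target marginal case fraction.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(metabolite = "purine",
                        class_filter = "nonsynonymous", maf_bin = "common",
                        compartment = "all",
                        beta = 0, baseline_prevalence = 0.5) {
  if (!is.finite(beta)) stop("beta must be finite")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1)")
  structure(list(metabolite = metabolite, class_filter = class_filter,
                 maf_bin = maf_bin, compartment = compartment,
                 beta = beta, baseline_prevalence = baseline_prevalence),
            class = "effect_spec")
}

#' Plant a signed-score effect on case status
#'
#' Computes the Metabolic Index Score each individual would receive for
#' the effect's metabolite and variant subset (cohort-wide orientation;
#' missing cells contribute 0) and redraws case status independently per
#' individual from `Pr(case) = plogis(alpha + beta * MIS)`, with `alpha`
#' calibrated by root-finding so the marginal prevalence matches
#' `baseline_prevalence`. With `beta = 0` this is exactly the null model.
#'
#' @param genotypes,variants,samples a cohort as from [simulate_cohort()].
#' @param model a [pathway_model()].
#' @param effect an [effect_spec()].
#' @param seed integer seed.
#' @return the sample table with resampled `status` and a `true_score`
#'   column; attributes `alpha` and `beta` record the generating model.
#' @export
plant_effect <- function(genotypes, variants, samples, model, effect,
                         seed = NULL) {
  stopifnot(inherits(effect, "effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  oriented <- orient_to_minor_allele(genotypes, samples, "all")
  subset <- subset_variants(variants, oriented, samples,
                            class_filter = effect$class_filter,
                            maf_bin = effect$maf_bin, stratum = "all")
  mis <- metabolic_index_score(oriented, subset, variants, model,
                               effect$metabolite,
                               compartment = effect$compartment,
                               complete_case = TRUE)
  beta <- effect$beta
  f <- function(a) mean(stats::plogis(a + beta * mis)) - effect$baseline_prevalence
  alpha <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  p <- stats::plogis(alpha + beta * mis)
  out <- samples
  out$status <- ifelse(stats::rbinom(nrow(samples), 1L, p) == 1L,
                       "case", "control")
  out$true_score <- as.numeric(mis)
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  out
}

#' Write a simulated cohort to the package's TSV dialects
#'
#' Emits `dosages.tsv`, `variants.tsv`, `samples.tsv` and a
#' `ground_truth.json` (seed-free record of the spec plus any planted
#' effect attributes present on the sample table).
#'
#' @param cohort a [simulate_cohort()] result (samples possibly replaced
#'   by [plant_effect()]).
#' @param dir output directory (created if absent).
#' @return invisibly, the file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("dosages.tsv", "variants.tsv", "samples.tsv",
                            "ground_truth.json"))
  write_dosage_table(cohort$genotypes, paths[1])
  utils::write.table(cohort$variants, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(spec = unclass(cohort$spec),
                alpha = attr(cohort$samples, "alpha"),
                beta = attr(cohort$samples, "beta"))
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
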