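# Variant subsetting, unweighted burden sums and the signed Metabolic
# Index Score (MIS) — the package's core computation. Every variant and
# every gene carries identical weight; the only per-gene quantity is the
# +1/-1 sign taken from the pathway model.

#' Select variants by functional class and stratum MAF bin
#'
#' The common/rare boundary is applied to the minor allele frequency
#' computed within the analysis stratum; a MAF exactly at the threshold is
#' classed common (the definition is "MAF >= threshold").
#'
#' @param variants variant annotation table.
#' @param m genotype matrix, already oriented for `stratum` (and LD-pruned
#'   if pruning is wanted upstream).
#' @param samples sample table.
#' @param class_filter character vector of [functional_classes] to keep,
#'   or `"all"`.
#' @param maf_bin `"common"`, `"rare"` or `"all"`.
#' @param stratum stratum label or `"all"`.
#' @param maf_threshold common/rare boundary, default 0.025.
#' @return object of class `variant_subset`: list with `variant_ids`,
#'   the filter settings, and the stratum MAFs of the members. An empty
#'   selection is allowed and flagged via `length(subset$variant_ids) == 0`.
#' @export
subset_variants <- function(variants, m, samples,
                            class_filter = "all",
                            maf_bin = c("all", "common", "rare"),
                            stratum = "all",
                            maf_threshold = 0.025) {
  maf_bin <- match.arg(maf_bin)
  validate_variant_table(variants)
  ids <- intersect(variants$variant_id, colnames(m))
  v <- variants[variants$variant_id %in% ids, , drop = FALSE]
  if (!identical(class_filter, "all")) {
    bad <- setdiff(class_filter, functional_classes)
    if (length(bad)) stop("unknown functional class: ", paste(bad, collapse = ", "))
    v <- v[v$functional_class %in% class_filter, , drop = FALSE]
  }
  maf <- compute_maf(m, samples, stratum)[v$variant_id]
  keep <- switch(maf_bin,
                 all    = rep(TRUE, nrow(v)),
                 common = !is.na(maf) & maf >= maf_threshold,
                 rare   = !is.na(maf) & maf < maf_threshold)
  structure(list(variant_ids = v$variant_id[keep],
                 class_filter = class_filter, maf_bin = maf_bin,
                 stratum = stratum, maf_threshold = maf_threshold,
                 maf = maf[keep]),
            class = "variant_subset")
}

#' @export
print.variant_subset <- function(x, ...) {
  cat(sprintf("Variant subset: %d variant(s) [class: %s; MAF bin: %s; stratum: %s]\n",
              length(x$variant_ids), paste(x$class_filter, collapse = "+"),
              x$maf_bin, x$stratum))
  invisible(x)
}

#' @keywords internal
#' @noRd
subset_ids <- function(subset) {
  if (inherits(subset, "variant_subset")) subset$variant_ids else as.character(subset)
}

#' Unweighted minor-allele burden sum
#'
#' Per individual, the plain tally of minor alleles over the subset:
#' 1 for a heterozygote, 2 for a minor-allele homozygote. Restricting the
#' subset to one gene gives the per-gene collapsing analysis; a pathway-wide
#' subset gives the whole-pathway mutation burden.
#'
#' @param m genotype matrix, oriented; complete by default.
#' @param subset a [subset_variants()] result or a character vector of
#'   variant ids.
#' @param complete_case if `TRUE`, missing cells are skipped (diagnostic
#'   mode); by default missing data must already be imputed.
#' @return named numeric vector of per-individual scores with attribute
#'   `provenance`.
#' @export
burden_sum <- function(m, subset, complete_case = FALSE) {
  ids <- subset_ids(subset)
  sub <- m[, ids, drop = FALSE]
  if (!complete_case && anyNA(sub))
    stop("burden_sum requires a complete matrix; impute first or set complete_case = TRUE")
  s <- rowSums(sub, na.rm = complete_case)
  attr(s, "provenance") <- list(type = "burden", n_variants = length(ids),
                                subset = if (inherits(subset, "variant_subset"))
                                  subset[c("class_filter", "maf_bin", "stratum")] else NULL)
  s
}

#' Signed pathway score (Metabolic Index Score)
#'
#' `MIS_i = sum_j s_gene(j) * dosage_ij` over the subset's variants whose
#' genes are signed for `metabolite` in the pathway model: minor-allele
#' homozygotes in a beneficial gene contribute +2, heterozygotes in a
#' competing gene contribute -1, and so on. Variants in genes the model
#' leaves unsigned for this metabolite contribute 0. `compartment` further
#' restricts the signed genes to cytoplasmic or mitochondrial enzymes.
#'
#' @inheritParams burden_sum
#' @param variants variant annotation table (maps variant -> gene).
#' @param model a [pathway_model()].
#' @param metabolite metabolite name present in the model.
#' @param compartment `"all"`, `"cytoplasmic"` or `"mitochondrial"`.
#' @return named numeric vector of per-individual scores with attribute
#'   `provenance` (incl. the signed variants actually used).
#' @export
metabolic_index_score <- function(m, subset, variants, model, metabolite,
                                  compartment = c("all", "cytoplasmic", "mitochondrial"),
                                  complete_case = FALSE) {
  compartment <- match.arg(compartment)
  signs <- pathway_signs(model, metabolite, compartment)
  ids <- subset_ids(subset)
  gene <- variants$gene[match(ids, variants$variant_id)]
  if (anyNA(gene))
    stop("subset variant(s) missing from annotation: ",
         paste(ids[is.na(gene)], collapse = ", "))
  w <- signs[gene]                      # NA for unsigned genes -> weight 0
  w[is.na(w)] <- 0
  sub <- m[, ids, drop = FALSE]
  if (!complete_case && anyNA(sub))
    stop("metabolic_index_score requires a complete matrix; impute first or set complete_case = TRUE")
  if (complete_case && anyNA(sub)) sub[is.na(sub)] <- 0
  s <- as.vector(sub %*% w)
  names(s) <- rownames(m)
  attr(s, "provenance") <- list(type = "mis", metabolite = metabolite,
                                compartment = compartment,
                                n_variants = length(ids),
                                n_signed = sum(w != 0),
                                signed_variants = ids[w != 0])
  s
}

#' Count distinct multi-site genotype combinations
#'
#' The number of unique dosage vectors over the subset's variants among
#' the selected samples — a measure of how heterogeneous the genotype
#' configurations underlying a score are.
#'
#' @inheritParams burden_sum
#' @param sample_filter logical/character/integer row selector
#'   (default: all samples).
#' @return integer count.
#' @export
distinct_genotype_combinations <- function(m, subset, sample_filter = NULL) {
  ids <- subset_ids(subset)
  if (!length(ids)) stop("subset is empty")
  sub <- m[, ids, drop = FALSE]
  if (!is.null(sample_filter)) sub <- sub[sample_filter, , drop = FALSE]
  keys <- do.call(paste, c(as.data.frame(sub), sep = "\r"))
  length(unique(keys))
}
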