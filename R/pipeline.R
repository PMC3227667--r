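# End-to-end orchestration: QC -> impute -> LD prune -> per-stratum
# orientation -> burden and signed-score grids -> permutation inference
# with max(T) adjustment over the full metabolite x subset x stratum
# family -> dichotomized odds ratios. One stratified label-permutation
# stream is shared by every hypothesis, which is what makes the family
# wide max(T) adjustment coherent across stratum-restricted cells.

#' Run the full pathway-informed collapsing analysis
#'
#' Stages, in order: missingness QC (samples then variants, strict
#' "more than" rule); stochastic frequency-based imputation within strata;
#' cohort-wide greedy LD pruning to one representative per group; then,
#' per analysis stratum, minor-allele orientation and stratum MAFs. On the
#' pruned, oriented data it computes (a) unweighted burden sums for
#' common/rare x {all, nonsynonymous, non-coding} subsets with permuted
#' p-values (Welch t for common sums, Mann-Whitney for the skewed rare
#' sums), (b) a per-gene collapsing grid (nonsynonymous common/rare;
#' p-values deliberately unadjusted and flagged as such), (c) the signed
#' Metabolic Index Score grid over every metabolite x subset x stratum
#' cell with raw and max(T)-adjusted p-values sharing one stratified
#' permutation stream, and (d) dichotomized odds ratios (control-median
#' cut and a zero cut excluding ties) per score cell. Pooled-cohort
#' ("all") hypotheses use stratified permutations, preserving per-stratum
#' case/control ratios.
#'
#' @param genotypes raw alt-dosage genotype matrix.
#' @param variants variant annotation table.
#' @param samples sample sheet.
#' @param model a [pathway_model()]; default [default_pathway_model()].
#' @param config an [analysis_config()].
#' @return object of class `pathway_scan`; see the components
#'   `qc`, `ld`, `burden_table`, `gene_table`, `mis_grid`, `or_table`,
#'   `top_cell`, `manifest`.
#' @export
run_pathway_scan <- function(genotypes, variants, samples,
                             model = default_pathway_model(),
                             config = analysis_config()) {
  validate_genotype_matrix(genotypes)
  validate_variant_table(variants)
  validate_sample_table(samples)
  set.seed(config$rng_seed)
  B <- config$n_permutations
  stage <- "missingness QC"
  res <- tryCatch({
    qc <- filter_missing(genotypes, config$missingness_threshold)
    m <- qc$genotypes
    samples <- samples[match(rownames(m), samples$sample_id), , drop = FALSE]
    variants_kept <- variants[match(colnames(m), variants$variant_id), , drop = FALSE]

    stage <- "imputation"
    m <- impute_missing(m, samples)

    stage <- "LD pruning"
    pruned <- ld_prune(m, config$ld_r2_threshold)
    m <- m[, pruned$retained, drop = FALSE]
    variants_kept <- variants_kept[match(colnames(m), variants_kept$variant_id), ,
                                   drop = FALSE]

    stage <- "orientation"
    strata <- config$strata_to_analyze
    if (is.null(strata)) strata <- c("all", sort(unique(samples$stratum)))
    oriented <- lapply(strata, function(s) orient_to_minor_allele(m, samples, s))
    names(oriented) <- strata

    case <- samples$status == "case"
    # one shared stratified permutation stream for every hypothesis
    L <- perm_label_matrix(case, B, strata = samples$stratum)
    raw_p <- function(x, mask, method) {
      x <- x[mask]
      if (length(unique(x)) == 1L)
        return(list(stat = 0, p = 1))
      obs <- abs(stats_for_labelmat(x, matrix(as.numeric(case[mask]), ncol = 1),
                                    method))
      st <- abs(stats_for_labelmat(x, L[mask, , drop = FALSE], method))
      tol <- 1e-8 * max(1, obs)
      list(stat = obs, p = (sum(st >= obs - tol) + 1) / (B + 1))
    }
    masks <- lapply(strata, function(s) stratum_rows(samples, s))
    names(masks) <- strata

    stage <- "burden analysis"
    bins <- expand.grid(class_filter = c("all", "nonsynonymous", "non_coding"),
                        maf_bin = c("common", "rare"),
                        stratum = strata, stringsAsFactors = FALSE)
    burden_rows <- lapply(seq_len(nrow(bins)), function(i) {
      b <- bins[i, ]
      cf <- if (b$class_filter == "all") "all" else b$class_filter
      sub <- subset_variants(variants_kept, oriented[[b$stratum]], samples,
                             class_filter = cf, maf_bin = b$maf_bin,
                             stratum = b$stratum,
                             maf_threshold = config$maf_threshold)
      mask <- masks[[b$stratum]]
      if (!length(sub$variant_ids)) {
        return(data.frame(b, n_variants = 0L, method = NA, statistic = NA,
                          p = NA, case_mean = NA, case_sd = NA, control_mean = NA,
                          control_sd = NA, case_median = NA, case_min = NA,
                          case_max = NA, control_median = NA, control_min = NA,
                          control_max = NA))
      }
      s <- burden_sum(oriented[[b$stratum]], sub)
      method <- if (b$maf_bin == "common") "t" else "mannwhitney"
      pt <- raw_p(s, mask, method)
      sc <- s[mask & case]; st0 <- s[mask & !case]
      data.frame(b, n_variants = length(sub$variant_ids), method = method,
                 statistic = pt$stat, p = pt$p,
                 case_mean = mean(sc), case_sd = stats::sd(sc),
                 control_mean = mean(st0), control_sd = stats::sd(st0),
                 case_median = stats::median(sc), case_min = min(sc),
                 case_max = max(sc), control_median = stats::median(st0),
                 control_min = min(st0), control_max = max(st0))
    })
    burden_table <- do.call(rbind, burden_rows)

    stage <- "per-gene analysis"
    gene_bins <- expand.grid(gene = unique(variants_kept$gene),
                             maf_bin = c("common", "rare"),
                             stratum = strata, stringsAsFactors = FALSE)
    gene_rows <- lapply(seq_len(nrow(gene_bins)), function(i) {
      g <- gene_bins[i, ]
      sub <- subset_variants(
        variants_kept[variants_kept$gene == g$gene, , drop = FALSE],
        oriented[[g$stratum]], samples, class_filter = "nonsynonymous",
        maf_bin = g$maf_bin, stratum = g$stratum,
        maf_threshold = config$maf_threshold)
      if (!length(sub$variant_ids))
        return(data.frame(g, n_variants = 0L, p_unadjusted = NA))
      s <- burden_sum(oriented[[g$stratum]], sub)
      method <- if (g$maf_bin == "common") "t" else "mannwhitney"
      pt <- raw_p(s, masks[[g$stratum]], method)
      data.frame(g, n_variants = length(sub$variant_ids), p_unadjusted = pt$p)
    })
    gene_table <- do.call(rbind, gene_rows)
    attr(gene_table, "note") <- "p-values are not adjusted for multiple comparisons"

    stage <- "signed-score grid"
    metabolites <- unique(model$metabolite)
    grid <- expand.grid(metabolite = metabolites,
                        subset_i = seq_along(config$variant_subsets),
                        stratum = strata, stringsAsFactors = FALSE)
    cells <- lapply(seq_len(nrow(grid)), function(i) {
      gr <- grid[i, ]
      vs <- config$variant_subsets[[gr$subset_i]]
      sub <- subset_variants(variants_kept, oriented[[gr$stratum]], samples,
                             class_filter = vs$class_filter,
                             maf_bin = vs$maf_bin, stratum = gr$stratum,
                             maf_threshold = config$maf_threshold)
      score <- if (length(sub$variant_ids))
        metabolic_index_score(oriented[[gr$stratum]], sub, variants_kept,
                              model, gr$metabolite)
      else numeric(nrow(samples))
      list(metabolite = gr$metabolite, class_filter = vs$class_filter,
           maf_bin = vs$maf_bin, stratum = gr$stratum,
           n_variants = length(sub$variant_ids),
           n_signed = if (length(sub$variant_ids))
             attr(score, "provenance")$n_signed else 0L,
           score = as.numeric(score))
    })
    score_matrix <- do.call(rbind, lapply(cells, `[[`, "score"))
    cell_masks <- lapply(cells, function(cl) masks[[cl$stratum]])
    # shared-stream max(T): same L as the raw p-values above
    obs <- numeric(length(cells))
    perm_stats <- matrix(0, length(cells), B)
    for (h in seq_along(cells)) {
      mk <- cell_masks[[h]]
      x <- score_matrix[h, mk]
      if (length(unique(x)) == 1L) next
      obs[h] <- abs(stats_for_labelmat(x, matrix(as.numeric(case[mk]), ncol = 1), "t"))
      perm_stats[h, ] <- abs(stats_for_labelmat(x, L[mk, , drop = FALSE], "t"))
    }
    tol <- 1e-8 * pmax(1, obs)
    rawp <- vapply(seq_along(cells), function(h)
      (sum(perm_stats[h, ] >= obs[h] - tol[h]) + 1) / (B + 1), numeric(1))
    mx <- apply(perm_stats, 2, max)
    adjp <- vapply(seq_along(cells), function(h)
      (sum(mx >= obs[h] - tol[h]) + 1) / (B + 1), numeric(1))
    adjp <- pmax(adjp, rawp)
    mis_grid <- data.frame(
      metabolite = vapply(cells, `[[`, character(1), "metabolite"),
      class_filter = vapply(cells, `[[`, character(1), "class_filter"),
      maf_bin = vapply(cells, `[[`, character(1), "maf_bin"),
      stratum = vapply(cells, `[[`, character(1), "stratum"),
      n_variants = vapply(cells, `[[`, integer(1), "n_variants"),
      n_signed = vapply(cells, function(cl) as.integer(cl$n_signed), integer(1)),
      case_mean = vapply(seq_along(cells), function(h)
        mean(score_matrix[h, cell_masks[[h]] & case]), numeric(1)),
      control_mean = vapply(seq_along(cells), function(h)
        mean(score_matrix[h, cell_masks[[h]] & !case]), numeric(1)),
      statistic = obs, raw_p = rawp, adjusted_p = adjp,
      stringsAsFactors = FALSE)
    attr(mis_grid, "family") <-
      sprintf("max(T) family: %d metabolite x subset x stratum cells, one shared stratified permutation stream",
              nrow(mis_grid))

    stage <- "odds ratios"
    or_rows <- lapply(seq_along(cells), function(h) {
      mk <- cell_masks[[h]]
      x <- score_matrix[h, mk]; lab <- case[mk]
      base <- mis_grid[h, c("metabolite", "class_filter", "maf_bin", "stratum")]
      one <- function(or_obj, rule) {
        if (is.null(or_obj)) return(NULL)
        cbind(base, rule = rule, or = or_obj$or, ci_low = or_obj$ci[1],
              ci_high = or_obj$ci[2], n_used = or_obj$n_used,
              flag = or_obj$flag, stringsAsFactors = FALSE)
      }
      med <- tryCatch(dichotomized_or(x, lab, "median_of_controls"),
                      error = function(e) NULL)
      zero <- tryCatch(dichotomized_or(x, lab, "fixed_cut", cut = 0),
                       error = function(e) NULL)
      rbind(one(med, "median_of_controls"), one(zero, "fixed_cut_0"))
    })
    or_table <- do.call(rbind, or_rows)

    top <- which.min(mis_grid$adjusted_p)
    top_mask <- cell_masks[[top]]
    top_scores <- score_matrix[top, top_mask]
    dist_tab <- table(score = top_scores,
                      status = ifelse(case[top_mask], "case", "control"))
    top_cell <- list(cell = mis_grid[top, ], distribution = dist_tab,
                     distinct_combinations = NA_integer_)

    manifest <- list(
      package_version = as.character(utils::packageVersion("pathburden")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$rng_seed, n_permutations = B,
      config = unclass(config)[setdiff(names(unclass(config)), "variant_subsets")],
      stages = list(
        input = dim(genotypes),
        post_qc = dim(qc$genotypes),
        post_prune = dim(m),
        strata = strata))

    structure(list(qc = qc$report, ld = pruned, burden_table = burden_table,
                   gene_table = gene_table, mis_grid = mis_grid,
                   or_table = or_table, top_cell = top_cell,
                   model = model, config = config, manifest = manifest),
              class = "pathway_scan")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
print.pathway_scan <- function(x, ...) {
  cat("Pathway-informed collapsing scan\n")
  print(x$qc)
  cat(sprintf("LD pruning: %d variant(s) retained in %d group(s)\n",
              length(x$ld$retained), length(x$ld$groups)))
  cat(sprintf("Signed-score grid: %d cells, %d permutations (seed %d)\n",
              nrow(x$mis_grid), x$manifest$n_permutations, x$manifest$seed))
  top <- x$top_cell$cell
  cat(sprintf("Top cell: %s / %s %s / %s  raw p = %.4g, max(T) adjusted p = %.4g\n",
              top$metabolite, top$maf_bin, top$class_filter, top$stratum,
              top$raw_p, top$adjusted_p))
  invisible(x)
}

#' @export
summary.pathway_scan <- function(object, ...) {
  print(object)
  cat("\nSigned-score grid:\n")
  print(object$mis_grid[, c("metabolite", "class_filter", "maf_bin", "stratum",
                            "n_variants", "raw_p", "adjusted_p")],
        row.names = FALSE, digits = 3)
  cat("\nBurden sums (pathway-wide):\n")
  print(object$burden_table[, c("class_filter", "maf_bin", "stratum",
                                "n_variants", "case_mean", "control_mean", "p")],
        row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.pathway_scan <- function(x, ...) {
  g <- x$mis_grid
  lab <- paste(substr(g$metabolite, 1, 4),
               ifelse(g$maf_bin == "common", "C", "R"),
               ifelse(g$class_filter == "nonsynonymous", "Ns", "NC"),
               substr(g$stratum, 1, 4), sep = ".")
  graphics::barplot(-log10(g$raw_p), names.arg = lab, las = 2,
                    cex.names = 0.6, ylab = "-log10 permuted p",
                    main = "Signed-score grid", ...)
  graphics::abline(h = -log10(0.05), lty = 2)
  invisible(x)
}

#' Write a scan's report bundle as TSV + JSON manifest
#'
#' Every table gets a header comment line recording the seed and
#' permutation count it was produced under.
#'
#' @param scan a [run_pathway_scan()] result.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_report <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# pathburden v%s seed=%d permutations=%d",
                 scan$manifest$package_version, scan$manifest$seed,
                 scan$manifest$n_permutations)
  emit <- function(tab, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    path
  }
  files <- c(
    emit(scan$burden_table, "burden.tsv"),
    emit(scan$gene_table, "genes.tsv"),
    emit(scan$mis_grid, "mis_grid.tsv"),
    emit(scan$or_table, "odds_ratios.tsv"),
    emit(data.frame(dropped = c(scan$qc$dropped_samples, scan$qc$dropped_variants),
                    kind = rep(c("sample", "variant"),
                               c(scan$qc$n_dropped_samples,
                                 scan$qc$n_dropped_variants))),
         "qc.tsv"),
    emit(do.call(rbind, lapply(scan$ld$groups, function(g)
      data.frame(representative = g$representative,
                 member = g$members, r2 = unname(g$r2)))),
      "ld_groups.tsv"))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(scan$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, manifest_path))
}
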