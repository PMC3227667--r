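# Variant subsetting, burden sums, Metabolic Index Score.

test_that("subset selection applies class filter and stratum MAF bin, boundary common", {
  # MAF exactly 0.025: 2 minor alleles in 40 -> common under the >= rule
  m <- gm(cbind(c(1, 1, rep(0, 38)), c(1, rep(0, 39))))
  s <- sample_table(m)
  v <- variant_table(m)
  expect_equal(unname(compute_maf(m, s))[1], 0.025)
  sub <- subset_variants(v, m, s, class_filter = "nonsynonymous",
                         maf_bin = "common")
  expect_identical(sub$variant_ids, "V001")
  sub_rare <- subset_variants(v, m, s, class_filter = "nonsynonymous",
                              maf_bin = "rare")
  expect_identical(sub_rare$variant_ids, "V002")

  # synonymous variant excluded by a nonsynonymous filter
  v2 <- v; v2$functional_class[1] <- "synonymous"
  sub2 <- subset_variants(v2, m, s, class_filter = "nonsynonymous",
                          maf_bin = "all")
  expect_identical(sub2$variant_ids, "V002")

  # empty subsets are allowed and flagged by their zero length
  sub3 <- subset_variants(v, m, s, class_filter = "frameshift", maf_bin = "all")
  expect_length(sub3$variant_ids, 0)
})

test_that("subset membership equals a brute-force filter pass on 30 variants", {
  set.seed(19)
  m <- gm(matrix(sample(0:2, 50 * 30, replace = TRUE, prob = c(.8, .15, .05)),
                 50, 30))
  s <- sample_table(m, stratum = rep(c("Hispanic", "White"), 25))
  v <- variant_table(m)
  v$functional_class <- sample(functional_classes, 30, replace = TRUE)
  m <- orient_to_minor_allele(m, s, "Hispanic")
  sub <- subset_variants(v, m, s, class_filter = c("nonsynonymous", "truncation"),
                         maf_bin = "common", stratum = "Hispanic")
  maf <- oracle_maf(m, which(s$stratum == "Hispanic"))
  manual <- colnames(m)[v$functional_class %in% c("nonsynonymous", "truncation") &
                          maf >= 0.025]
  expect_identical(sub$variant_ids, manual)
})

test_that("burden sum tallies 1 per heterozygote and 2 per homozygote", {
  m <- gm(rbind(c(1, 0, 0), c(0, 0, 0), c(2, 1, 0)))
  ids <- colnames(m)
  b <- burden_sum(m, ids)
  expect_equal(as.numeric(b), c(1, 0, 3))

  # 50x200 random fixture equals the per-cell brute-force loop
  set.seed(23)
  m2 <- gm(matrix(sample(0:2, 50 * 200, replace = TRUE), 50, 200))
  ids2 <- sample(colnames(m2), 80)
  expect_equal(as.numeric(burden_sum(m2, ids2)), oracle_burden(m2, ids2))

  # missing cells require an explicit complete-case opt-in
  m3 <- gm(rbind(c(1, NA), c(0, 2)))
  expect_error(burden_sum(m3, colnames(m3)), "complete")
  expect_equal(as.numeric(burden_sum(m3, colnames(m3), complete_case = TRUE)), c(1, 2))
})

test_that("MIS worked cases: +2 beneficial homozygote, -1 competing heterozygote", {
  model <- toy_model()
  # one individual: homozygote at a PLUS1 variant, reference elsewhere
  m <- gm(rbind(c(2, 0, 0)), samples = "S1", variants = c("Vp", "Vq", "Vm"))
  v <- data.frame(variant_id = c("Vp", "Vq", "Vm"),
                  gene = c("PLUS1", "PLUS2", "MINUS1"),
                  functional_class = "nonsynonymous", stringsAsFactors = FALSE)
  expect_equal(as.numeric(metabolic_index_score(m, colnames(m), v, model, "purine")), 2)

  # heterozygote at a competing gene only
  m2 <- gm(rbind(c(0, 0, 1)), samples = "S1", variants = c("Vp", "Vq", "Vm"))
  expect_equal(as.numeric(metabolic_index_score(m2, colnames(m2), v, model, "purine")), -1)

  # het in a + gene and minor homozygote in a - gene: +1 - 2 = -1
  m3 <- gm(rbind(c(1, 0, 2)), samples = "S1", variants = c("Vp", "Vq", "Vm"))
  expect_equal(as.numeric(metabolic_index_score(m3, colnames(m3), v, model, "purine")), -1)

  # variants in genes unsigned for the metabolite contribute 0
  v4 <- v; v4$gene[2] <- "UNSIGNED"
  m4 <- gm(rbind(c(1, 2, 0)), samples = "S1", variants = c("Vp", "Vq", "Vm"))
  expect_equal(as.numeric(metabolic_index_score(m4, colnames(m4), v4, model, "purine")), 1)
})

test_that("compartment filter reproduces the four-gene cytoplasmic purine score", {
  model <- default_pathway_model()
  genes <- c("ALDH1L1", "MTHFD1", "ATIC", "GART", "MTHFD2", "MTFMT")
  set.seed(41)
  m <- gm(matrix(sample(0:2, 30 * 6, replace = TRUE), 30, 6))
  v <- variant_table(m); v$gene <- genes
  mis_cyto <- metabolic_index_score(m, colnames(m), v, model, "purine",
                                    compartment = "cytoplasmic")
  # manual four-gene construction: ALDH1L1 -, MTHFD1/ATIC/GART +
  manual <- -m[, 1] + m[, 2] + m[, 3] + m[, 4]
  expect_equal(as.numeric(mis_cyto), unname(manual))
  expect_setequal(attr(mis_cyto, "provenance")$signed_variants, colnames(m)[1:4])
})

test_that("MIS properties: antisymmetry, decomposition, burden reduction, bounds", {
  set.seed(29)
  for (rep in 1:5) {
    co <- random_cohort(n = 25, v = 16, seed = rep, n_genes = 4)
    signs <- sample(c(1, -1), 4, replace = TRUE)
    model <- pathway_model(data.frame(
      metabolite = "purine", gene = paste0("G", 1:4),
      sign = ifelse(signs > 0, "+", "-"), compartment = "cyto"))
    flipped <- pathway_model(data.frame(
      metabolite = "purine", gene = paste0("G", 1:4),
      sign = ifelse(signs > 0, "-", "+"), compartment = "cyto"))
    mis <- metabolic_index_score(co$genotypes, colnames(co$genotypes),
                                 co$variants, model, "purine")
    mis_neg <- metabolic_index_score(co$genotypes, colnames(co$genotypes),
                                     co$variants, flipped, "purine")
    expect_equal(as.numeric(mis_neg), -as.numeric(mis))  # sign antisymmetry

    plus_genes <- paste0("G", which(signs > 0))
    plus_ids <- co$variants$variant_id[co$variants$gene %in% plus_genes]
    minus_ids <- setdiff(co$variants$variant_id, plus_ids)
    bp <- if (length(plus_ids)) burden_sum(co$genotypes, plus_ids)
          else numeric(nrow(co$genotypes))
    bm <- if (length(minus_ids)) burden_sum(co$genotypes, minus_ids)
          else numeric(nrow(co$genotypes))
    expect_equal(as.numeric(mis), as.numeric(bp) - as.numeric(bm))   # decomposition

    expect_true(all(mis == round(mis)))
    expect_true(all(abs(mis) <= 2 * ncol(co$genotypes)))  # bounds
  }

  # all signs +1, no compartment filter: MIS == burden over signed genes
  co <- random_cohort(n = 20, v = 12, seed = 99, n_genes = 3)
  all_plus <- pathway_model(data.frame(
    metabolite = "purine", gene = paste0("G", 1:3), sign = "+",
    compartment = "cyto"))
  expect_equal(
    as.numeric(metabolic_index_score(co$genotypes, colnames(co$genotypes),
                                     co$variants, all_plus, "purine")),
    as.numeric(burden_sum(co$genotypes, colnames(co$genotypes))))

  # subset additivity of the burden over a disjoint union
  ids <- colnames(co$genotypes)
  aa <- ids[1:5]; bb <- ids[6:12]
  expect_equal(burden_sum(co$genotypes, c(aa, bb)),
               burden_sum(co$genotypes, aa) + burden_sum(co$genotypes, bb),
               ignore_attr = TRUE)
})

test_that("metabolite absent from the model is rejected", {
  co <- random_cohort(n = 5, v = 3, seed = 1)
  expect_error(
    metabolic_index_score(co$genotypes, colnames(co$genotypes), co$variants,
                          toy_model(), "serine"),
    "absent")
})

test_that("distinct genotype combinations are counted as unique dosage vectors", {
  m <- gm(matrix(rep(c(0L, 1L, 2L), each = 3), 3, 3, byrow = FALSE))
  m[] <- 1L
  expect_equal(distinct_genotype_combinations(m, colnames(m)), 1)

  m2 <- gm(rbind(c(0, 1), c(1, 0), c(2, 2)))
  expect_equal(distinct_genotype_combinations(m2, colnames(m2)), 3)

  set.seed(61)
  m3 <- gm(matrix(sample(0:2, 40 * 9, replace = TRUE), 40, 9))
  oracle <- length(unique(lapply(seq_len(40), function(i) unname(m3[i, ]))))
  expect_equal(distinct_genotype_combinations(m3, colnames(m3)), oracle)
  # sample filter restricts the rows considered
  expect_equal(distinct_genotype_combinations(m3, colnames(m3), 1:10),
               length(unique(lapply(1:10, function(i) unname(m3[i, ])))))
})
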