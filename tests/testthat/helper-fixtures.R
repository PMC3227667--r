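# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# genotype matrix from a plain numeric matrix, with default ids
gm <- function(m, samples = NULL, variants = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  rownames(m) <- samples %||% sprintf("S%03d", seq_len(nrow(m)))
  colnames(m) <- variants %||% sprintf("V%03d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample table for a matrix: first n_cases rows cases, one stratum unless given
sample_table <- function(m, n_cases = floor(nrow(m) / 2), stratum = "Hispanic") {
  n <- nrow(m)
  data.frame(sample_id = rownames(m),
             status = rep(c("case", "control"), c(n_cases, n - n_cases)),
             stratum = rep_len(stratum, n),
             stringsAsFactors = FALSE)
}

# annotation for a matrix: all variants in one gene/class unless given
variant_table <- function(m, gene = "GENE1", functional_class = "nonsynonymous") {
  data.frame(variant_id = colnames(m),
             gene = rep_len(gene, ncol(m)),
             functional_class = rep_len(functional_class, ncol(m)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

# one-gene-per-sign toy pathway model
toy_model <- function(metabolite = "purine") {
  pathway_model(data.frame(
    metabolite = metabolite,
    gene = c("PLUS1", "PLUS2", "MINUS1"),
    sign = c("+", "+", "-"),
    compartment = c("cyto", "mito", "cyto"),
    stringsAsFactors = FALSE))
}

# small random complete cohort for property tests
random_cohort <- function(n = 40, v = 20, seed = 1, n_genes = 4) {
  set.seed(seed)
  m <- gm(matrix(sample(0:2, n * v, replace = TRUE, prob = c(.7, .2, .1)), n, v))
  genes <- paste0("G", rep_len(seq_len(n_genes), v))
  variants <- variant_table(m)
  variants$gene <- genes
  list(genotypes = m, variants = variants, samples = sample_table(m))
}

# independent brute-force oracles -------------------------------------------

# brute-force MAF: tally minor alleles cell by cell
oracle_maf <- function(m, rows = seq_len(nrow(m))) {
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[rows, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    sum(x) / (2 * length(x))
  }, numeric(1))
}

# brute-force burden: explicit double loop
oracle_burden <- function(m, ids) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m)))
    for (j in ids) out[i] <- out[i] + m[i, j]
  out
}

# Welch t from the closed formula
oracle_welch_t <- function(x1, x0) {
  (mean(x1) - mean(x0)) /
    sqrt(var(x1) / length(x1) + var(x0) / length(x0))
}

# exhaustive two-sided permutation p for a statistic function
oracle_exhaustive_p <- function(scores, case, stat_fn) {
  n <- length(scores)
  n1 <- sum(case)
  obs <- abs(stat_fn(scores[case], scores[!case]))
  idx <- combn(n, n1)
  hits <- 0L
  for (k in seq_len(ncol(idx))) {
    g <- rep(FALSE, n); g[idx[, k]] <- TRUE
    if (abs(stat_fn(scores[g], scores[!g])) >= obs - 1e-10) hits <- hits + 1L
  }
  hits / ncol(idx)
}
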