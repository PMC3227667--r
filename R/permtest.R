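# Label-permutation inference. The engine is vectorized over permutations:
# a permutation is a 0/1 column of a label matrix, and the t and
# Mann-Whitney statistics for all permutations come out of one crossprod.
# Group sizes are preserved by construction (labels are shuffled, never
# redrawn), optionally within strata.

#' @keywords internal
#' @noRd
as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (!all(l %in% c("case", "control")))
    stop("labels must be logical or 'case'/'control'")
  l == "case"
}

#' @keywords internal
#' @noRd
ks_sup_distance <- function(x, g) {
  n1 <- sum(g); n0 <- length(g) - n1
  ord <- order(x)
  gg <- g[ord]; xs <- x[ord]
  cdf1 <- cumsum(gg) / n1
  cdf0 <- cumsum(!gg) / n0
  last <- c(xs[-1] != xs[-length(xs)], TRUE)  # evaluate at distinct values only
  max(abs(cdf1 - cdf0)[last])
}

# Centered statistics for every column of a 0/1 label matrix L (1 = case).
# Centered means symmetric about 0 under exchangeability: Welch t as-is,
# Mann-Whitney U minus its null mean n1*n0/2, KS D (non-negative) as-is.
#' @keywords internal
#' @noRd
stats_for_labelmat <- function(x, L, method) {
  n <- length(x)
  n1 <- colSums(L); n0 <- n - n1
  if (method == "t") {
    s1 <- as.vector(crossprod(L, x))
    ss1 <- as.vector(crossprod(L, x^2))
    s0 <- sum(x) - s1; ss0 <- sum(x^2) - ss1
    m1 <- s1 / n1; m0 <- s0 / n0
    v1 <- pmax(ss1 - n1 * m1^2, 0) / pmax(n1 - 1, 1)
    v0 <- pmax(ss0 - n0 * m0^2, 0) / pmax(n0 - 1, 1)
    se <- sqrt(v1 / n1 + v0 / n0)
    d <- m1 - m0
    ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  } else if (method == "mannwhitney") {
    r <- rank(x)
    u1 <- as.vector(crossprod(L, r)) - n1 * (n1 + 1) / 2
    u1 - n1 * n0 / 2
  } else if (method == "ks") {
    vapply(seq_len(ncol(L)), function(b) ks_sup_distance(x, L[, b] == 1),
           numeric(1))
  } else stop("unknown method: ", method)
}

#' @keywords internal
#' @noRd
observed_centered_stat <- function(x, case, method) {
  stats_for_labelmat(x, matrix(as.numeric(case), ncol = 1), method)
}

# Random label matrix preserving case counts, optionally within strata.
#' @keywords internal
#' @noRd
perm_label_matrix <- function(case, B, strata = NULL) {
  n <- length(case)
  L <- matrix(0, n, B)
  if (is.null(strata)) {
    n1 <- sum(case)
    for (b in seq_len(B)) L[sample.int(n, n1), b] <- 1
  } else {
    for (s in unique(strata)) {
      rows <- which(strata == s)
      k <- sum(case[rows])
      if (k == 0L) next
      for (b in seq_len(B)) L[rows[sample.int(length(rows), k)], b] <- 1
    }
  }
  L
}

#' @keywords internal
#' @noRd
n_arrangements <- function(case, strata = NULL) {
  if (is.null(strata)) return(choose(length(case), sum(case)))
  prod(vapply(unique(strata), function(s) {
    rows <- strata == s
    choose(sum(rows), sum(case & rows))
  }, numeric(1)))
}

# Centered statistics over every case/control arrangement (combn order).
#' @keywords internal
#' @noRd
exhaustive_stats <- function(x, n1, method) {
  n <- length(x)
  idx <- utils::combn(n, n1)
  C <- ncol(idx)
  n0 <- n - n1
  if (method == "t") {
    X1 <- matrix(x[idx], nrow = n1)
    s1 <- colSums(X1); ss1 <- colSums(X1^2)
    s0 <- sum(x) - s1; ss0 <- sum(x^2) - ss1
    m1 <- s1 / n1; m0 <- s0 / n0
    v1 <- pmax(ss1 - n1 * m1^2, 0) / max(n1 - 1, 1)
    v0 <- pmax(ss0 - n0 * m0^2, 0) / max(n0 - 1, 1)
    se <- sqrt(v1 / n1 + v0 / n0)
    d <- m1 - m0
    st <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  } else if (method == "mannwhitney") {
    r <- rank(x)
    R1 <- matrix(r[idx], nrow = n1)
    st <- colSums(R1) - n1 * (n1 + 1) / 2 - n1 * n0 / 2
  } else {
    st <- vapply(seq_len(C), function(b) {
      g <- rep(FALSE, n); g[idx[, b]] <- TRUE
      ks_sup_distance(x, g)
    }, numeric(1))
  }
  list(stats = st, n_arrangements = C)
}

#' Two-sample statistic for a score vector
#'
#' * `t`: Welch (unequal-variance) t on the case/control means.
#' * `mannwhitney`: Mann-Whitney U for the case group
#'   (`U = R1 - n1(n1+1)/2`).
#' * `ks`: Kolmogorov-Smirnov sup-distance between the two empirical CDFs.
#'
#' @param scores numeric per-individual scores.
#' @param labels `"case"`/`"control"` vector (or logical, `TRUE` = case).
#' @param method `"t"`, `"mannwhitney"` or `"ks"`.
#' @return the raw statistic (one number).
#' @export
two_sample_stat <- function(scores, labels, method = c("t", "mannwhitney", "ks")) {
  method <- match.arg(method)
  case <- as_case_logical(labels)
  if (!any(case) || all(case)) stop("both groups must be non-empty")
  if (method == "t") {
    if (stats::var(scores) == 0)
      stop("zero pooled variance: the t statistic is undefined; ",
           "use method = 'mannwhitney' or a permutation test of means")
    return(unname(observed_centered_stat(scores, case, "t")))
  }
  if (method == "mannwhitney") {
    n1 <- sum(case); n0 <- sum(!case)
    return(unname(observed_centered_stat(scores, case, "mannwhitney") + n1 * n0 / 2))
  }
  ks_sup_distance(scores, case)
}

#' Permutation p-value from case-control label shuffling
#'
#' The observed statistic is compared with its distribution under random
#' reassignment of case/control labels (group sizes fixed). When the
#' number of distinct label arrangements is at most `exhaustive_cap` (and
#' no stratification is requested) the full enumeration is used and the
#' p-value is the exact proportion `b / C`; otherwise `B` Monte-Carlo
#' permutations give the add-one estimator `p = (b + 1) / (B + 1)`, which
#' can never be zero. Two-sided comparisons use the magnitude of the
#' centered statistic (t as-is, U centered at `n1 n0 / 2`, KS D). Scores
#' that are all equal return `p = 1` by convention.
#'
#' @inheritParams two_sample_stat
#' @param B number of Monte-Carlo permutations.
#' @param seed integer seed (`NULL` leaves the RNG stream alone).
#' @param strata optional stratum labels: permutations then shuffle labels
#'   within each stratum, preserving per-stratum case/control ratios
#'   (Monte-Carlo only).
#' @param sided `"two"` (default), `"greater"` or `"less"`, on the
#'   centered statistic.
#' @param exhaustive_cap arrangement count at or below which exhaustive
#'   enumeration replaces Monte-Carlo sampling (default 1e6).
#' @return object of class `perm_test`: observed raw and centered
#'   statistics, method, permutation count, exceedance count and `p.value`.
#' @export
permutation_pvalue <- function(scores, labels, method = c("t", "mannwhitney", "ks"),
                               B = 1000L, seed = NULL, strata = NULL,
                               sided = c("two", "greater", "less"),
                               exhaustive_cap = 1e6) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  case <- as_case_logical(labels)
  if (!any(case) || all(case)) stop("both groups must be non-empty")
  degenerate <- length(unique(scores)) == 1L
  if (degenerate) {
    return(structure(list(statistic = 0, centered = 0, method = method,
                          exhaustive = TRUE, n_permutations = 1L,
                          exceedance = 1L, p.value = 1, sided = sided,
                          seed = seed, degenerate = TRUE),
                     class = "perm_test"))
  }
  obs <- observed_centered_stat(scores, case, method)
  exceeds <- function(st) {
    tol <- 1e-8 * max(1, abs(obs))
    switch(sided,
           two     = abs(st) >= abs(obs) - tol,
           greater = st >= obs - tol,
           less    = st <= obs + tol)
  }
  C <- n_arrangements(case, strata)
  if (is.null(strata) && C <= exhaustive_cap) {
    ex <- exhaustive_stats(scores, sum(case), method)
    b <- sum(exceeds(ex$stats))
    res <- list(exhaustive = TRUE, n_permutations = ex$n_arrangements,
                exceedance = b, p.value = b / ex$n_arrangements)
  } else {
    if (!is.null(seed)) set.seed(seed)
    L <- perm_label_matrix(case, B, strata)
    st <- stats_for_labelmat(scores, L, method)
    b <- sum(exceeds(st))
    res <- list(exhaustive = FALSE, n_permutations = as.integer(B),
                exceedance = b, p.value = (b + 1) / (B + 1))
  }
  raw <- if (method == "mannwhitney") obs + sum(case) * sum(!case) / 2 else obs
  structure(c(list(statistic = unname(raw), centered = unname(obs),
                   method = method, sided = sided, seed = seed,
                   degenerate = FALSE, stratified = !is.null(strata)),
              res),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s-sided): statistic = %.4g, p = %.4g\n",
              x$method, x$sided, x$statistic, x$p.value))
  cat(sprintf("  %s arrangements: %d, exceedances: %d%s\n",
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations, x$exceedance,
              if (isTRUE(x$stratified)) " (stratified)" else ""))
  invisible(x)
}

#' Single-step max(T) family-wise adjustment
#'
#' All hypotheses share one label-permutation stream. For every
#' permutation the maximum of the absolute centered statistics over the
#' family is recorded; the adjusted p-value of hypothesis `h` is the
#' exceedance rate of that maximum over `|obs_h|` (add-one Monte-Carlo
#' estimator, exact proportion under exhaustive enumeration). Raw
#' p-values come from the same stream, so a single-hypothesis family has
#' adjusted equal to raw. Hypotheses may be restricted to subsets of
#' individuals via `masks` (e.g. stratum-specific cells of an analysis
#' grid under one cohort-wide stratified stream); degenerate (constant)
#' score rows carry statistic 0 throughout.
#'
#' @param score_matrix hypotheses x individuals numeric matrix.
#' @param labels cohort case/control labels (length = ncol).
#' @param method one method for all hypotheses or a vector per hypothesis
#'   (`"t"`, `"mannwhitney"`, `"ks"`).
#' @param B Monte-Carlo permutation count.
#' @param seed integer seed.
#' @param strata optional stratum labels for stratified permutation.
#' @param masks optional list (one logical vector per hypothesis) of
#'   individuals each hypothesis is computed on; default all.
#' @param exhaustive_cap as in [permutation_pvalue()] (unstratified,
#'   unmasked families only).
#' @return object of class `maxt_result` with a `table` data.frame
#'   (statistic, raw_p, adjusted_p per hypothesis).
#' @export
maxt_adjust <- function(score_matrix, labels, method = "t", B = 1000L,
                        seed = NULL, strata = NULL, masks = NULL,
                        exhaustive_cap = 1e6) {
  if (!is.matrix(score_matrix)) score_matrix <- rbind(score_matrix)
  H <- nrow(score_matrix)
  n <- ncol(score_matrix)
  case <- as_case_logical(labels)
  if (length(case) != n) stop("labels length must equal ncol(score_matrix)")
  method <- rep_len(method, H)
  if (is.null(masks)) masks <- rep(list(rep(TRUE, n)), H)

  h_stats <- function(L_full) {
    # |centered stat| per hypothesis (rows) for each label column
    out <- matrix(0, H, ncol(L_full))
    for (h in seq_len(H)) {
      mk <- masks[[h]]
      x <- score_matrix[h, mk]
      if (length(unique(x)) == 1L) next  # degenerate row -> statistic 0
      out[h, ] <- abs(stats_for_labelmat(x, L_full[mk, , drop = FALSE], method[h]))
    }
    out
  }

  obs <- as.vector(h_stats(matrix(as.numeric(case), ncol = 1)))
  tol <- 1e-8 * pmax(1, obs)

  simple <- is.null(strata) && all(vapply(masks, all, logical(1)))
  C <- n_arrangements(case, strata)
  if (simple && C <= exhaustive_cap) {
    idx <- utils::combn(n, sum(case))
    L <- matrix(0, n, ncol(idx))
    L[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = nrow(idx)))] <- 1
    st <- h_stats(L)
    denom <- ncol(idx)
    raw <- vapply(seq_len(H), function(h) sum(st[h, ] >= obs[h] - tol[h]) / denom,
                  numeric(1))
    mx <- apply(st, 2, max)
    adj <- vapply(seq_len(H), function(h) sum(mx >= obs[h] - tol[h]) / denom,
                  numeric(1))
    exhaustive <- TRUE; nperm <- denom
  } else {
    if (!is.null(seed)) set.seed(seed)
    L <- perm_label_matrix(case, B, strata)
    st <- h_stats(L)
    raw <- vapply(seq_len(H), function(h) (sum(st[h, ] >= obs[h] - tol[h]) + 1) / (B + 1),
                  numeric(1))
    mx <- apply(st, 2, max)
    adj <- vapply(seq_len(H), function(h) (sum(mx >= obs[h] - tol[h]) + 1) / (B + 1),
                  numeric(1))
    exhaustive <- FALSE; nperm <- as.integer(B)
  }
  adj <- pmax(adj, raw)  # monotonicity guard against Monte-Carlo tie noise
  structure(list(table = data.frame(
    hypothesis = if (!is.null(rownames(score_matrix))) rownames(score_matrix)
                 else paste0("h", seq_len(H)),
    statistic = obs, method = method, raw_p = raw, adjusted_p = adj,
    stringsAsFactors = FALSE),
    n_permutations = nperm, exhaustive = exhaustive, seed = seed,
    stratified = !is.null(strata)), class = "maxt_result")
}

#' @export
print.maxt_result <- function(x, ...) {
  cat(sprintf("max(T) adjustment over %d hypotheses (%s, %d permutations%s)\n",
              nrow(x$table), if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations,
              if (isTRUE(x$stratified)) ", stratified" else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
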