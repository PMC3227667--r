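# Two-sample statistics, permutation p-values, max(T), logistic
# association, dichotomized odds ratios.

test_that("two-sample statistics match their closed forms", {
  # identical distributions: KS sup-distance is 0
  x <- c(1, 2, 3, 1, 2, 3)
  lab <- rep(c("case", "control"), each = 3)
  expect_equal(two_sample_stat(x, lab, "ks"), 0)

  # complete separation with cases low: U = 0
  y <- c(0, 1, 2, 10, 11, 12)
  expect_equal(two_sample_stat(y, lab, "mannwhitney"), 0)

  # hand-sized Welch t against the closed formula
  set.seed(3)
  z <- rnorm(14)
  lab2 <- rep(c("case", "control"), c(6, 8))
  expect_equal(two_sample_stat(z, lab2, "t"),
               oracle_welch_t(z[1:6], z[7:14]))

  # KS against stats::ks.test on tie-free data
  expect_equal(two_sample_stat(z, lab2, "ks"),
               unname(suppressWarnings(ks.test(z[1:6], z[7:14]))$statistic))

  # zero pooled variance under t is an error pointing at the alternatives
  expect_error(two_sample_stat(rep(2, 6), lab, "t"), "mannwhitney")
})

test_that("exhaustive permutation p matches full enumeration", {
  # separated groups of 3+3: only the 2 extreme assignments reach |t|
  scores <- c(10, 11, 12, 0, 1, 2)
  lab <- rep(c("case", "control"), each = 3)
  pt <- permutation_pvalue(scores, lab, "t")
  expect_true(pt$exhaustive)
  expect_equal(pt$n_permutations, 20L)
  expect_equal(pt$p.value, 2 / 20)

  # agrees with an independent enumeration oracle for each method
  set.seed(8)
  sc <- rnorm(9)
  lab9 <- rep(c("case", "control"), c(4, 5))
  for (method in c("t", "mannwhitney")) {
    stat_fn <- if (method == "t") oracle_welch_t
      else function(x1, x0) {
        r <- rank(c(x1, x0))
        sum(r[seq_along(x1)]) - length(x1) * (length(x1) + 1) / 2 -
          length(x1) * length(x0) / 2
      }
    expect_equal(permutation_pvalue(sc, lab9, method)$p.value,
                 oracle_exhaustive_p(sc, lab9 == "case", stat_fn),
                 info = method)
  }

  # degenerate scores: p = 1 by convention
  expect_equal(permutation_pvalue(rep(4, 8),
                                  rep(c("case", "control"), 4), "t")$p.value, 1)
})

test_that("Monte-Carlo permutation agrees with enumeration and is seed-stable", {
  set.seed(14)
  sc <- rnorm(12)
  lab <- rep(c("case", "control"), 6)
  exact <- permutation_pvalue(sc, lab, "t")$p.value
  mc <- permutation_pvalue(sc, lab, "t", B = 4000, seed = 5,
                           exhaustive_cap = 10)   # force Monte-Carlo
  expect_false(mc$exhaustive)
  mc_sd <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(mc$p.value - exact), 3 * mc_sd + 2 / 4000)
  mc2 <- permutation_pvalue(sc, lab, "t", B = 4000, seed = 5,
                            exhaustive_cap = 10)
  expect_identical(mc$p.value, mc2$p.value)
})

test_that("permutation p-values are valid under the null", {
  set.seed(100)
  n_sim <- 400
  hits <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    sc <- rnorm(40)
    lab <- sample(rep(c("case", "control"), 20))
    hits[i] <- permutation_pvalue(sc, lab, "t", B = 99,
                                  exhaustive_cap = 1)$p.value <= 0.05
  }
  # binomial 99% bound around alpha = 0.05 (B = 99 makes p <= .05 achievable at b <= 4)
  expect_lt(mean(hits), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("joint relabeling of scores and labels leaves results unchanged", {
  set.seed(44)
  sc <- rnorm(16)
  lab <- rep(c("case", "control"), 8)
  perm <- sample(16)
  p1 <- permutation_pvalue(sc, lab, "mannwhitney")
  p2 <- permutation_pvalue(sc[perm], lab[perm], "mannwhitney")
  expect_equal(p1$p.value, p2$p.value)
  expect_equal(p1$statistic, p2$statistic)
})

test_that("max(T) adjustment: identity, duplicates, enumeration oracle, monotonicity", {
  set.seed(52)
  sc <- rnorm(12)
  lab <- rep(c("case", "control"), 6)
  one <- maxt_adjust(rbind(sc), lab, "t")
  expect_equal(one$table$adjusted_p, one$table$raw_p)

  two <- maxt_adjust(rbind(sc, sc), lab, "t")
  expect_equal(two$table$adjusted_p[1], two$table$adjusted_p[2])
  expect_equal(two$table$adjusted_p, two$table$raw_p)

  # 3 hypotheses x 10 individuals: brute-force max-distribution oracle
  scores <- matrix(rnorm(30), 3, 10)
  lab10 <- rep(c("case", "control"), each = 5)
  res <- maxt_adjust(scores, lab10, "t")
  expect_true(res$exhaustive)
  idx <- combn(10, 5)
  stat_mat <- sapply(seq_len(ncol(idx)), function(k) {
    g <- rep(FALSE, 10); g[idx[, k]] <- TRUE
    apply(scores, 1, function(x) abs(oracle_welch_t(x[g], x[!g])))
  })  # hypotheses x arrangements
  obs <- apply(scores, 1, function(x)
    abs(oracle_welch_t(x[lab10 == "case"], x[lab10 == "control"])))
  maxima <- apply(stat_mat, 2, max)
  oracle_adj <- sapply(1:3, function(h) mean(maxima >= obs[h] - 1e-10))
  oracle_raw <- sapply(1:3, function(h) mean(stat_mat[h, ] >= obs[h] - 1e-10))
  expect_equal(res$table$adjusted_p, oracle_adj)
  expect_equal(res$table$raw_p, oracle_raw)

  # adjusted >= raw on random Monte-Carlo families, degenerate rows tolerated
  scores2 <- rbind(matrix(rnorm(80), 4, 20), rep(1, 20))
  lab20 <- rep(c("case", "control"), 10)
  res2 <- maxt_adjust(scores2, lab20, "t", B = 300, seed = 6)
  expect_true(all(res2$table$adjusted_p >= res2$table$raw_p))
  expect_true(all(res2$table$adjusted_p <= 1))
})

test_that("max(T) controls family-wise error on all-null families", {
  set.seed(71)
  n_sim <- 300
  fwer <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    scores <- matrix(rnorm(3 * 30), 3, 30)
    lab <- sample(rep(c("case", "control"), 15))
    res <- maxt_adjust(scores, lab, "t", B = 99, exhaustive_cap = 1)
    fwer[i] <- any(res$table$adjusted_p <= 0.05)
  }
  expect_lt(mean(fwer), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("single-variant logistic association behaves at the null and under separation", {
  set.seed(81)
  n <- 2000
  dosage <- rbinom(n, 2, 0.3)
  lab <- sample(rep(c("case", "control"), n / 2))
  fit <- single_variant_assoc(dosage, lab)
  expect_equal(fit$method, "ml")
  expect_lt(abs(log(fit$or)), 0.25)
  expect_true(fit$ci[1] < fit$or && fit$or < fit$ci[2])

  # stratum adjustment runs and returns a finite estimate
  strat <- sample(c("A", "B"), n, replace = TRUE)
  fit_adj <- single_variant_assoc(dosage, lab, stratum = strat)
  expect_true(is.finite(fit_adj$or))

  # a lone carrier who is a case: separation -> Firth fallback, finite OR
  dosage2 <- c(1, rep(0, 99))
  lab2 <- c("case", rep(c("case", "control"), c(49, 50)))
  fit2 <- single_variant_assoc(dosage2, lab2)
  expect_equal(fit2$method, "firth")
  expect_equal(fit2$flag, "separation")
  expect_true(is.finite(fit2$or) && fit2$or > 0)

  # monomorphic dosage: flagged, no estimate
  fit3 <- single_variant_assoc(rep(0, 50), rep(c("case", "control"), 25))
  expect_equal(fit3$flag, "monomorphic")
  expect_true(is.na(fit3$or))
})

test_that("logistic association recovers a known per-allele log-odds", {
  set.seed(91)
  n <- 5000
  covered <- logical(25)
  est <- numeric(25)
  for (i in seq_along(covered)) {
    dosage <- rbinom(n, 2, 0.3)
    p <- plogis(-0.3 + 0.5 * dosage)
    lab <- ifelse(rbinom(n, 1, p) == 1, "case", "control")
    fit <- single_variant_assoc(dosage, lab)
    est[i] <- log(fit$or)
    covered[i] <- log(fit$ci[1]) <= 0.5 && 0.5 <= log(fit$ci[2])
  }
  expect_gt(mean(covered), 0.8)         # ~95% nominal
  expect_equal(mean(est), 0.5, tolerance = 0.05)
})

test_that("dichotomized odds ratios match the closed form with a Woolf CI", {
  # null 2x2 table
  sc <- rep(c(0, 1), 20)
  lab <- rep(c("case", "control"), each = 20)
  or0 <- dichotomized_or(sc, lab, rule = "fixed_cut", cut = 0.5, ties = "below")
  expect_equal(or0$or, 1)
  expect_true(or0$ci[1] < 1 && 1 < or0$ci[2])

  # a=5, b=20, c=20, d=5 by construction
  sc2 <- c(rep(1, 5), rep(0, 20), rep(1, 20), rep(0, 5))
  lab2 <- rep(c("case", "control"), each = 25)
  or2 <- dichotomized_or(sc2, lab2, rule = "fixed_cut", cut = 0.5, ties = "below")
  expect_equal(or2$or, 25 / 400)
  expect_equal(or2$ci,
               exp(log(0.0625) + c(-1, 1) * qnorm(0.975) *
                     sqrt(1 / 5 + 1 / 20 + 1 / 20 + 1 / 5)))
  expect_true(is.na(or2$flag))

  # control median rule: scores {1,2,2,3} -> cut 2, ties below
  sc3 <- c(3, 3, 1, 2, 1, 2, 2, 3)
  lab3 <- rep(c("case", "control"), each = 4)
  or3 <- dichotomized_or(sc3, lab3, rule = "median_of_controls")
  expect_match(or3$cut, "= 2")
  expect_equal(unname(or3$table["case", "above"]), 2)   # the two 3s
  expect_equal(unname(or3$table["control", "above"]), 1)

  # Haldane correction triggers iff a zero cell exists
  # (cases: 15 above / 0 below; controls: 3 above / 12 below)
  lab4 <- rep(c("case", "control"), each = 15)
  sc4 <- c(rep(1, 15), rep(1, 3), rep(0, 12))
  or4 <- dichotomized_or(sc4, lab4, rule = "fixed_cut", cut = 0.5, ties = "below")
  expect_equal(or4$flag, "haldane_correction")
  expect_equal(or4$or, (15.5 * 12.5) / (0.5 * 3.5))

  # extremes rule drops the middle of the distribution
  sc5 <- c(-2, -1, 0, 1, 4, 5, -1, 0, 1, 2, 4, 6)
  lab5 <- rep(c("case", "control"), each = 6)
  or5 <- dichotomized_or(sc5, lab5, rule = "extremes", lo = -1, hi = 4)
  expect_equal(or5$n_used, sum(sc5 <= -1 | sc5 >= 4))

  # empty arm after dichotomization is an error
  expect_error(dichotomized_or(rep(1, 10), rep(c("case", "control"), 5),
                               rule = "fixed_cut", cut = 5), "arm")
})
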