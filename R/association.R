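# Single-variant log-additive association and dichotomized odds ratios.

# Firth penalized logistic regression (Newton-Raphson on the modified
# score U*(b) = X'(y - p + h(1/2 - p))). Used as the fallback when the
# ML fit shows (quasi-)separation, which is routine for singletons in a
# case-control resequencing study.
#' @keywords internal
#' @noRd
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  p_dim <- ncol(X)
  beta <- rep(0, p_dim)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) return(NULL)
    h <- rowSums((X %*% info_inv) * XW)        # hat diagonal
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- info_inv %*% U
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))  # damp
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  vcov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  if (is.null(vcov)) return(NULL)
  list(coefficients = beta, vcov = vcov, iterations = it)
}

#' Single-variant log-additive association
#'
#' Logistic regression of case status on the 0/1/2 minor-allele dosage
#' (log-additive inheritance), optionally adjusted for race-ethnicity via
#' stratum indicator covariates. The per-allele odds ratio is
#' `exp(coefficient)` with a Wald 95% CI and p-value. When the ML fit
#' shows separation (non-convergence, exploding coefficient or fitted
#' probabilities at 0/1), the fit switches to Firth penalized likelihood
#' and the result is flagged. Monomorphic variants return a flagged,
#' estimate-free result.
#'
#' @param dosage per-individual dosage in `{0, 1, 2}`.
#' @param labels case/control labels.
#' @param stratum optional stratum labels used as adjustment covariates.
#' @return object of class `variant_assoc`: `or`, `ci` (length-2), `p`,
#'   `beta`, `se`, `method` (`"ml"`, `"firth"` or `"none"`), `flag`.
#' @export
single_variant_assoc <- function(dosage, labels, stratum = NULL) {
  case <- as_case_logical(labels)
  ok <- !is.na(dosage)
  dosage <- dosage[ok]; case <- case[ok]
  if (!is.null(stratum)) stratum <- factor(stratum[ok])
  if (length(unique(dosage)) == 1L) {
    return(structure(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                          p = NA_real_, beta = NA_real_, se = NA_real_,
                          method = "none", flag = "monomorphic"),
                     class = "variant_assoc"))
  }
  X <- if (is.null(stratum) || nlevels(stratum) < 2L)
    cbind(1, dosage)
  else
    cbind(1, dosage, stats::model.matrix(~stratum)[, -1, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(case), family = stats::binomial()))
  p_hat <- fit$fitted.values
  separated <- !fit$converged || abs(fit$coefficients[2]) > 10 ||
    any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8)
  if (separated) {
    ff <- firth_logistic(X, as.numeric(case))
    if (is.null(ff)) {
      return(structure(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                            p = NA_real_, beta = NA_real_, se = NA_real_,
                            method = "none", flag = "fit_failed"),
                       class = "variant_assoc"))
    }
    beta <- ff$coefficients[2]
    se <- sqrt(ff$vcov[2, 2])
    method <- "firth"; flag <- "separation"
  } else {
    beta <- fit$coefficients[2]
    # Wald covariance from the final IRLS weights
    w <- p_hat * (1 - p_hat)
    vc <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
    if (is.null(vc)) {
      se <- NA_real_
    } else se <- sqrt(vc[2, 2])
    method <- "ml"; flag <- NA_character_
  }
  z <- beta / se
  structure(list(or = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 beta = unname(beta), se = unname(se),
                 method = method, flag = flag),
            class = "variant_assoc")
}

#' @export
print.variant_assoc <- function(x, ...) {
  if (x$method == "none") {
    cat("Single-variant association: no estimate (", x$flag, ")\n", sep = "")
  } else {
    cat(sprintf("Single-variant association (%s%s): OR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                x$method, if (!is.na(x$flag)) paste0(", ", x$flag) else "",
                x$or, x$ci[1], x$ci[2], x$p))
  }
  invisible(x)
}

#' Case-control odds ratio after dichotomizing a score
#'
#' Builds the 2x2 table of status against score above/below a cutpoint and
#' returns `OR = ad/bc` with a Woolf log-scale 95% CI. Cut rules:
#'
#' * `median_of_controls`: cut at the median score of the controls;
#'   scores strictly greater than the cut form the "above" arm (ties at
#'   the cut go below).
#' * `fixed_cut`: cut at `cut`; by default individuals exactly at the cut
#'   are excluded (e.g. comparing scores below 0 to scores above 0 leaves
#'   the zeros out); set `ties = "below"` to pool them with the lower arm.
#' * `extremes`: keep only scores `<= lo` or `>= hi`, compare the two
#'   tails.
#'
#' A zero cell triggers the Haldane-Anscombe 0.5 correction (flagged).
#'
#' @param scores per-individual scores.
#' @param labels case/control labels.
#' @param rule `"median_of_controls"`, `"fixed_cut"` or `"extremes"`.
#' @param cut cutpoint for `fixed_cut`.
#' @param lo,hi tail bounds for `extremes`.
#' @param ties `"below"` or `"exclude"`; default `"below"` except for
#'   `fixed_cut`, whose default is `"exclude"`.
#' @param conf_level CI level (default 0.95).
#' @return object of class `or_result`: the 2x2 `table` (rows case/control,
#'   columns above/below), `or`, `ci`, `cut` description, `flag`.
#' @export
dichotomized_or <- function(scores, labels,
                            rule = c("median_of_controls", "fixed_cut", "extremes"),
                            cut = 0, lo = NULL, hi = NULL, ties = NULL,
                            conf_level = 0.95) {
  rule <- match.arg(rule)
  case <- as_case_logical(labels)
  if (is.null(ties)) ties <- if (rule == "fixed_cut") "exclude" else "below"
  ties <- match.arg(ties, c("below", "exclude"))
  keep <- rep(TRUE, length(scores))
  if (rule == "median_of_controls") {
    cutpoint <- stats::median(scores[!case])
    above <- scores > cutpoint
    if (ties == "exclude") keep <- scores != cutpoint
    cut_desc <- sprintf("control median = %g (ties %s)", cutpoint, ties)
  } else if (rule == "fixed_cut") {
    cutpoint <- cut
    above <- scores > cutpoint
    if (ties == "exclude") keep <- scores != cutpoint
    cut_desc <- sprintf("fixed cut = %g (ties %s)", cutpoint, ties)
  } else {
    if (is.null(lo) || is.null(hi) || lo >= hi)
      stop("extremes rule needs lo < hi")
    keep <- scores <= lo | scores >= hi
    above <- scores >= hi
    cut_desc <- sprintf("extremes: <= %g vs >= %g", lo, hi)
  }
  case_k <- case[keep]; above_k <- above[keep]
  a <- sum(case_k & above_k);  b <- sum(case_k & !above_k)
  cc <- sum(!case_k & above_k); d <- sum(!case_k & !above_k)
  if ((a + b) == 0L || (cc + d) == 0L)
    stop("a label group is empty after dichotomization")
  if ((a + cc) == 0L || (b + d) == 0L)
    stop("an arm is empty after dichotomization")
  flag <- NA_character_
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("above", "below")))
  if (any(tab == 0L)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    flag <- "haldane_correction"
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(table = tab, or = or,
                 ci = exp(log(or) + c(-1, 1) * z * se),
                 conf_level = conf_level, rule = rule, cut = cut_desc,
                 n_used = sum(keep), flag = flag),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("Dichotomized odds ratio (%s): OR = %.3g (%.0f%% CI %.3g-%.3g)%s\n",
              x$cut, x$or, 100 * x$conf_level, x$ci[1], x$ci[2],
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  print(x$table)
  invisible(x)
}
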