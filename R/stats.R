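## Statistical procedures used by the cohort comparisons. Standard tests are
## delegated to base R (binom.test, kruskal.test, fisher.test, p.adjust, lm);
## the arm-density group test is a patient-level permutation test.

.test_result <- function(statistic, p_value, n_used, detail = list()) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_used = n_used, detail = detail),
            class = "besomatic_test")
}

#' @export
print.besomatic_test <- function(x, ...) {
  cat("statistic =", format(x$statistic), " p =", format(x$p_value),
      " n =", x$n_used, "\n")
  invisible(x)
}

#' Exact sign test on paired differences
#'
#' Ties (zero differences) are excluded; the two-sided p-value is the exact
#' binomial probability of the observed positive/negative split at p = 0.5.
#'
#' @param differences Numeric vector of paired differences.
#' @return A test result with `detail$n_positive`, `detail$n_negative`,
#'   `detail$n_ties`.
#' @export
sign_test <- function(differences) {
  stopifnot(length(differences) >= 1L)
  n_pos <- sum(differences > 0)
  n_neg <- sum(differences < 0)
  n_ties <- sum(differences == 0)
  n_used <- n_pos + n_neg
  if (n_used == 0L) {
    warning("all differences are ties; sign test undefined, p = 1")
    p <- 1
  } else {
    p <- stats::binom.test(n_pos, n_used, p = 0.5)$p.value
  }
  .test_result(n_pos, p, n_used,
               list(n_positive = n_pos, n_negative = n_neg, n_ties = n_ties))
}

#' Kruskal-Wallis test for two groups
#'
#' Rank-based H with tie correction, p from the chi-square distribution with
#' one degree of freedom. Degenerate input (all values identical) gives H = 0,
#' p = 1.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A test result.
#' @export
kruskal_wallis <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  x <- c(group_a, group_b)
  if (length(unique(x)) == 1L) {
    return(.test_result(0, 1, length(x)))
  }
  kt <- stats::kruskal.test(list(group_a, group_b))
  .test_result(unname(kt$statistic), kt$p.value, length(x))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities no larger
#' than the observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A test result (statistic is the conditional odds ratio estimate).
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(.test_result(NA_real_, 1, sum(table)))
  }
  ft <- stats::fisher.test(table)
  .test_result(unname(ft$estimate), ft$p.value, sum(table))
}

#' Benjamini-Hochberg adjustment
#'
#' @param p_values Numeric vector of p-values.
#' @param fdr Target false discovery rate.
#' @return List with `q_values` and logical `rejected` (q <= fdr).
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = !is.na(q) & q <= fdr)
}

#' Permutation test for a group effect on arm mutation density
#'
#' The patient is the exchangeable unit: the statistic is the difference in
#' group means of per-patient mean arm densities, and its null distribution is
#' obtained by permuting patient group labels. This respects the within-patient
#' correlation of arm densities exactly.
#'
#' @param density_table Output of [arm_density_table].
#' @param meta Patient table with `nsaid_user`.
#' @param n_perm Number of label permutations.
#' @param seed RNG seed (local to this call).
#' @return A test result; `detail$mean_user`, `detail$mean_nonuser`.
#' @export
group_effect_on_arm_density <- function(density_table, meta,
                                        n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse p-value")
  per_patient <- tapply(density_table$density, density_table$patient_id, mean)
  per_patient <- per_patient[meta$patient_id]
  grp <- meta$nsaid_user
  if (sum(grp) < 2L || sum(!grp) < 2L) stop("need >= 2 patients per group")
  obs <- mean(per_patient[grp]) - mean(per_patient[!grp])
  n_user <- sum(grp)
  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(grp)
      mean(per_patient[lab]) - mean(per_patient[!lab])
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_stats) >= abs(obs))) / (n_perm + 1)
  .test_result(obs, p, length(per_patient),
               list(mean_user = mean(per_patient[grp]),
                    mean_nonuser = mean(per_patient[!grp]),
                    n_perm = n_perm))
}

#' Multivariable linear model on log-transformed mutation counts
#'
#' Fits least squares of `log(count + 1)` on the given covariates and reports
#' estimates, standard errors and two-sided t p-values.
#'
#' @param counts Per-patient mutation counts (non-negative).
#' @param covariates data.frame of covariates (logical or numeric), e.g.
#'   `nsaid_user`, `ever_smoker`, `tp53_mutant`.
#' @return data.frame with one row per model term.
#' @export
multivariable_lm <- function(counts, covariates) {
  stopifnot(nrow(covariates) == length(counts), all(counts >= 0))
  df <- as.data.frame(lapply(covariates, as.numeric))
  const <- vapply(df, function(x) length(unique(x)) == 1L, logical(1))
  if (any(const)) {
    stop("constant covariate: ", paste(names(df)[const], collapse = ", "))
  }
  df$.y <- log(counts + 1)
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased terms: ", paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
             t_value = sm[, 3], p_value = sm[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a list of test results as a TSV-ready data.frame
#'
#' @param results Named list of test results.
#' @return data.frame with columns `test`, `statistic`, `p`, `n`, `detail`
#'   (JSON).
#' @export
test_results_table <- function(results) {
  data.frame(
    test = names(results),
    statistic = vapply(results, function(r) as.numeric(r$statistic)[1],
                       numeric(1)),
    p = vapply(results, function(r) r$p_value, numeric(1)),
    n = vapply(results, function(r) as.integer(r$n_used), integer(1)),
    detail = vapply(results, function(r) {
      as.character(jsonlite::toJSON(r$detail, auto_unbox = TRUE, digits = 10))
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
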