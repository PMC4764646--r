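#' Chi-square goodness-of-fit burden test for one gene
#'
#' Compares the qualifying-variant count in cases against controls under
#' the null that counts split in proportion to cohort sizes: with pooled
#' count `T`, the expected case count is `T * n_case / (n_case + n_control)`.
#' The statistic is `sum((O - E)^2 / E)` with 1 degree of freedom and no
#' continuity correction; small expected counts are the norm in the
#' rare-variant regime, and the exact Fisher stage is the backstop.
#'
#' @param case_count,control_count Qualifying-variant (or carrier) counts;
#'   vectorized.
#' @param n_case,n_control Cohort sizes (individuals).
#' @return A tibble with columns `chi2_stat` and `p_value`.
#' @examples
#' chi2_burden(3, 55, 0, 164) # chi2 ~ 8.95, p ~ 0.0028
#' @export
chi2_burden <- function(case_count, n_case, control_count, n_control) {
  stopifnot(n_case > 0, n_control > 0,
            all(case_count >= 0), all(control_count >= 0))
  total <- case_count + control_count
  if (any(total < 1)) {
    stop("no qualifying variants: pooled count is zero, test undefined",
         call. = FALSE)
  }
  e_case <- total * n_case / (n_case + n_control)
  e_ctrl <- total - e_case
  chi2 <- (case_count - e_case)^2 / e_case +
    (control_count - e_ctrl)^2 / e_ctrl
  tibble::tibble(
    chi2_stat = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg step-up false discovery rate procedure
#'
#' Standard step-up rule over `m` tests: sort p-values ascending, compute
#' critical values `(i / m) * alpha`, and declare significant all items
#' with rank at most the largest `i` whose sorted p-value is at or below
#' its critical value. Adjusted p-values are the usual step-up minima
#' (`min over j >= i of (m / j) * p_(j)`, capped at 1, as computed by
#' `stats::p.adjust`). `m` may exceed the number of supplied p-values to
#' correct over tests that were run but not reported.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @param m Number of tests corrected for (default `length(p_values)`).
#' @return A tibble in the input order with columns `p_value`,
#'   `bh_critical` (the critical value at each item's rank), `p_adjusted`
#'   and `significant`.
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05,
                               m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, m >= length(p_values))
  k <- length(p_values)
  if (k == 0) {
    return(tibble::tibble(p_value = numeric(), bh_critical = numeric(),
                          p_adjusted = numeric(), significant = logical()))
  }
  ord <- order(p_values)
  rank <- integer(k)
  rank[ord] <- seq_len(k)
  critical <- (rank / m) * alpha
  passing <- which(p_values[ord] <= (seq_len(k) / m) * alpha)
  cutoff_rank <- if (length(passing) == 0) 0L else max(passing)
  tibble::tibble(
    p_value = p_values,
    bh_critical = critical,
    p_adjusted = stats::p.adjust(p_values, method = "BH", n = m),
    significant = rank <= cutoff_rank
  )
}

#' Two-sided Fisher's exact test on carrier counts
#'
#' Conditions on the margins of the 2x2 table
#' (carriers / non-carriers x case / control) and sums, over the
#' hypergeometric distribution of the case-carrier count, the probability
#' of every outcome no more likely than the observed one (the
#' minimum-likelihood two-sided convention, as in `stats::fisher.test`).
#' The odds ratio is the sample cross-product ratio, `Inf` when an
#' off-diagonal zero makes it unbounded and `NaN` when both diagonals
#' vanish.
#'
#' @param case_carriers,control_carriers Carrier counts; vectorized.
#' @param n_case,n_control Cohort sizes (individuals).
#' @return A tibble with columns `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_carriers(2, 55, 0, 164) # p ~ 0.0622
#' @export
fisher_exact_carriers <- function(case_carriers, n_case,
                                  control_carriers, n_control) {
  stopifnot(all(case_carriers >= 0), all(case_carriers <= n_case),
            all(control_carriers >= 0), all(control_carriers <= n_control))
  k <- max(length(case_carriers), length(control_carriers))
  a <- rep_len(case_carriers, k)
  b <- rep_len(control_carriers, k)
  p <- numeric(k)
  or <- numeric(k)
  for (i in seq_len(k)) {
    total_carriers <- a[i] + b[i]
    # support of the case-carrier count given fixed margins
    lo <- max(0L, total_carriers - n_control)
    hi <- min(total_carriers, n_case)
    probs <- stats::dhyper(lo:hi, total_carriers,
                           n_case + n_control - total_carriers, n_case)
    obs <- probs[a[i] - lo + 1L]
    # relative tolerance guards ties against floating-point noise
    p[i] <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
    num <- a[i] * (n_control - b[i])
    den <- b[i] * (n_case - a[i])
    or[i] <- if (den == 0 && num == 0) NaN else if (den == 0) Inf
             else num / den
  }
  tibble::tibble(odds_ratio = or, p_value = p)
}

#' Case-vs-control burden screen over recurrent genes
#'
#' For every recurrent gene, counts qualifying variants (or carriers) in
#' the control cohort, runs [chi2_burden()] against the case counts, and
#' applies [benjamini_hochberg()]. Genes are retained at raw
#' `p <= alpha`; the BH flags are reported alongside so that a screen in
#' which nothing survives correction can still fall back on the raw rule
#' explicitly. Case and control records must have been filtered under the
#' same configuration: the screen refuses to compare burdens whose filter
#' fingerprints differ.
#'
#' @param recurrence Output of [find_recurrent_genes()] on the case cohort
#'   (carries the case filter fingerprint).
#' @param case_manifest,control_manifest Cohort manifests; cohort sizes are
#'   their row counts.
#' @param control_records Retained (filtered) records of the control
#'   cohort, carrying its filter fingerprint.
#' @param alpha Significance level for the raw rule and the BH level
#'   (default 0.05).
#' @param m Number of tests for BH (default: number of recurrent genes).
#' @param unit `"variants"` (default: qualifying-variant counts, the
#'   screening unit) or `"carriers"` (distinct individuals).
#' @return A list with tibbles `results` (one row per recurrent gene:
#'   `gene`, `case_count`, `n_case`, `control_count`, `n_control`,
#'   `chi2_stat`, `p_value`, `bh_critical`, `p_adjusted`,
#'   `significant_raw`, `significant_bh`), `retained` and `removed`
#'   (subsets by the raw rule, `removed` with a `reason` column).
#' @export
burden_screen <- function(recurrence, case_manifest, control_records,
                          control_manifest, alpha = 0.05, m = NULL,
                          unit = c("variants", "carriers")) {
  unit <- match.arg(unit)
  fp_case <- attr(recurrence, "filter_fingerprint")
  fp_ctrl <- attr(control_records, "filter_fingerprint")
  if (is.null(fp_case) || is.null(fp_ctrl) || !identical(fp_case, fp_ctrl)) {
    stop("filter fingerprint mismatch between case and control cohorts; ",
         "both must be filtered with the same filter_config before their ",
         "burdens are comparable", call. = FALSE)
  }
  empty <- tibble::tibble(
    gene = character(), case_count = integer(), n_case = integer(),
    control_count = integer(), n_control = integer(), chi2_stat = double(),
    p_value = double(), bh_critical = double(), p_adjusted = double(),
    significant_raw = logical(), significant_bh = logical()
  )
  if (nrow(recurrence) == 0) {
    return(list(results = empty, retained = empty,
                removed = dplyr::mutate(empty, reason = character())))
  }
  n_case <- nrow(case_manifest)
  n_control <- nrow(control_manifest)
  if (is.null(m)) m <- nrow(recurrence)

  case_count <- if (unit == "variants") {
    recurrence$n_observations
  } else {
    recurrence$n_carriers
  }
  control_count <- if (unit == "variants") {
    ctrl_tab <- table(control_records$gene)
  } else {
    ctrl_tab <- table(unique(control_records[, c("gene", "sample_id")])$gene)
  }
  control_count <- as.integer(ifelse(recurrence$gene %in% names(ctrl_tab),
                                     ctrl_tab[recurrence$gene], 0L))

  chi <- chi2_burden(case_count, n_case, control_count, n_control)
  bh <- benjamini_hochberg(chi$p_value, alpha = alpha, m = m)
  results <- tibble::tibble(
    gene = recurrence$gene,
    case_count = as.integer(case_count),
    n_case = n_case,
    control_count = control_count,
    n_control = n_control,
    chi2_stat = chi$chi2_stat,
    p_value = chi$p_value,
    bh_critical = bh$bh_critical,
    p_adjusted = bh$p_adjusted,
    significant_raw = chi$p_value <= alpha,
    significant_bh = bh$significant
  )
  removed <- results[!results$significant_raw, , drop = FALSE]
  removed$reason <- sprintf(
    "burden not enriched over controls (chi2 p = %.3g > %.3g)",
    removed$p_value, alpha
  )
  list(
    results = results,
    retained = results[results$significant_raw, , drop = FALSE],
    removed = removed
  )
}

#' Write burden-screen results as TSV
#'
#' @param results The `results` tibble from [burden_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_burden_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
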