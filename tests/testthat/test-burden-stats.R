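test_that("chi2 burden test matches hand-derived examples", {
  # E_case = 3 * 55 / 219 = 0.7534; statistic ~ 8.95, p ~ 0.0028
  r <- chi2_burden(3, 55, 0, 164)
  expect_equal(r$chi2_stat, 8.945455, tolerance = 1e-6)
  expect_equal(r$p_value, 0.002781609, tolerance = 1e-6)
  # proportional rates: essentially no signal
  r2 <- chi2_burden(5, 55, 15, 164)
  expect_lt(r2$chi2_stat, 0.001)
  expect_gt(r2$p_value, 0.98)
  expect_error(chi2_burden(0, 55, 0, 164), "no qualifying variants")
})

test_that("chi2 burden agrees with chisq.test to 1e-10 on 1000 configs", {
  set.seed(101)
  max_abs <- 0
  for (i in 1:1000) {
    n1 <- sample(10:500, 1)
    n2 <- sample(10:500, 1)
    c1 <- sample(0:30, 1)
    c2 <- sample(0:30, 1)
    if (c1 + c2 == 0) c1 <- 1
    got <- chi2_burden(c1, n1, c2, n2)
    ref <- suppressWarnings(
      stats::chisq.test(c(c1, c2), p = c(n1, n2) / (n1 + n2),
                        correct = FALSE))
    max_abs <- max(max_abs,
                   abs(got$chi2_stat - unname(ref$statistic)),
                   abs(got$p_value - ref$p.value))
  }
  expect_lt(max_abs, 1e-10)
})

test_that("BH step-up reproduces the hand-computed example", {
  # criticals at m = 4, alpha = 0.05: 0.0125, 0.025, 0.0375, 0.05
  out <- benjamini_hochberg(c(0.001, 0.02, 0.04, 0.9), alpha = 0.05, m = 4)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$bh_critical, c(0.0125, 0.025, 0.0375, 0.05))
  expect_equal(out$p_adjusted,
               p.adjust(c(0.001, 0.02, 0.04, 0.9), "BH"))

  out1 <- benjamini_hochberg(1, m = 1)
  expect_false(out1$significant)
  expect_equal(out1$p_adjusted, 1)
  out2 <- benjamini_hochberg(0.03, alpha = 0.05, m = 1)
  expect_true(out2$significant)
  expect_equal(out2$p_adjusted, 0.03)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # m may exceed the number of supplied p-values
  out3 <- benjamini_hochberg(0.03, alpha = 0.05, m = 10)
  expect_false(out3$significant)
  expect_equal(out3$p_adjusted, 0.3)
})

test_that("BH significant set grows with alpha and m=1 is raw thresholding", {
  set.seed(33)
  for (rep in 1:20) {
    p <- runif(sample(3:12, 1))
    alphas <- c(0.01, 0.05, 0.1, 0.2)
    sets <- lapply(alphas, function(a)
      which(benjamini_hochberg(p, alpha = a)$significant))
    for (i in seq_along(alphas)[-1]) {
      expect_true(all(sets[[i - 1]] %in% sets[[i]]))
    }
    # adjusted p monotone in raw p
    out <- benjamini_hochberg(p)
    expect_true(all(diff(out$p_adjusted[order(out$p_value)]) >= -1e-12))
  }
  p1 <- runif(1)
  expect_equal(benjamini_hochberg(p1, alpha = 0.05, m = 1)$significant,
               p1 <= 0.05)
})

test_that("Fisher p matches hypergeometric enumeration and examples", {
  # P(X = 2) = (55 * 54) / (219 * 218) with both carriers in cases
  r <- fisher_exact_carriers(2, 55, 0, 164)
  expect_equal(r$p_value, (55 * 54) / (219 * 218), tolerance = 1e-12)
  expect_equal(r$odds_ratio, Inf)
  expect_equal(fisher_exact_carriers(0, 55, 0, 164)$p_value, 1.0)
  # symmetry under swapping case and control columns
  expect_equal(fisher_exact_carriers(3, 40, 1, 80)$p_value,
               fisher_exact_carriers(1, 80, 3, 40)$p_value)

  # exhaustive check against an independent enumeration for margins <= 60
  enum_p <- function(a, n1, b, n2) {
    k <- a + b
    xs <- max(0, k - n2):min(k, n1)
    probs <- choose(n1, xs) * choose(n2, k - xs) / choose(n1 + n2, k)
    obs <- probs[xs == a]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }
  for (n1 in c(5, 11, 23)) {
    for (n2 in c(7, 19, 37)) {
      for (a in 0:min(6, n1)) {
        for (b in 0:min(6, n2)) {
          expect_equal(fisher_exact_carriers(a, n1, b, n2)$p_value,
                       enum_p(a, n1, b, n2), tolerance = 1e-12)
        }
      }
    }
  }
  # and against fisher.test on random larger tables
  set.seed(55)
  for (i in 1:50) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    ref <- stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2))
    expect_equal(fisher_exact_carriers(a, n1, b, n2)$p_value,
                 ref$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher and chi2 p-values converge as counts scale", {
  # hold the statistic at O(1) by shrinking the proportion difference at
  # the 1/sqrt(n) rate; in this regime the central limit theorem makes
  # the exact and asymptotic p-values agree increasingly well (at fixed
  # non-null proportions both p-values vanish and relative tail accuracy
  # is not guaranteed)
  rel_diff <- sapply(c(1, 4, 16, 64), function(s) {
    a <- 2 * s + round(2 * sqrt(s)); b <- 2 * s
    n1 <- 100 * s; n2 <- 100 * s
    pf <- fisher_exact_carriers(a, n1, b, n2)$p_value
    pc <- chi2_burden(a, n1, b, n2)$p_value
    abs(pf - pc) / pc
  })
  expect_true(all(diff(rel_diff) < 0))
  expect_lt(rel_diff[length(rel_diff)], 0.1)
})

test_that("burden screen retains enriched genes and explains removals", {
  manifest_case <- mk_manifest(sprintf("S%02d", 1:55))
  manifest_ctrl <- mk_manifest(sprintf("C%03d", 1:164), role = "control")
  cfg <- filter_config()
  case <- mk_records(
    mk_record("S01", pos = 1L, gene = "ENRICHED"),
    mk_record("S02", pos = 2L, gene = "ENRICHED"),
    mk_record("S03", pos = 3L, gene = "ENRICHED"),
    mk_record("S04", pos = 10L, gene = "FLAT"),
    mk_record("S05", pos = 11L, gene = "FLAT"),
    mk_record("S06", pos = 12L, gene = "FLAT"),
    mk_record("S07", pos = 13L, gene = "FLAT"),
    mk_record("S08", pos = 14L, gene = "FLAT")
  )
  ctrl_rows <- lapply(1:15, function(i)
    mk_record(sprintf("C%03d", i), pos = 100L + i, gene = "FLAT"))
  case_f <- filter_cohort(case, cfg, "ZZZ")
  ctrl_f <- filter_cohort(validate_variant_table(
    dplyr::bind_rows(ctrl_rows)), cfg, "ZZZ")
  rec <- find_recurrent_genes(case_f$retained, manifest_case)
  scr <- burden_screen(rec, manifest_case, ctrl_f$retained, manifest_ctrl)
  expect_setequal(scr$results$gene, c("ENRICHED", "FLAT"))
  expect_equal(scr$retained$gene, "ENRICHED")
  expect_equal(scr$removed$gene, "FLAT")
  expect_match(scr$removed$reason, "not enriched")
  # counts flow through: 3 vs 0 and 5 vs 15
  expect_equal(scr$results$case_count[scr$results$gene == "ENRICHED"], 3L)
  expect_equal(
    scr$results$control_count[scr$results$gene == "FLAT"], 15L)

  # empty recurrence table -> empty screen
  empty <- burden_screen(rec[0, ], manifest_case, ctrl_f$retained,
                         manifest_ctrl)
  expect_equal(nrow(empty$results), 0)
})

test_that("burden screen refuses mismatched filter fingerprints", {
  manifest_case <- mk_manifest(c("S1", "S2"))
  manifest_ctrl <- mk_manifest(c("C1", "C2"), role = "control")
  case <- mk_records(mk_record("S1", pos = 1L), mk_record("S2", pos = 2L))
  ctrl <- mk_records(mk_record("C1", pos = 5L))
  case_f <- filter_cohort(case, filter_config(), "ZZZ")
  ctrl_f <- filter_cohort(ctrl, filter_config(phylop_min = 2.0), "ZZZ")
  rec <- find_recurrent_genes(case_f$retained, manifest_case)
  expect_error(
    burden_screen(rec, manifest_case, ctrl_f$retained, manifest_ctrl),
    "fingerprint")
})
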