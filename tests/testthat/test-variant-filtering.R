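test_that("quality gate thresholds are inclusive and indel-aware", {
  cfg <- filter_config()
  x <- mk_records(
    # exactly at every threshold: passes
    mk_record(total_reads = 10L, variant_reads = 5L, unique_starts = 5L),
    # 27% variant reads: fails the fraction rule only
    mk_record(total_reads = 100L, variant_reads = 27L,
              unique_starts = 10L),
    # frameshift indel without unique starts: rule skipped, passes
    mk_record(total_reads = 30L, variant_reads = 12L, csq = "frameshift",
              ref = "AT", alt = "A", phylop = NA_real_),
    # unique starts just below: fails that rule only
    mk_record(total_reads = 40L, variant_reads = 20L, unique_starts = 4L)
  )
  q <- passes_quality(x, cfg)
  expect_equal(q$pass, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(q$failed_rules[[2]], "variant_fraction")
  expect_equal(q$failed_rules[[4]], "unique_starts")
})

test_that("frequency gate enforces MAF <= cutoff in every panel", {
  cfg <- filter_config()
  x <- mk_records(
    mk_record(ac_inhouse = 0, ac_evs = 1),           # EVS MAF 0.0000769
    mk_record(ac_evs = 27),                          # EVS MAF ~0.002
    mk_record(ac_inhouse = 0, ac_evs = 0),
    mk_record(ac_inhouse = 5, ac_evs = 0)            # inhouse ~0.0012
  )
  expect_equal(passes_frequency(x, cfg), c(TRUE, FALSE, TRUE, FALSE))

  # an enforced panel without columns is an error naming the panel
  cfg2 <- filter_config(frequency_panels = c("inhouse", "evs", "exac"))
  expect_error(passes_frequency(x, cfg2), "exac")

  # a per-config zero cutoff reproduces the strict absent-from-panel rule
  cfg3 <- filter_config(max_panel_maf = 0)
  expect_equal(passes_frequency(x, cfg3), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("impact classification keeps truncations regardless of PhyloP", {
  cfg <- filter_config()
  x <- mk_records(
    mk_record(csq = "canonical_splice", phylop = 2.427),
    mk_record(csq = "missense", phylop = 4.531),
    mk_record(csq = "missense", phylop = 2.99),
    mk_record(csq = "missense", phylop = 3.0),
    mk_record(csq = "synonymous", phylop = 6.0),
    mk_record(csq = "other", phylop = 6.0),
    mk_record(csq = "nonsense", phylop = -2.0)
  )
  expect_equal(
    classify_impact(x, cfg),
    c("truncating", "conserved_missense", "excluded", "conserved_missense",
      "excluded", "excluded", "truncating")
  )
  # missing PhyloP on a missense record: excluded with a warning
  y <- mk_records(mk_record(csq = "missense", phylop = NA_real_))
  expect_warning(cls <- classify_impact(y, cfg), "PhyloP")
  expect_equal(cls, "excluded")
})

test_that("truncating verdicts are independent of the PhyloP draw", {
  cfg <- filter_config()
  set.seed(11)
  for (csq in c("nonsense", "frameshift", "canonical_splice")) {
    x <- dplyr::bind_rows(lapply(runif(25, -10, 10), function(p) {
      mk_record(csq = csq, phylop = p,
                ref = if (csq == "frameshift") "AT" else "A",
                alt = if (csq == "frameshift") "A" else "G")
    }))
    x <- validate_variant_table(x)
    expect_true(all(classify_impact(x, cfg) == "truncating"))
  }
})

test_that("LoF-tolerant exclusion removes listed genes, preserving order", {
  x <- mk_records(
    mk_record("S1", pos = 1L, gene = "KEEP1"),
    mk_record("S1", pos = 2L, gene = "OR4C11"),
    mk_record("S1", pos = 3L, gene = "KEEP2")
  )
  out <- exclude_lof_tolerant(x, c("or4c11"))
  expect_equal(out$gene, c("KEEP1", "KEEP2"))
  expect_equal(exclude_lof_tolerant(x, "UNRELATED")$gene, x$gene)
})

test_that("filter_cohort composes the gates and summarizes per sample", {
  cfg <- filter_config()
  x <- mk_records(
    # S1: all records fail quality
    mk_record("S1", pos = 1L, total_reads = 9L, variant_reads = 4L,
              unique_starts = 3L),
    # S2: one truncating + two conserved missense survive, one too common
    mk_record("S2", pos = 10L, csq = "nonsense", phylop = 0.5),
    mk_record("S2", pos = 11L, csq = "missense", phylop = 3.3),
    mk_record("S2", pos = 12L, csq = "missense", phylop = 7.1),
    mk_record("S2", pos = 13L, csq = "missense", phylop = 7.1, ac_evs = 50),
    # S2: LoF-tolerant gene
    mk_record("S2", pos = 14L, gene = "OR4C11", phylop = 6.0)
  )
  f <- filter_cohort(x, cfg, lof_tolerant = c("OR4C11"))
  s1 <- f$summary[f$summary$sample_id == "S1", ]
  expect_equal(s1$n_truncating, 0L)
  expect_equal(s1$n_conserved_missense, 0L)
  s2 <- f$summary[f$summary$sample_id == "S2", ]
  expect_equal(s2$n_truncating, 1L)
  expect_equal(s2$n_conserved_missense, 2L)
  # summary totals recount the retained records (independent pass)
  expect_equal(sum(f$summary$n_retained), nrow(f$retained))
  recount <- table(f$retained$sample_id)
  for (s in names(recount)) {
    expect_equal(unname(recount[s]),
                 f$summary$n_retained[f$summary$sample_id == s],
                 ignore_attr = TRUE)
  }
  # the funnel is monotone non-increasing
  expect_true(all(diff(f$funnel) <= 0))
})

test_that("filtering is monotone: outputs are a subset of inputs", {
  sim <- simulate_cohort(simulation_config(seed = 5, n_genes = 30))
  f <- filter_cohort(sim$case, filter_config(), "ZZZ_NOT_A_GENE")
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$alt)
  expect_true(all(key(f$retained) %in% key(sim$case)))
  expect_false(any(duplicated(key(f$retained))))
})

test_that("raising any threshold never enlarges the retained set", {
  sim <- simulate_cohort(simulation_config(seed = 6, n_genes = 40,
                                           fraction_quality_fail = 0.3,
                                           fraction_common = 0.3))
  base_cfg <- filter_config()
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$alt)
  base <- key(filter_cohort(sim$case, base_cfg, "ZZZ")$retained)
  tighter <- list(
    filter_config(min_total_reads = 30),
    filter_config(min_variant_reads = 12),
    filter_config(min_unique_starts = 10),
    filter_config(min_variant_fraction = 0.45),
    filter_config(max_panel_maf = 0.0002),
    filter_config(phylop_min = 5.0)
  )
  for (cfg in tighter) {
    got <- key(filter_cohort(sim$case, cfg, "ZZZ")$retained)
    expect_true(all(got %in% base))
  }
})
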