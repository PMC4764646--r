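test_that("known-gene annotation reports hits without verdicts", {
  packs <- test_packs()
  x <- mk_records(
    mk_record("S1", pos = 1L, gene = "MSH6"),
    mk_record("S2", pos = 2L, gene = "BLM"),
    mk_record("S3", pos = 3L, gene = "NOVELGENE")
  )
  x$impact_class <- "conserved_missense"
  hits <- annotate_known_genes(x, packs)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$category[hits$gene == "MSH6"], "crc_predisposition")
  expect_equal(hits$category[hits$gene == "BLM"], "cancer_syndrome")
  expect_true(all(grepl("follow-up", hits$note)))
  expect_error(annotate_known_genes(x, packs["crc_driver"]),
               "crc_predisposition")
})

test_that("triage applies the four evidence steps in fixed order", {
  packs <- test_packs()
  manifest <- mk_manifest(c("S1", "S2", "S3"))
  rec <- function(gene, csq, sample_id, pos) {
    r <- mk_record(sample_id, pos = pos, gene = gene, csq = csq,
                   phylop = 5.0)
    r
  }
  x <- validate_variant_table(dplyr::bind_rows(
    # all-truncating recurrent gene -> step 1
    rec("TRUNCG", "canonical_splice", "S1", 1L),
    rec("TRUNCG", "canonical_splice", "S2", 2L),
    # driver gene with missense -> step 2
    rec("PTPN12", "missense", "S1", 10L),
    rec("PTPN12", "missense", "S2", 11L),
    # mouse + KEGG -> step 3
    rec("LRP6", "missense", "S1", 20L),
    rec("LRP6", "missense", "S3", 21L),
    # mouse list only, no KEGG membership -> none
    rec("RASGRF1", "missense", "S1", 30L),
    rec("RASGRF1", "missense", "S2", 31L),
    # GWAS -> step 4
    rec("GREM1", "missense", "S2", 40L),
    rec("GREM1", "missense", "S3", 41L)
  ))
  x$impact_class <- classify_impact(x, filter_config())
  out <- triage_candidates(x, manifest, packs)
  got <- setNames(out$retained_at_step, out$gene)
  expect_equal(unname(got["TRUNCG"]), "step1_truncating_recurrent")
  expect_equal(unname(got["PTPN12"]), "step2_driver")
  expect_equal(unname(got["LRP6"]), "step3_mouse_and_kegg")
  expect_equal(unname(got["RASGRF1"]), "none")
  expect_equal(unname(got["GREM1"]), "step4_gwas")
  expect_error(triage_candidates(x, manifest, packs["gwas"]), "crc_driver")
})

test_that("triage uses first-match semantics and ignores unrelated genes", {
  packs <- test_packs()
  manifest <- mk_manifest(c("S1", "S2"))
  # a driver gene whose variants are all truncating matches steps 1 and 2:
  # reported at step 1, with both steps listed
  x <- mk_records(
    mk_record("S1", pos = 1L, gene = "PTPN12", csq = "nonsense"),
    mk_record("S2", pos = 2L, gene = "PTPN12", csq = "nonsense"))
  x$impact_class <- "truncating"
  out <- triage_candidates(x, manifest, packs)
  expect_equal(out$retained_at_step, "step1_truncating_recurrent")
  expect_true(all(c("step1_truncating_recurrent", "step2_driver") %in%
                    out$all_steps[[1]]))

  # adding an unrelated gene never changes an existing verdict
  y <- mk_records(
    mk_record("S1", pos = 1L, gene = "PTPN12", csq = "nonsense"),
    mk_record("S2", pos = 2L, gene = "PTPN12", csq = "nonsense"),
    mk_record("S1", pos = 50L, gene = "OTHERG", csq = "missense"))
  y$impact_class <- ifelse(y$csq == "nonsense", "truncating",
                           "conserved_missense")
  out2 <- triage_candidates(y, manifest, packs)
  expect_equal(out2$retained_at_step[out2$gene == "PTPN12"],
               out$retained_at_step)
  # every triaged gene comes from the input (no invention)
  expect_setequal(out2$gene, unique(y$gene))
})

test_that("step 1 requires truncating variants in unrelated carriers", {
  packs <- test_packs()
  related <- mk_manifest(c("S1", "S2"), family_ids = c("FA", "FA"))
  x <- mk_records(
    mk_record("S1", pos = 1L, gene = "TRUNCG", csq = "nonsense"),
    mk_record("S2", pos = 2L, gene = "TRUNCG", csq = "nonsense"))
  x$impact_class <- "truncating"
  out <- triage_candidates(x, related, packs)
  expect_equal(out$retained_at_step, "none")
  # a mixed gene (truncating + missense) is not all-truncating
  unrelated <- mk_manifest(c("S1", "S2"))
  y <- mk_records(
    mk_record("S1", pos = 1L, gene = "TRUNCG", csq = "nonsense"),
    mk_record("S2", pos = 2L, gene = "TRUNCG", csq = "missense"))
  y$impact_class <- ifelse(y$csq == "nonsense", "truncating",
                           "conserved_missense")
  expect_equal(triage_candidates(y, unrelated, packs)$retained_at_step,
               "none")
})

test_that("replication selection applies the frequency and impact rules", {
  cfg <- filter_config()
  x <- mk_records(
    # conserved missense, absent from EVS: selected
    mk_record("R1", pos = 1L, csq = "missense", phylop = 4.24),
    # missense below the conservation cutoff: rejected
    mk_record("R2", pos = 2L, csq = "missense", phylop = 2.0),
    # truncating but common in EVS: rejected
    mk_record("R3", pos = 3L, csq = "nonsense", ac_evs = 140),
    # truncating and rare: selected
    mk_record("R4", pos = 4L, csq = "canonical_splice", phylop = 0.1)
  )
  out <- select_replication_variants(x, cfg)
  expect_setequal(out$sample_id, c("R1", "R4"))
  expect_setequal(unique(out$impact_class),
                  c("conserved_missense", "truncating"))
})

test_that("candidate reports are complete, valid and byte-deterministic", {
  fx <- make_fixture_cohort()
  packs <- test_packs()
  report <- run_discovery(fx$discovery, fx$discovery_manifest,
                          fx$control1, fx$control1_manifest, packs)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_candidate_report(report, dir1)
  write_candidate_report(report, dir2)
  for (f in c("candidates.tsv", "candidates.json", "summary.txt")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  parsed <- jsonlite::read_json(file.path(dir1, "candidates.json"))
  expect_setequal(
    names(parsed),
    c("funnel", "filter_summary", "biallelic", "recurrence", "burden",
      "known_gene_hits", "triage"))

  # an empty run still writes valid, fully sectioned output
  empty_report <- run_discovery(fx$discovery[0, ], fx$discovery_manifest,
                                fx$control1[0, ], fx$control1_manifest,
                                packs)
  dir3 <- withr::local_tempdir()
  write_candidate_report(empty_report, dir3)
  parsed_empty <- jsonlite::read_json(file.path(dir3, "candidates.json"))
  expect_setequal(names(parsed_empty), names(parsed))
})
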