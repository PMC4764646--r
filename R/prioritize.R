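#' Annotate retained variants falling in known predisposition genes
#'
#' Reports every retained variant whose gene is on the known CRC
#' predisposition list or the wider cancer-syndrome list. Hits are
#' annotations, never verdicts: establishing pathogenicity requires
#' functional evidence (e.g. tumor mismatch-repair status for MMR-gene
#' hits) that sits outside this analysis, so every hit carries the note
#' "requires functional follow-up".
#'
#' @param records Retained (filtered) records with `impact_class`.
#' @param packs Gene-list packs; must include `crc_predisposition` and
#'   `cancer_syndrome` (see [read_gene_packs()]).
#' @return A tibble with columns `gene`, `category`, `sample_id`,
#'   `variant`, `impact_class`, `note`.
#' @export
annotate_known_genes <- function(records, packs) {
  for (need in c("crc_predisposition", "cancer_syndrome")) {
    if (is.null(packs[[need]])) {
      stop("gene-list pack '", need, "' is required but missing",
           call. = FALSE)
    }
  }
  category <- ifelse(records$gene %in% packs$crc_predisposition,
                     "crc_predisposition",
                     ifelse(records$gene %in% packs$cancer_syndrome,
                            "cancer_syndrome", NA_character_))
  hit <- !is.na(category)
  tibble::tibble(
    gene = records$gene[hit],
    category = category[hit],
    sample_id = records$sample_id[hit],
    variant = paste0(records$chrom[hit], ":", records$pos[hit], ":",
                     records$ref[hit], ">", records$alt[hit]),
    impact_class = records$impact_class[hit],
    note = "requires functional follow-up"
  ) |>
    dplyr::arrange(.data$gene, .data$variant)
}

#' Four-step evidence triage of burden-screen survivors
#'
#' Applies the ordered evidence steps to each surviving gene and reports
#' the first that matches:
#' 1. `step1_truncating_recurrent` — every qualifying variant in the gene
#'    is protein-truncating and truncating variants occur in at least two
#'    unrelated carriers;
#' 2. `step2_driver` — the gene is on the CRC driver list;
#' 3. `step3_mouse_and_kegg` — the gene was hit in mouse transposon CRC
#'    screens *and* belongs to a cancer-related KEGG pathway;
#' 4. `step4_gwas` — the gene was identified in CRC GWAS.
#' Genes matching no step are reported with `retained_at_step = "none"`.
#' All matching steps are also listed for transparency.
#'
#' @param survivor_records Retained records restricted to burden-screen
#'   survivor genes, with `impact_class`.
#' @param manifest Cohort manifest (for the unrelated-carriers condition).
#' @param packs Gene-list packs; must include `crc_driver`,
#'   `mouse_transposon`, `kegg_cancer_pathways` and `gwas`.
#' @return A tibble with one row per survivor gene: `gene`,
#'   `retained_at_step`, `all_steps` (list), `n_truncating`,
#'   `n_conserved_missense`, `supporting_variants` (list).
#' @export
triage_candidates <- function(survivor_records, manifest, packs) {
  for (need in c("crc_driver", "mouse_transposon", "kegg_cancer_pathways",
                 "gwas")) {
    if (is.null(packs[[need]])) {
      stop("gene-list pack '", need, "' is required but missing",
           call. = FALSE)
    }
  }
  genes <- sort(unique(survivor_records$gene))
  if (length(genes) == 0) {
    return(tibble::tibble(
      gene = character(), retained_at_step = character(),
      all_steps = list(), n_truncating = integer(),
      n_conserved_missense = integer(), supporting_variants = list()
    ))
  }
  fam <- manifest$family_id[match(survivor_records$sample_id,
                                  manifest$sample_id)]
  rows <- lapply(genes, function(g) {
    idx <- survivor_records$gene == g
    rec <- survivor_records[idx, , drop = FALSE]
    trunc <- rec$impact_class == "truncating"
    all_truncating <- all(trunc)
    trunc_families <- unique(fam[idx][trunc])
    step1 <- all_truncating && sum(trunc) >= 2 && length(trunc_families) >= 2
    steps <- c(
      if (step1) "step1_truncating_recurrent",
      if (g %in% packs$crc_driver) "step2_driver",
      if (g %in% packs$mouse_transposon &&
          g %in% packs$kegg_cancer_pathways) "step3_mouse_and_kegg",
      if (g %in% packs$gwas) "step4_gwas"
    )
    tibble::tibble(
      gene = g,
      retained_at_step = if (length(steps) == 0) "none" else steps[1],
      all_steps = list(if (length(steps) == 0) character() else steps),
      n_truncating = sum(trunc),
      n_conserved_missense = sum(rec$impact_class == "conserved_missense"),
      supporting_variants = list(sort(unique(
        paste0(rec$chrom, ":", rec$pos, ":", rec$ref, ">", rec$alt)
      )))
    )
  })
  dplyr::bind_rows(rows)
}

#' Select replication-cohort variants worth validating
#'
#' The replication (re-sequencing) selection rule: keep calls with a minor
#' allele frequency at most `max_panel_maf` in the reference panel
#' (default: the EVS panel) that are protein-truncating, splice-site, or
#' missense with PhyloP at or above the conservation cutoff. An optional
#' platform-specific quality gate is applied first when
#' `apply_quality = TRUE`.
#'
#' @param records Validated replication-cohort records.
#' @param config A [filter_config()]; its `phylop_min` and `max_panel_maf`
#'   drive the rule. `frequency_panels` defaults to `"evs"` here unless
#'   the config enforces others.
#' @param panels Panels on which to enforce the MAF rule (default `"evs"`).
#' @param apply_quality Also apply the read-level quality gate
#'   (default FALSE: re-sequencing platforms carry their own calling QC).
#' @return Selected records with `impact_class` added.
#' @export
select_replication_variants <- function(records, config = filter_config(),
                                        panels = "evs",
                                        apply_quality = FALSE) {
  cfg <- config
  cfg$frequency_panels <- panels
  if (apply_quality) {
    records <- records[passes_quality(records, cfg)$pass, , drop = FALSE]
  }
  records <- records[passes_frequency(records, cfg), , drop = FALSE]
  impact <- classify_impact(records, cfg)
  out <- records[impact != "excluded", , drop = FALSE]
  out$impact_class <- impact[impact != "excluded"]
  out
}

#' Write the candidate report bundle
#'
#' Emits the full stage-by-stage result set in machine-readable form
#' (`candidates.tsv`, `candidates.json`) and a human-readable
#' `summary.txt`. Ordering is deterministic (gene, then position), so
#' regenerating the report from the same inputs is byte-identical.
#'
#' @param report A named list as assembled by [run_discovery()]:
#'   `filter_summary`, `funnel`, `biallelic`, `recurrence`, `burden`,
#'   `known_gene_hits`, `triage`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_candidate_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    stop("cannot write report to directory: ", dir, call. = FALSE)
  }
  triage_flat <- tibble::tibble(
    gene = report$triage$gene,
    retained_at_step = report$triage$retained_at_step,
    all_steps = vapply(report$triage$all_steps, paste, character(1),
                       collapse = ","),
    n_truncating = report$triage$n_truncating,
    n_conserved_missense = report$triage$n_conserved_missense,
    supporting_variants = vapply(report$triage$supporting_variants, paste,
                                 character(1), collapse = ",")
  )
  tsv_path <- file.path(dir, "candidates.tsv")
  readr::write_tsv(triage_flat, tsv_path)

  json_path <- file.path(dir, "candidates.json")
  jsonlite::write_json(
    list(
      funnel = as.list(report$funnel),
      filter_summary = report$filter_summary,
      biallelic = report$biallelic,
      recurrence = tibble::tibble(
        gene = report$recurrence$gene,
        n_observations = report$recurrence$n_observations,
        n_variants = report$recurrence$n_variants,
        n_carriers = report$recurrence$n_carriers,
        n_unrelated_carriers = report$recurrence$n_unrelated_carriers,
        variants = vapply(report$recurrence$variants, paste, character(1),
                          collapse = ",")
      ),
      burden = report$burden$results,
      known_gene_hits = report$known_gene_hits,
      triage = triage_flat
    ),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  summary_path <- file.path(dir, "summary.txt")
  lines <- c(
    "Candidate-gene discovery report",
    "===============================",
    "",
    "Filter funnel (records remaining after each stage):",
    sprintf("  %-14s %d", names(report$funnel), report$funnel),
    "",
    sprintf("Samples summarized: %d", nrow(report$filter_summary)),
    sprintf("Biallelic candidate genes: %d", nrow(report$biallelic)),
    sprintf("Recurrently affected genes: %d", nrow(report$recurrence)),
    sprintf("Genes surviving burden screen: %d",
            nrow(report$burden$retained)),
    sprintf("Known-gene hits: %d", nrow(report$known_gene_hits)),
    "",
    "Triage:",
    if (nrow(triage_flat) == 0) "  (none)" else
      sprintf("  %-12s %s", triage_flat$gene, triage_flat$retained_at_step)
  )
  writeLines(lines, summary_path)
  invisible(c(tsv = tsv_path, json = json_path, summary = summary_path))
}
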