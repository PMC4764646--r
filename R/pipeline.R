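#' Run the discovery analysis end-to-end
#'
#' Executes, on validated inputs: the filter cascade on the case and
#' control cohorts (same configuration, fingerprint-checked), per-sample
#' biallelic candidate detection, recurrence over unrelated carriers, the
#' case-vs-control burden screen, known-gene annotation, and the
#' four-step triage. Stage record counts (the analysis funnel) are logged
#' when `verbose = TRUE` and always returned. Identical inputs give
#' byte-identical report files.
#'
#' @param case_records,control_records Validated variant tables.
#' @param case_manifest,control_manifest Cohort manifests.
#' @param packs Gene-list packs (see [read_gene_packs()]); all seven ids
#'   are required.
#' @param config A [filter_config()].
#' @param alpha Burden-screen level (default 0.05).
#' @param m BH denominator (default: number of recurrent genes).
#' @param burden_unit `"variants"` or `"carriers"`.
#' @param out_dir Optional directory for the report bundle.
#' @param verbose Log stage counts with `message()` (default FALSE).
#' @return A list: `filter_summary`, `funnel` (named integer vector),
#'   `biallelic`, `recurrence`, `burden`, `known_gene_hits`, `triage`,
#'   plus `case_retained` and `control_retained`.
#' @export
run_discovery <- function(case_records, case_manifest,
                          control_records, control_manifest,
                          packs, config = filter_config(),
                          alpha = 0.05, m = NULL,
                          burden_unit = c("variants", "carriers"),
                          out_dir = NULL, verbose = FALSE) {
  burden_unit <- match.arg(burden_unit)
  missing_packs <- setdiff(pack_ids(), names(packs))
  if (length(missing_packs) > 0) {
    stop("missing gene-list pack(s): ",
         paste(missing_packs, collapse = ", "), call. = FALSE)
  }
  say <- function(...) if (verbose) message(...)

  say("filtering case cohort (", nrow(case_records), " records)")
  case_f <- filter_cohort(case_records, config, packs$lof_tolerant)
  say("filtering control cohort (", nrow(control_records), " records)")
  ctrl_f <- filter_cohort(control_records, config, packs$lof_tolerant)

  say("case records retained: ", nrow(case_f$retained))
  biallelic <- case_f$retained |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(g, key) {
      out <- find_biallelic_candidates(
        dplyr::mutate(g, sample_id = key$sample_id))
      if (nrow(out) > 0) out$sample_id <- key$sample_id
      out
    }) |>
    dplyr::bind_rows()
  if (nrow(biallelic) == 0) {
    biallelic <- tibble::tibble(gene = character(), mechanism = character(),
                                n_variants = integer(),
                                sample_id = character())
  }
  say("biallelic candidate genes: ", nrow(biallelic))

  recurrence <- find_recurrent_genes(case_f$retained, case_manifest)
  say("recurrently affected genes: ", nrow(recurrence))

  burden <- burden_screen(recurrence, case_manifest, ctrl_f$retained,
                          control_manifest, alpha = alpha, m = m,
                          unit = burden_unit)
  say("genes surviving burden screen: ", nrow(burden$retained))

  known <- annotate_known_genes(case_f$retained, packs)
  survivor_records <- case_f$retained[
    case_f$retained$gene %in% burden$retained$gene, , drop = FALSE]
  triage <- triage_candidates(survivor_records, case_manifest, packs)
  say("triage: ", sum(triage$retained_at_step != "none"),
      " gene(s) retained at an evidence step")

  funnel <- c(
    case_f$funnel,
    recurrent_genes = nrow(recurrence),
    burden_survivors = nrow(burden$retained),
    triaged = sum(triage$retained_at_step != "none")
  )
  report <- list(
    filter_summary = case_f$summary,
    funnel = funnel,
    biallelic = biallelic,
    recurrence = recurrence,
    burden = burden,
    known_gene_hits = known,
    triage = triage,
    case_retained = case_f$retained,
    control_retained = ctrl_f$retained
  )
  if (!is.null(out_dir)) {
    write_candidate_report(report, out_dir)
  }
  report
}

#' Run the replication analysis for a candidate-gene list
#'
#' Restricts the replication-cohort calls to the candidate genes, applies
#' the re-sequencing variant selection rule
#' ([select_replication_variants()]), and compares per-gene carrier
#' counts against a second control panel with Fisher's exact test and a
#' BH correction over the candidate genes. When no replication variant
#' qualifies, the Fisher stage is skipped with a notice and an empty
#' comparison table is returned.
#'
#' @param replication_records Validated replication-cohort variant table.
#' @param replication_manifest Replication cohort manifest.
#' @param candidate_genes Character vector of genes to replicate.
#' @param control2_counts Tibble with columns `gene`, `count` (qualifying
#'   variants in the second control panel) and `n_individuals`.
#' @param config A [filter_config()] (drives the selection rule).
#' @param alpha Level for the BH correction (default 0.05).
#' @param panels Panels enforced by the selection rule (default `"evs"`).
#' @param verbose Log stage counts (default FALSE).
#' @return A list: `selected` (qualifying replication records),
#'   `fisher` (per-gene tibble: `gene`, `replication_count`,
#'   `n_replication`, `control2_count`, `n_control2`, `odds_ratio`,
#'   `p_value`, `p_adjusted`, `significant`), `skipped` (flag).
#' @export
run_replication <- function(replication_records, replication_manifest,
                            candidate_genes, control2_counts,
                            config = filter_config(), alpha = 0.05,
                            panels = "evs", verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  restricted <- replication_records[
    replication_records$gene %in% toupper(candidate_genes), , drop = FALSE]
  say("replication records in candidate genes: ", nrow(restricted))
  selected <- select_replication_variants(restricted, config,
                                          panels = panels)
  say("qualifying replication variants: ", nrow(selected))

  empty_fisher <- tibble::tibble(
    gene = character(), replication_count = integer(),
    n_replication = integer(), control2_count = integer(),
    n_control2 = integer(), odds_ratio = double(), p_value = double(),
    p_adjusted = double(), significant = logical()
  )
  if (nrow(selected) == 0) {
    say("no qualifying replication variants; Fisher stage skipped")
    return(list(selected = selected, fisher = empty_fisher,
                skipped = TRUE))
  }
  genes <- sort(unique(toupper(candidate_genes)))
  n_rep <- nrow(replication_manifest)
  rep_carriers <- vapply(genes, function(g) {
    length(unique(selected$sample_id[selected$gene == g]))
  }, integer(1))
  ctrl2 <- control2_counts[match(genes, toupper(control2_counts$gene)), ,
                           drop = FALSE]
  if (any(is.na(ctrl2$count))) {
    stop("control2_counts is missing candidate gene(s): ",
         paste(genes[is.na(ctrl2$count)], collapse = ", "), call. = FALSE)
  }
  fe <- fisher_exact_carriers(rep_carriers, n_rep, ctrl2$count,
                              ctrl2$n_individuals[1])
  bh <- benjamini_hochberg(fe$p_value, alpha = alpha, m = length(genes))
  fisher <- tibble::tibble(
    gene = genes,
    replication_count = as.integer(rep_carriers),
    n_replication = n_rep,
    control2_count = as.integer(ctrl2$count),
    n_control2 = as.integer(ctrl2$n_individuals),
    odds_ratio = fe$odds_ratio,
    p_value = fe$p_value,
    p_adjusted = bh$p_adjusted,
    significant = bh$significant
  )
  list(selected = selected, fisher = fisher, skipped = FALSE)
}

#' Read a pipeline configuration file (YAML)
#'
#' The file mirrors the function arguments: a `paths` block
#' (`case_variants`, `case_manifest`, `control_variants`,
#' `control_manifest`, `packs_dir`, `out_dir`), a `filter` block with any
#' [filter_config()] fields, and a `burden` block (`alpha`, `m`, `unit`).
#'
#' @param path Path to the YAML file.
#' @return A list with elements `paths`, `filter` (a `filter_config`) and
#'   `burden`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  fc <- do.call(filter_config, raw$filter %||% list())
  burden <- raw$burden %||% list()
  list(
    paths = raw$paths %||% list(),
    filter = fc,
    burden = list(
      alpha = burden$alpha %||% 0.05,
      m = burden$m,
      unit = burden$unit %||% "variants"
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the discovery pipeline from a configuration file
#'
#' Thin file-based wrapper over [run_discovery()]: reads the variant
#' tables, manifests and packs named in the config and writes the report
#' bundle to `paths$out_dir`.
#'
#' @param config_path Path to a YAML pipeline configuration.
#' @param verbose Log stage counts (default TRUE).
#' @return The [run_discovery()] report, invisibly.
#' @export
run_discovery_from_config <- function(config_path, verbose = TRUE) {
  cfg <- read_pipeline_config(config_path)
  p <- cfg$paths
  for (need in c("case_variants", "case_manifest", "control_variants",
                 "control_manifest", "packs_dir", "out_dir")) {
    if (is.null(p[[need]])) {
      stop("pipeline config is missing paths$", need, call. = FALSE)
    }
  }
  report <- run_discovery(
    case_records = read_annotated_variants(p$case_variants, "tsv"),
    case_manifest = read_cohort_manifest(p$case_manifest),
    control_records = read_annotated_variants(p$control_variants, "tsv"),
    control_manifest = read_cohort_manifest(p$control_manifest),
    packs = read_gene_packs(p$packs_dir),
    config = cfg$filter,
    alpha = cfg$burden$alpha,
    m = cfg$burden$m,
    burden_unit = cfg$burden$unit,
    out_dir = p$out_dir,
    verbose = verbose
  )
  invisible(report)
}
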