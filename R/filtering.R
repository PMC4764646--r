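#' Filter-cascade configuration
#'
#' Thresholds for the call-level filter cascade. All comparisons are
#' inclusive: a call at exactly a threshold passes.
#'
#' @param min_total_reads Minimum read depth at the position (default 10).
#' @param min_variant_reads Minimum reads supporting the variant (default 5).
#' @param min_unique_starts Minimum unique read start positions (default 5);
#'   only enforced for substitutions, where the field is available.
#' @param min_variant_fraction Minimum fraction of variant reads
#'   (default 0.28).
#' @param max_panel_maf Maximum minor allele frequency tolerated in each
#'   enforced reference panel (default 0.001). A per-panel override of 0
#'   reproduces a strict "absent from panel" rule.
#' @param phylop_min Minimum PhyloP conservation score for a missense
#'   variant to count as conserved (default 3.0). Protein-truncating
#'   classes are retained regardless of PhyloP.
#' @param frequency_panels Panel ids on which the MAF rule is enforced
#'   (default `c("inhouse", "evs")`). Records must carry
#'   `ac_<panel>`/`n_<panel>` columns for each.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_total_reads = 10,
                          min_variant_reads = 5,
                          min_unique_starts = 5,
                          min_variant_fraction = 0.28,
                          max_panel_maf = 0.001,
                          phylop_min = 3.0,
                          frequency_panels = c("inhouse", "evs")) {
  stopifnot(
    min_total_reads >= 0, min_variant_reads >= 0, min_unique_starts >= 0,
    min_variant_fraction > 0, min_variant_fraction <= 1,
    max_panel_maf >= 0, is.finite(phylop_min),
    length(frequency_panels) >= 1
  )
  structure(
    list(
      min_total_reads = min_total_reads,
      min_variant_reads = min_variant_reads,
      min_unique_starts = min_unique_starts,
      min_variant_fraction = min_variant_fraction,
      max_panel_maf = max_panel_maf,
      phylop_min = phylop_min,
      frequency_panels = frequency_panels
    ),
    class = "filter_config"
  )
}

#' Fingerprint of a filter configuration
#'
#' Canonical string encoding every threshold. Case and control cohorts must
#' be filtered under configurations with identical fingerprints before
#' their burdens are comparable; [burden_screen()] enforces this.
#'
#' @param config A [filter_config()].
#' @return A single string.
#' @export
filter_fingerprint <- function(config) {
  stopifnot(inherits(config, "filter_config"))
  vals <- vapply(config, function(v) paste(format(v, digits = 15),
                                           collapse = ","), character(1))
  paste(names(config), vals, sep = "=", collapse = ";")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) {
    cat(" ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read-level quality gate
#'
#' A call passes when depth, variant reads, unique starts and variant-read
#' fraction all meet their thresholds (inclusive). The unique-starts rule is
#' skipped when the field is absent, as it is for insertions/deletions
#' where read starts cannot be counted per allele.
#'
#' @param records A validated variant table.
#' @param config A [filter_config()].
#' @return A tibble with columns `pass` (logical) and `failed_rules`
#'   (list of character vectors naming the violated rules), one row per
#'   input record.
#' @export
passes_quality <- function(records, config = filter_config()) {
  frac <- ifelse(records$total_reads > 0,
                 records$variant_reads / records$total_reads, 0)
  fails <- cbind(
    total_reads = records$total_reads < config$min_total_reads,
    variant_reads = records$variant_reads < config$min_variant_reads,
    unique_starts = !is.na(records$unique_starts) &
      records$unique_starts < config$min_unique_starts,
    variant_fraction = frac < config$min_variant_fraction
  )
  failed_rules <- apply(fails, 1, function(f) colnames(fails)[f],
                        simplify = FALSE)
  tibble::tibble(
    pass = rowSums(fails) == 0,
    failed_rules = if (nrow(records) == 0) list() else failed_rules
  )
}

#' Population-frequency gate
#'
#' A record is retained iff its minor allele frequency is at most
#' `max_panel_maf` in every enforced reference panel. Missing allele counts
#' in an enforced panel are treated as zero observations only if the panel
#' columns exist; an enforced panel without columns is an error, since a
#' silently skipped panel would un-filter common variants.
#'
#' @param records A validated variant table.
#' @param config A [filter_config()].
#' @return Logical vector, one element per record.
#' @export
passes_frequency <- function(records, config = filter_config()) {
  keep <- rep(TRUE, nrow(records))
  for (p in config$frequency_panels) {
    ac_col <- paste0("ac_", p)
    n_col <- paste0("n_", p)
    if (!ac_col %in% names(records) || !n_col %in% names(records)) {
      stop("enforced frequency panel '", p,
           "' is missing from the variant table (need columns ", ac_col,
           " and ", n_col, ")", call. = FALSE)
    }
    ac <- records[[ac_col]]
    nn <- records[[n_col]]
    maf <- ifelse(is.na(ac) | is.na(nn) | nn == 0, 0, ac / (2 * nn))
    keep <- keep & maf <= config$max_panel_maf
  }
  keep
}

#' Classify a variant's predicted impact
#'
#' Nonsense, frameshift and canonical splice-site changes are
#' protein-truncating regardless of conservation. Missense changes count
#' only when their PhyloP score meets `phylop_min` (inclusive). Synonymous
#' and other consequences, and sub-threshold missense, are excluded. A
#' missense record with a missing PhyloP score is excluded with a warning
#' rather than silently.
#'
#' @param records A validated variant table.
#' @param config A [filter_config()].
#' @return Character vector with values `"truncating"`,
#'   `"conserved_missense"` or `"excluded"`.
#' @export
classify_impact <- function(records, config = filter_config()) {
  csq <- records$csq
  truncating <- csq %in% c("nonsense", "frameshift", "canonical_splice")
  missing_phylop <- csq == "missense" & is.na(records$phylop)
  if (any(missing_phylop)) {
    warning(sum(missing_phylop),
            " missense record(s) with missing PhyloP excluded from the ",
            "conserved-missense class", call. = FALSE)
  }
  conserved <- csq == "missense" & !is.na(records$phylop) &
    records$phylop >= config$phylop_min
  ifelse(truncating, "truncating",
         ifelse(conserved, "conserved_missense", "excluded"))
}

#' Drop records in loss-of-function-tolerant genes
#'
#' @param records A validated variant table (gene symbols upper-cased at
#'   ingest).
#' @param lof_tolerant Character vector of LoF-tolerant gene symbols.
#' @return `records` minus rows whose gene is in the tolerant list; order
#'   preserved.
#' @export
exclude_lof_tolerant <- function(records, lof_tolerant) {
  records[!records$gene %in% toupper(lof_tolerant), , drop = FALSE]
}

#' Run the full call-level filter cascade over a cohort
#'
#' Applies, in order: the read-level quality gate, the reference-panel
#' frequency gate, the LoF-tolerant gene exclusion, and impact
#' classification. Retained records are those classified `truncating` or
#' `conserved_missense`; the per-sample summary partitions them into the
#' two classes. A funnel of record counts after each stage is attached for
#' logging.
#'
#' @param records A validated variant table for one cohort.
#' @param config A [filter_config()].
#' @param lof_tolerant Character vector of LoF-tolerant gene symbols
#'   (required; read it with [read_gene_list()], which rejects empty lists).
#' @return A list with elements `retained` (records plus `impact_class`,
#'   carrying the filter fingerprint as attribute `filter_fingerprint`),
#'   `summary` (tibble `sample_id`, `n_truncating`, `n_conserved_missense`,
#'   `n_retained`, one row per sample seen in the input), and `funnel`
#'   (named integer vector of record counts per stage).
#' @export
filter_cohort <- function(records, config = filter_config(), lof_tolerant) {
  stopifnot(is.character(lof_tolerant), length(lof_tolerant) > 0)
  samples <- unique(records$sample_id)

  q <- passes_quality(records, config)
  after_quality <- records[q$pass, , drop = FALSE]
  after_freq <- after_quality[passes_frequency(after_quality, config), ,
                              drop = FALSE]
  after_lof <- exclude_lof_tolerant(after_freq, lof_tolerant)
  impact <- classify_impact(after_lof, config)
  retained <- after_lof[impact != "excluded", , drop = FALSE]
  retained$impact_class <- impact[impact != "excluded"]

  summary <- dplyr::left_join(
    tibble::tibble(sample_id = samples),
    retained |>
      dplyr::count(.data$sample_id, .data$impact_class) |>
      tidyr::pivot_wider(names_from = "impact_class", values_from = "n",
                         values_fill = 0L),
    by = "sample_id"
  )
  for (col in c("truncating", "conserved_missense")) {
    if (!col %in% names(summary)) summary[[col]] <- 0L
    summary[[col]][is.na(summary[[col]])] <- 0L
  }
  summary <- tibble::tibble(
    sample_id = summary$sample_id,
    n_truncating = as.integer(summary$truncating),
    n_conserved_missense = as.integer(summary$conserved_missense),
    n_retained = as.integer(summary$truncating + summary$conserved_missense)
  )

  attr(retained, "filter_fingerprint") <- filter_fingerprint(config)
  list(
    retained = retained,
    summary = summary,
    funnel = c(
      input = nrow(records),
      quality = nrow(after_quality),
      frequency = nrow(after_freq),
      lof_tolerant = nrow(after_lof),
      impact = nrow(retained)
    )
  )
}
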