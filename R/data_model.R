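#' Column layout of an annotated variant table
#'
#' One row is one sequenced allele observation in one sample, together with
#' its gene/transcript annotation, consequence, conservation score, optional
#' in-silico predictor labels, and per-reference-panel allele counts.
#'
#' Fixed columns (in order): `sample_id`, `chrom`, `pos` (1-based), `ref`,
#' `alt`, `total_reads`, `variant_reads`, `unique_starts` (NA for indels),
#' `gene`, `transcript`, `cdna`, `prot`, `csq`, `phylop`, `sift`, `pph2`,
#' `agvgd`, `dbsnp`. Reference panels follow as paired columns
#' `ac_<panel>` (allele count) and `n_<panel>` (diploid individuals in the
#' panel), one pair per panel.
#'
#' @return Character vector of the fixed column names.
#' @export
variant_columns <- function() {
  c(
    "sample_id", "chrom", "pos", "ref", "alt",
    "total_reads", "variant_reads", "unique_starts",
    "gene", "transcript", "cdna", "prot", "csq", "phylop",
    "sift", "pph2", "agvgd", "dbsnp"
  )
}

#' Controlled consequence vocabulary
#'
#' The consequence of a variant on its transcript, collapsed to the classes
#' the filter cascade distinguishes. `canonical_splice` means a change at
#' the +/-1 or +/-2 intronic positions flanking an exon; that definition is
#' encoded upstream by the annotation source, not re-derived here.
#'
#' @return Character vector of accepted `csq` values.
#' @export
consequence_levels <- function() {
  c("nonsense", "frameshift", "canonical_splice", "missense",
    "synonymous", "other")
}

#' Identify reference-panel columns in a variant table
#'
#' @param x A variant table (data frame).
#' @return Character vector of panel ids for which both `ac_<panel>` and
#'   `n_<panel>` columns are present.
#' @export
panel_ids <- function(x) {
  ac <- sub("^ac_", "", grep("^ac_", names(x), value = TRUE))
  nn <- sub("^n_", "", grep("^n_", names(x), value = TRUE))
  intersect(ac, nn)
}

#' Validate an annotated variant table
#'
#' Checks the structural invariants every downstream stage relies on:
#' positive 1-based positions, `0 <= variant_reads <= total_reads`,
#' `unique_starts` absent (NA) for insertions/deletions, consequences drawn
#' from the controlled vocabulary, and panel allele counts bounded by twice
#' the panel size. Missing optional fields must be `NA`, never zero.
#'
#' @param x A data frame with the columns of [variant_columns()] plus any
#'   number of `ac_<panel>`/`n_<panel>` pairs.
#' @param source Label used in error messages (e.g. a file path).
#' @return `x` as a tibble, invisibly classed, with `variant_read_fraction`
#'   added.
#' @export
validate_variant_table <- function(x, source = "variant table") {
  missing_cols <- setdiff(variant_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop(source, ": missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    x$variant_read_fraction <- numeric(0)
    return(x)
  }

  bad <- which(is.na(x$pos) | x$pos < 1)
  if (length(bad) > 0) {
    stop(source, ": row ", bad[1], ": pos must be a 1-based coordinate >= 1",
         call. = FALSE)
  }
  bad <- which(is.na(x$total_reads) | is.na(x$variant_reads) |
                 x$variant_reads < 0 | x$variant_reads > x$total_reads)
  if (length(bad) > 0) {
    stop(source, ": row ", bad[1],
         ": variant_reads must satisfy 0 <= variant_reads <= total_reads",
         call. = FALSE)
  }
  bad <- which(!x$csq %in% consequence_levels())
  if (length(bad) > 0) {
    stop(source, ": row ", bad[1], ": unknown consequence '",
         x$csq[bad[1]], "'; accepted terms are: ",
         paste(consequence_levels(), collapse = ", "), call. = FALSE)
  }
  is_indel <- nchar(x$ref) != nchar(x$alt) | x$csq == "frameshift"
  bad <- which(is_indel & !is.na(x$unique_starts))
  if (length(bad) > 0) {
    stop(source, ": row ", bad[1],
         ": unique_starts must be absent for insertions/deletions",
         call. = FALSE)
  }
  for (p in panel_ids(x)) {
    ac <- x[[paste0("ac_", p)]]
    nn <- x[[paste0("n_", p)]]
    bad <- which(!is.na(ac) & !is.na(nn) & (nn <= 0 | ac > 2 * nn))
    if (length(bad) > 0) {
      stop(source, ": row ", bad[1], ": panel '", p,
           "': allele_count must satisfy 0 <= ac <= 2 * n_individuals",
           call. = FALSE)
    }
  }
  x$gene <- toupper(x$gene)
  x$variant_read_fraction <- x$variant_reads / x$total_reads
  x
}

#' Minor allele frequency from an allele count and a panel size
#'
#' MAF is the allele count divided by the chromosome count `2 * n` of the
#' diploid panel. Cohort tables that print carrier counts with all carriers
#' heterozygous use the carrier count as the allele count, so e.g. one
#' carrier among 55 individuals gives 1 / 110 = 0.009091.
#'
#' @param allele_count Non-negative allele count(s), at most `2 * n_individuals`.
#' @param n_individuals Positive number of diploid individuals in the panel.
#' @return Frequency in `[0, 1]`; vectorized over both arguments.
#' @examples
#' compute_maf(1, 55)      # 0.00909...
#' compute_maf(111, 60706) # 0.000914...
#' @export
compute_maf <- function(allele_count, n_individuals) {
  if (any(is.na(n_individuals)) || any(n_individuals <= 0)) {
    stop("n_individuals must be > 0", call. = FALSE)
  }
  if (any(is.na(allele_count)) || any(allele_count < 0) ||
      any(allele_count > 2 * n_individuals)) {
    stop("allele_count must satisfy 0 <= allele_count <= 2 * n_individuals",
         call. = FALSE)
  }
  allele_count / (2 * n_individuals)
}
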