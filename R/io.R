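#' Read an annotated variant table (TSV or VCF dialect)
#'
#' Both dialects yield one row per sample-variant observation with the
#' columns of [variant_columns()] plus one `ac_<panel>`/`n_<panel>` pair per
#' reference panel, validated by [validate_variant_table()]. Coordinates are
#' 1-based (VCF convention) in both dialects.
#'
#' The TSV dialect is a tab-separated file with header
#' `sample_id chrom pos ref alt total_reads variant_reads unique_starts
#' gene transcript cdna prot csq phylop sift pph2 agvgd dbsnp ac_* n_*`;
#' an empty string means absent and is read as `NA` (never coerced to zero).
#'
#' The VCF dialect expects per-sample FORMAT fields `DP` (total reads),
#' `VR` (variant reads) and `US` (unique starts, substitutions only), and
#' INFO keys `GENE`, `TRANSCRIPT`, `CDNA`, `PROT`, `CSQ`, `PHYLOP`, `SIFT`,
#' `PPH2`, `AGVGD`, `DBSNP`, plus `AC_<panel>`/`N_<panel>` pairs. A
#' sample-variant observation is emitted for every sample whose genotype
#' carries the ALT allele (or, with a missing GT, whose `VR` is positive).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A tibble, one row per sample-variant observation, with
#'   `variant_read_fraction` added.
#' @export
read_annotated_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  x <- switch(dialect,
    tsv = read_variants_tsv(path),
    vcf = read_variants_vcf(path)
  )
  validate_variant_table(x, source = path)
}

read_variants_tsv <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      total_reads = readr::col_integer(),
      variant_reads = readr::col_integer(),
      unique_starts = readr::col_integer(),
      gene = readr::col_character(),
      transcript = readr::col_character(),
      cdna = readr::col_character(),
      prot = readr::col_character(),
      csq = readr::col_character(),
      phylop = readr::col_double(),
      sift = readr::col_character(),
      pph2 = readr::col_character(),
      agvgd = readr::col_character(),
      dbsnp = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"),
    progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop(path, ": malformed row at line ", probs$row[1] + 1L, ": ",
         probs$expected[1], ", got '", probs$actual[1], "'", call. = FALSE)
  }
  x
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(vcf, getINFO = FALSE))
  n_var <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]

  info_chr <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n_var) else as.character(v)
  }
  info_num <- function(key) suppressWarnings(as.numeric(info_chr(key)))

  # discover reference panels from the header
  meta_ids <- regmatches(vcf@meta, regexpr("ID=[A-Za-z0-9_]+", vcf@meta))
  meta_ids <- sub("^ID=", "", meta_ids)
  panels <- intersect(
    sub("^AC_", "", grep("^AC_", meta_ids, value = TRUE)),
    sub("^N_", "", grep("^N_", meta_ids, value = TRUE))
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  vr <- vcfR::extract.gt(vcf, element = "VR", as.numeric = TRUE)
  us <- vcfR::extract.gt(vcf, element = "US", as.numeric = TRUE)

  carries <- function(g, v) {
    ifelse(is.na(g), !is.na(v) & v > 0, grepl("1", g, fixed = TRUE))
  }

  rows <- list()
  for (s in samples) {
    keep <- which(carries(gt[, s], vr[, s]))
    if (length(keep) == 0) next
    row <- tibble::tibble(
      sample_id = s,
      chrom = fix$CHROM[keep],
      pos = as.integer(fix$POS[keep]),
      ref = fix$REF[keep],
      alt = fix$ALT[keep],
      total_reads = as.integer(dp[keep, s]),
      variant_reads = as.integer(vr[keep, s]),
      unique_starts = as.integer(us[keep, s]),
      gene = info_chr("GENE")[keep],
      transcript = info_chr("TRANSCRIPT")[keep],
      cdna = info_chr("CDNA")[keep],
      prot = info_chr("PROT")[keep],
      csq = info_chr("CSQ")[keep],
      phylop = info_num("PHYLOP")[keep],
      sift = info_chr("SIFT")[keep],
      pph2 = info_chr("PPH2")[keep],
      agvgd = info_chr("AGVGD")[keep],
      dbsnp = info_chr("DBSNP")[keep]
    )
    for (p in panels) {
      row[[paste0("ac_", p)]] <- info_num(paste0("AC_", p))[keep]
      row[[paste0("n_", p)]] <- info_num(paste0("N_", p))[keep]
    }
    rows[[s]] <- row
  }
  if (length(rows) == 0) {
    out <- tibble::tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), total_reads = integer(),
      variant_reads = integer(), unique_starts = integer(),
      gene = character(), transcript = character(), cdna = character(),
      prot = character(), csq = character(), phylop = double(),
      sift = character(), pph2 = character(), agvgd = character(),
      dbsnp = character()
    )
    for (p in panels) {
      out[[paste0("ac_", p)]] <- double()
      out[[paste0("n_", p)]] <- double()
    }
    return(out)
  }
  dplyr::bind_rows(rows)
}

#' Write a variant table in the TSV dialect
#'
#' Inverse of the TSV reader: `NA` is written as the empty string, the
#' derived `variant_read_fraction` column is dropped, and a written table
#' read back with [read_annotated_variants()] is identical on all fields.
#'
#' @param x A validated variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(x, path) {
  keep <- c(variant_columns(),
            as.vector(rbind(paste0("ac_", panel_ids(x)),
                            paste0("n_", panel_ids(x)))))
  readr::write_tsv(x[, intersect(keep, names(x))], path, na = "")
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; `#` starts a comment; blank lines are ignored.
#' Symbols are upper-cased and de-duplicated. An empty result is an error,
#' because an empty evidence list would silently disable the triage step it
#' feeds.
#'
#' @param path Path to the list file.
#' @return Sorted character vector of unique, upper-cased gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("gene list not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  symbols <- unique(toupper(lines[nzchar(lines)]))
  if (length(symbols) == 0) {
    stop("gene list is empty: ", path, call. = FALSE)
  }
  sort(symbols)
}

#' Recognized gene-list pack ids
#' @return Character vector of the seven list ids the triage stages use.
#' @export
pack_ids <- function() {
  c("crc_predisposition", "cancer_syndrome", "lof_tolerant", "crc_driver",
    "mouse_transposon", "kegg_cancer_pathways", "gwas")
}

#' Read a directory of gene-list packs
#'
#' The directory must contain a `manifest.tsv` with columns `list_id` and
#' `file`, each file a plain-text gene list. Unknown `list_id`s are an
#' error; missing packs are permitted here and checked by the stages that
#' need them.
#'
#' @param dir Directory containing `manifest.tsv` and the list files.
#' @return Named list of symbol vectors, one per pack.
#' @export
read_gene_packs <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop("pack manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- readr::read_tsv(manifest_path, col_types = "cc",
                              progress = FALSE, show_col_types = FALSE)
  bad <- setdiff(manifest$list_id, pack_ids())
  if (length(bad) > 0) {
    stop("unknown list_id in pack manifest: ", paste(bad, collapse = ", "),
         "; accepted ids: ", paste(pack_ids(), collapse = ", "),
         call. = FALSE)
  }
  packs <- lapply(file.path(dir, manifest$file), read_gene_list)
  names(packs) <- manifest$list_id
  packs
}

#' Locate the gene-list packs shipped with the package
#'
#' The bundled packs are illustrative reconstructions for demonstration and
#' testing: each contains the genes the triage logic must recognize plus
#' field-standard members, but none is pinned to a specific external
#' catalog release. Substitute your own packs directory for real analyses.
#'
#' @return Path to the bundled packs directory.
#' @export
default_packs_dir <- function() {
  system.file("extdata", "packs", package = "crcburden", mustWork = TRUE)
}

#' Read a cohort manifest
#'
#' Tab-separated with columns `sample_id`, `cohort_id`, `role` (one of
#' `discovery`, `replication`, `control`) and `family_id`. Sample ids must
#' be unique; `family_id` groups related individuals so recurrence can be
#' counted over unrelated carriers.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with one row per sample.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  m <- readr::read_tsv(path, col_types = "cccc", progress = FALSE,
                       show_col_types = FALSE)
  needed <- c("sample_id", "cohort_id", "role", "family_id")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols) > 0) {
    stop(path, ": manifest is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(m$sample_id)) {
    stop(path, ": duplicated sample_id in manifest", call. = FALSE)
  }
  bad <- setdiff(unique(m$role), c("discovery", "replication", "control"))
  if (length(bad) > 0) {
    stop(path, ": unknown role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}
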