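#' Is a chromosome name an autosome?
#'
#' Accepts `"1"`..`"22"` with or without a `chr` prefix; everything else
#' (X, Y, MT, contigs) is non-autosomal.
#'
#' @param chrom Character vector of chromosome names.
#' @return Logical vector.
#' @export
is_autosome <- function(chrom) {
  core <- sub("^chr", "", chrom, ignore.case = TRUE)
  core %in% as.character(1:22)
}

#' Call zygosity from the variant-read fraction
#'
#' A call is homozygous only on an autosome with at least 95% variant
#' reads (inclusive); anything else — including high-fraction calls on sex
#' chromosomes, where hemizygosity confounds the read fraction — is called
#' heterozygous. No genotype-likelihood model is used.
#'
#' @param records A validated variant table (needs `chrom`,
#'   `variant_read_fraction`).
#' @param hom_fraction Minimum variant-read fraction for a homozygous call
#'   (default 0.95).
#' @return Character vector of `"hom"`/`"het"`, one element per record.
#' @export
call_zygosity <- function(records, hom_fraction = 0.95) {
  ifelse(is_autosome(records$chrom) &
           records$variant_read_fraction >= hom_fraction,
         "hom", "het")
}

#' Genes with putative biallelic variants in one sample
#'
#' A gene is a biallelic (recessive-model) candidate in a sample when the
#' sample carries a homozygous qualifying variant in it, or at least two
#' distinct heterozygous qualifying variants (putative compound
#' heterozygote; phasing is unavailable, so trans configuration is not
#' verified). Identical variants (same chrom/pos/alt) count once.
#'
#' @param sample_records Retained (filtered) records of a single sample.
#' @param hom_fraction Passed to [call_zygosity()].
#' @return A tibble with columns `gene`, `mechanism`
#'   (`"homozygous"` or `"putative_compound_het"`) and `n_variants`.
#' @export
find_biallelic_candidates <- function(sample_records, hom_fraction = 0.95) {
  if (nrow(sample_records) == 0) {
    return(tibble::tibble(gene = character(), mechanism = character(),
                          n_variants = integer()))
  }
  if (length(unique(sample_records$sample_id)) > 1) {
    stop("find_biallelic_candidates expects records of a single sample",
         call. = FALSE)
  }
  zyg <- call_zygosity(sample_records, hom_fraction)
  key <- paste(sample_records$chrom, sample_records$pos,
               sample_records$alt, sep = ":")
  distinct <- !duplicated(key)
  x <- tibble::tibble(
    gene = sample_records$gene[distinct],
    zyg = zyg[distinct]
  )
  out <- x |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      any_hom = any(.data$zyg == "hom"),
      n_het = sum(.data$zyg == "het"),
      n_variants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$any_hom | .data$n_het >= 2) |>
    dplyr::mutate(
      mechanism = ifelse(.data$any_hom, "homozygous", "putative_compound_het")
    )
  tibble::tibble(gene = out$gene, mechanism = out$mechanism,
                 n_variants = as.integer(out$n_variants)) |>
    dplyr::arrange(.data$gene)
}

#' Genes recurrently affected across unrelated individuals
#'
#' A gene is recurrent when qualifying variants occur in at least
#' `min_unrelated` distinct families of the cohort. Identical variants in
#' different families count as evidence (a shared rare allele in unrelated
#' carriers is recurrence, not duplication). With
#' `require_unrelated = FALSE` the looser reading — at least two distinct
#' qualifying variants anywhere in the cohort, even in one individual —
#' is applied instead.
#'
#' @param records Retained (filtered) records of one cohort.
#' @param manifest Cohort manifest mapping `sample_id` to `family_id`
#'   (see [read_cohort_manifest()]).
#' @param min_unrelated Minimum number of distinct carrier families
#'   (default 2).
#' @param require_unrelated Use the unrelated-carriers rule (default TRUE).
#' @return A tibble with one row per recurrent gene: `gene`,
#'   `n_observations` (sample-variant observations, the burden-screen
#'   unit), `n_variants` (distinct variant identities), `n_carriers`,
#'   `n_unrelated_carriers`, and list-columns `carriers`, `families` and
#'   `variants` (the distinct `chrom:pos:ref>alt` identities). Carries the
#'   input's `filter_fingerprint` attribute forward.
#' @export
find_recurrent_genes <- function(records, manifest, min_unrelated = 2,
                                 require_unrelated = TRUE) {
  missing_samples <- setdiff(unique(records$sample_id), manifest$sample_id)
  if (length(missing_samples) > 0) {
    stop("sample(s) missing from manifest: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(
    gene = character(), n_observations = integer(), n_variants = integer(),
    n_carriers = integer(), n_unrelated_carriers = integer(),
    carriers = list(), families = list(), variants = list()
  )
  if (nrow(records) == 0) {
    attr(empty, "filter_fingerprint") <- attr(records, "filter_fingerprint")
    return(empty)
  }
  x <- tibble::tibble(
    gene = records$gene,
    sample_id = records$sample_id,
    variant = paste0(records$chrom, ":", records$pos, ":",
                     records$ref, ">", records$alt),
    family_id = manifest$family_id[match(records$sample_id,
                                         manifest$sample_id)]
  )
  out <- x |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_observations = dplyr::n(),
      n_variants = dplyr::n_distinct(.data$variant),
      n_carriers = dplyr::n_distinct(.data$sample_id),
      n_unrelated_carriers = dplyr::n_distinct(.data$family_id),
      carriers = list(sort(unique(.data$sample_id))),
      families = list(sort(unique(.data$family_id))),
      variants = list(sort(unique(.data$variant))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
  keep <- if (require_unrelated) {
    out$n_unrelated_carriers >= min_unrelated
  } else {
    out$n_variants >= min_unrelated | out$n_unrelated_carriers >= min_unrelated
  }
  out <- out[keep, , drop = FALSE]
  out$n_observations <- as.integer(out$n_observations)
  out$n_variants <- as.integer(out$n_variants)
  out$n_carriers <- as.integer(out$n_carriers)
  out$n_unrelated_carriers <- as.integer(out$n_unrelated_carriers)
  attr(out, "filter_fingerprint") <- attr(records, "filter_fingerprint")
  out
}

#' Write a recurrence table as TSV
#'
#' @param recurrence Output of [find_recurrent_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recurrence_tsv <- function(recurrence, path) {
  flat <- tibble::tibble(
    gene = recurrence$gene,
    n_variants = recurrence$n_variants,
    n_carriers = recurrence$n_carriers,
    n_unrelated_carriers = recurrence$n_unrelated_carriers,
    variants = vapply(recurrence$variants, paste, character(1),
                      collapse = ",")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
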