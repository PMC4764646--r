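#' Deterministic demonstration cohort with embedded candidate variants
#'
#' Builds a small, fully deterministic case-control bundle around eight
#' reported early-onset CRC candidate-gene variants: two canonical
#' splice-site changes in *EMR3* (carriers P025 and P002), three conserved
#' missense observations in *PTPN12* (p.R522M in P014; p.S684L shared by
#' the unrelated carriers P045 and P054), and three conserved missense
#' variants in *LRP6* (p.W239L in P002, p.N789S in P001, p.T867A in P008),
#' with their published PhyloP scores and reference-panel allele counts.
#' These are embedded in background noise variants, every one of which is
#' constructed to fail exactly one filter gate (read-level quality, panel
#' frequency, LoF-tolerant gene, or impact class), so the full discovery
#' pipeline must retain exactly the eight embedded variants and triage
#' *EMR3* at step 1, *PTPN12* at step 2 (driver list) and *LRP6* at step 3
#' (mouse transposon hits intersected with cancer KEGG pathways).
#'
#' The replication bundle contains one qualifying *PTPN12* variant
#' (p.A105V in sample RC204, PhyloP 4.24, absent from all panels) among
#' failing noise, and per-gene qualifying-variant counts for a second,
#' larger control panel (2,329 individuals) for the Fisher stage.
#'
#' All sample identities, counts and scores are fixed constants; the
#' bundle involves no randomness.
#'
#' @param dir Optional directory; when given, the tables, manifests and a
#'   copy of the bundled gene-list packs are written there in the TSV
#'   dialect.
#' @return A list: `discovery`, `discovery_manifest`, `control1`,
#'   `control1_manifest`, `replication`, `replication_manifest`,
#'   `control2_counts` (tibble `gene`, `count`, `n_individuals`),
#'   `packs_dir`.
#' @export
make_fixture_cohort <- function(dir = NULL) {
  v <- function(sample_id, chrom, pos, ref, alt, gene, transcript, cdna,
                prot, csq, phylop, dbsnp = NA_character_,
                total_reads = 60L, variant_reads = 30L,
                unique_starts = 12L,
                ac_inhouse = 0, ac_evs = 0, ac_control2 = 0, ac_exac = 0,
                sift = NA_character_, pph2 = NA_character_,
                agvgd = NA_character_) {
    if (nchar(ref) != nchar(alt)) unique_starts <- NA_integer_
    tibble::tibble(
      sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
      ref = ref, alt = alt, total_reads = as.integer(total_reads),
      variant_reads = as.integer(variant_reads),
      unique_starts = as.integer(unique_starts),
      gene = gene, transcript = transcript, cdna = cdna, prot = prot,
      csq = csq, phylop = phylop, sift = sift, pph2 = pph2, agvgd = agvgd,
      dbsnp = dbsnp,
      ac_inhouse = ac_inhouse, n_inhouse = 2037,
      ac_evs = ac_evs, n_evs = 6503,
      ac_control2 = ac_control2, n_control2 = 2329,
      ac_exac = ac_exac, n_exac = 60706
    )
  }

  embedded <- dplyr::bind_rows(
    v("P025", "19", 14496000, "G", "A", "EMR3", "NM_032571",
      "c.882+1G>A", "p.?", "canonical_splice", 2.427,
      ac_evs = 1, ac_exac = 11),
    v("P002", "19", 14503000, "A", "C", "EMR3", "NM_032571",
      "c.1249-2A>C", "p.?", "canonical_splice", 3.787,
      ac_control2 = 1),
    v("P014", "7", 77538000, "G", "T", "PTPN12", "NM_002835",
      "c.1565G>T", "p.R522M", "missense", 4.531,
      ac_control2 = 2, sift = "Del.", pph2 = "Prob.dam.", agvgd = "C25"),
    v("P045", "7", 77541000, "C", "T", "PTPN12", "NM_002835",
      "c.2051C>T", "p.S684L", "missense", 3.958, dbsnp = "rs201001953",
      ac_evs = 3, ac_control2 = 3, ac_exac = 111,
      sift = "Del.", pph2 = "Prob.dam.", agvgd = "C0"),
    v("P054", "7", 77541000, "C", "T", "PTPN12", "NM_002835",
      "c.2051C>T", "p.S684L", "missense", 3.958, dbsnp = "rs201001953",
      ac_evs = 3, ac_control2 = 3, ac_exac = 111,
      sift = "Del.", pph2 = "Prob.dam.", agvgd = "C0"),
    v("P002", "12", 12272000, "C", "A", "LRP6", "NM_002336",
      "c.716C>A", "p.W239L", "missense", 5.103,
      sift = "Del.", pph2 = "Prob.dam.", agvgd = "C65"),
    v("P001", "12", 12290000, "T", "C", "LRP6", "NM_002336",
      "c.2366T>C", "p.N789S", "missense", 6.244,
      sift = "Del.", pph2 = "Benign", agvgd = "C55"),
    v("P008", "12", 12294000, "A", "G", "LRP6", "NM_002336",
      "c.2599A>G", "p.T867A", "missense", 5.13, dbsnp = "rs141458215",
      ac_control2 = 3, ac_exac = 14,
      sift = "Del", pph2 = "Benign", agvgd = "C55")
  )

  case_ids <- sprintf("P%03d", 1:55)
  # one failing noise variant per case sample, cycling through the gates
  noise_row <- function(sample_id, i) {
    kind <- i %% 5
    if (kind == 0) {        # fails read-level quality (27% variant reads)
      v(sample_id, "2", 1000000 + i, "G", "A", "NOISEQ", "NM_900001",
        "c.100G>A", "p.G34S", "missense", 5.0,
        total_reads = 100L, variant_reads = 27L, unique_starts = 10L)
    } else if (kind == 1) { # common in the EVS panel
      v(sample_id, "3", 2000000 + i, "G", "A", "NOISEF", "NM_900002",
        "c.200G>A", "p.R67H", "missense", 5.5, ac_evs = 100)
    } else if (kind == 2) { # LoF-tolerant gene
      v(sample_id, "4", 3000000 + i, "C", "T", "OR4C11", "NM_900003",
        "c.300C>T", "p.R100W", "missense", 6.0)
    } else if (kind == 3) { # synonymous
      v(sample_id, "5", 4000000 + i, "T", "C", "NOISES", "NM_900004",
        "c.400T>C", "p.=", "synonymous", 1.2)
    } else {                # missense below the conservation cutoff
      v(sample_id, "6", 5000000 + i, "A", "G", "NOISEP", "NM_900005",
        "c.500A>G", "p.K167E", "missense", 2.1)
    }
  }
  noise <- dplyr::bind_rows(
    lapply(seq_along(case_ids),
           function(i) noise_row(case_ids[i], i))
  )
  discovery <- validate_variant_table(
    dplyr::bind_rows(embedded, noise), "fixture discovery cohort")
  discovery_manifest <- tibble::tibble(
    sample_id = case_ids, cohort_id = "fixture_discovery",
    role = "discovery", family_id = sprintf("F%03d", 1:55)
  )

  ctrl_ids <- sprintf("C%03d", 1:164)
  # controls carry only failing noise: no qualifying burden anywhere
  control1 <- validate_variant_table(
    dplyr::bind_rows(
      lapply(seq_along(ctrl_ids),
             function(i) noise_row(ctrl_ids[i], i + 1))
    ),
    "fixture control cohort 1")
  control1_manifest <- tibble::tibble(
    sample_id = ctrl_ids, cohort_id = "fixture_control1",
    role = "control", family_id = sprintf("FC%03d", 1:164)
  )

  rep_ids <- c("RC204", sprintf("R%03d", 1:173))
  replication <- validate_variant_table(
    dplyr::bind_rows(
      v("RC204", "7", 77510000, "C", "T", "PTPN12", "NM_002835",
        "c.314C>T", "p.A105V", "missense", 4.24,
        total_reads = 500L, variant_reads = 240L, unique_starts = 40L,
        sift = "Del.", pph2 = "Prob.dam.", agvgd = "C65"),
      # failing noise in the three candidate genes
      v("R001", "7", 77512000, "G", "A", "PTPN12", "NM_002835",
        "c.330G>A", "p.M110I", "missense", 1.4,
        total_reads = 400L, variant_reads = 190L, unique_starts = 30L),
      v("R002", "12", 12275000, "G", "A", "LRP6", "NM_002336",
        "c.800G>A", "p.R267Q", "missense", 4.8, ac_evs = 90,
        total_reads = 350L, variant_reads = 160L, unique_starts = 25L)
    ),
    "fixture replication cohort")
  replication_manifest <- tibble::tibble(
    sample_id = rep_ids, cohort_id = "fixture_replication",
    role = "replication",
    family_id = paste0("FR", seq_along(rep_ids))
  )

  control2_counts <- tibble::tibble(
    gene = c("EMR3", "PTPN12", "LRP6"),
    count = c(1L, 4L, 5L),
    n_individuals = 2329L
  )

  bundle <- list(
    discovery = discovery,
    discovery_manifest = discovery_manifest,
    control1 = control1,
    control1_manifest = control1_manifest,
    replication = replication,
    replication_manifest = replication_manifest,
    control2_counts = control2_counts,
    packs_dir = default_packs_dir()
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_variant_tsv(discovery, file.path(dir, "discovery.tsv"))
    write_variant_tsv(control1, file.path(dir, "control1.tsv"))
    write_variant_tsv(replication, file.path(dir, "replication.tsv"))
    readr::write_tsv(discovery_manifest,
                     file.path(dir, "discovery_manifest.tsv"))
    readr::write_tsv(control1_manifest,
                     file.path(dir, "control1_manifest.tsv"))
    readr::write_tsv(replication_manifest,
                     file.path(dir, "replication_manifest.tsv"))
    readr::write_tsv(control2_counts,
                     file.path(dir, "control2_counts.tsv"))
    packs_out <- file.path(dir, "packs")
    if (!dir.exists(packs_out)) dir.create(packs_out)
    file.copy(list.files(default_packs_dir(), full.names = TRUE),
              packs_out, overwrite = TRUE)
  }
  bundle
}
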