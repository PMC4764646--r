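# In-code fixture builders shared across the suite.

# A valid variant record row with overridable fields; panels inhouse + evs.
mk_record <- function(sample_id = "S1", chrom = "1", pos = 100L,
                      ref = "A", alt = "G", total_reads = 60L,
                      variant_reads = 30L, unique_starts = 12L,
                      gene = "GENE1", transcript = "NM_000001",
                      cdna = "c.100A>G", prot = "p.K34E",
                      csq = "missense", phylop = 5.0,
                      sift = NA_character_, pph2 = NA_character_,
                      agvgd = NA_character_, dbsnp = NA_character_,
                      ac_inhouse = 0, n_inhouse = 2037,
                      ac_evs = 0, n_evs = 6503) {
  if (nchar(ref) != nchar(alt) || csq == "frameshift") {
    unique_starts <- NA_integer_
    if (nchar(ref) == nchar(alt)) ref <- "AT"  # keep indel shape consistent
  }
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, total_reads = as.integer(total_reads),
    variant_reads = as.integer(variant_reads),
    unique_starts = as.integer(unique_starts),
    gene = gene, transcript = transcript, cdna = cdna, prot = prot,
    csq = csq, phylop = phylop, sift = sift, pph2 = pph2, agvgd = agvgd,
    dbsnp = dbsnp, ac_inhouse = ac_inhouse, n_inhouse = n_inhouse,
    ac_evs = ac_evs, n_evs = n_evs
  )
}

mk_records <- function(...) {
  validate_variant_table(dplyr::bind_rows(...), "test fixture")
}

mk_manifest <- function(sample_ids, family_ids = NULL, role = "discovery") {
  tibble::tibble(
    sample_id = sample_ids,
    cohort_id = "test",
    role = role,
    family_id = family_ids %||% paste0("F_", sample_ids)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal VCF in the package's VCF dialect, written to a temp file.
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description=\"Transcript\">",
    "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS c.\">",
    "##INFO=<ID=PROT,Number=1,Type=String,Description=\"HGVS p.\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=PHYLOP,Number=1,Type=Float,Description=\"PhyloP\">",
    "##INFO=<ID=AC_inhouse,Number=1,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=N_inhouse,Number=1,Type=Integer,Description=\"N\">",
    "##INFO=<ID=AC_evs,Number=1,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=N_evs,Number=1,Type=Integer,Description=\"N\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=VR,Number=1,Type=Integer,Description=\"Variant reads\">",
    "##FORMAT=<ID=US,Number=1,Type=Integer,Description=\"Unique starts\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE_A", "SAMPLE_B", sep = "\t"),
    paste("7", "1565", ".", "G", "T", ".", ".",
          paste0("GENE=PTPN12;TRANSCRIPT=NM_002835;CDNA=c.1565G>T;",
                 "PROT=p.R522M;CSQ=missense;PHYLOP=4.531;",
                 "AC_inhouse=0;N_inhouse=2037;AC_evs=0;N_evs=6503"),
          "GT:DP:VR:US", "0/1:60:30:12", "0/0:55:0:0", sep = "\t"),
    paste("1", "2000", ".", "C", "A", ".", ".",
          paste0("GENE=GENE2;TRANSCRIPT=NM_000002;CDNA=c.10C>A;",
                 "PROT=p.?;CSQ=nonsense;PHYLOP=1.2;",
                 "AC_inhouse=1;N_inhouse=2037;AC_evs=2;N_evs=6503"),
          "GT:DP:VR:US", "0/0:40:0:0", "0/1:45:20:9", sep = "\t")
  )
  writeLines(lines, path)
  path
}

test_packs <- function() read_gene_packs(default_packs_dir())
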