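#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated case-control exome
#' study. Per sample and gene, qualifying-variant counts are Poisson with
#' a per-individual rate derived from `background_rate` (the expected
#' number of qualifying variants per gene across the whole case cohort);
#' spiked genes multiply the case rate by their relative risk. Each
#' emitted variant draws read-level evidence, an impact class, a PhyloP
#' score from a two-component uniform mixture straddling the conservation
#' cutoff, and reference-panel allele counts straddling the MAF cutoff, so
#' every filter gate is exercised on both sides of its threshold.
#'
#' @param n_case Number of case individuals (default 55).
#' @param n_control Number of control individuals (default 164).
#' @param n_genes Number of genes (default 100).
#' @param background_rate Expected qualifying variants per gene summed
#'   over the case cohort (default 1.0); the per-individual Poisson rate
#'   is `background_rate / n_case` in both cohorts.
#' @param spiked_genes Named numeric vector: names are gene symbols
#'   (must be among the generated `G0001`-style names), values are
#'   relative risks (>= 1) applied to the case rate (default none).
#' @param fraction_truncating Probability a variant is protein-truncating
#'   (default 0.15, the truncating share of qualifying calls in a typical
#'   early-onset CRC exome screen); otherwise missense.
#' @param p_conserved Probability a missense variant draws its PhyloP
#'   from the conserved component, uniform on `[3, 7]`; otherwise uniform
#'   on `[0, 3)` (default 0.7).
#' @param fraction_common Probability a variant is common in the
#'   reference panels (MAF above 0.001 in every panel; default 0.1).
#' @param fraction_quality_fail Probability a variant's read-level
#'   evidence is drawn to fail at least one quality rule (default 0.1).
#' @param fraction_homozygous Probability a call is homozygous
#'   (variant-read fraction drawn at or above 0.95; default 0.02).
#' @param panels Named integer vector of reference-panel sizes
#'   (default `c(inhouse = 2037, evs = 6503)`).
#' @param families Optional named character vector mapping sample ids to
#'   family ids; unmapped samples are unrelated singletons (the default).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 55,
                              n_control = 164,
                              n_genes = 100,
                              background_rate = 1.0,
                              spiked_genes = c(),
                              fraction_truncating = 0.15,
                              p_conserved = 0.7,
                              fraction_common = 0.1,
                              fraction_quality_fail = 0.1,
                              fraction_homozygous = 0.02,
                              panels = c(inhouse = 2037L, evs = 6503L),
                              families = NULL,
                              seed = 1L) {
  stopifnot(
    n_case >= 1, n_control >= 1, n_genes >= 1, background_rate >= 0,
    fraction_truncating >= 0, fraction_truncating <= 1,
    p_conserved >= 0, p_conserved <= 1,
    fraction_common >= 0, fraction_common <= 1,
    fraction_quality_fail >= 0, fraction_quality_fail <= 1,
    fraction_homozygous >= 0, fraction_homozygous <= 1,
    length(panels) >= 1, !is.null(names(panels))
  )
  if (length(spiked_genes) > 0) {
    stopifnot(!is.null(names(spiked_genes)), all(spiked_genes >= 1))
  }
  structure(
    list(
      n_case = n_case, n_control = n_control, n_genes = n_genes,
      background_rate = background_rate, spiked_genes = spiked_genes,
      fraction_truncating = fraction_truncating,
      p_conserved = p_conserved, fraction_common = fraction_common,
      fraction_quality_fail = fraction_quality_fail,
      fraction_homozygous = fraction_homozygous, panels = panels,
      families = families, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Gene names used by the generator
#' @param n_genes Number of genes.
#' @return Character vector `G0001`, `G0002`, ...
#' @export
simulated_gene_names <- function(n_genes) {
  sprintf("G%04d", seq_len(n_genes))
}

# run code under a local RNG state so simulation never disturbs the
# caller's random stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Simulate a case-control exome cohort with known truth
#'
#' Generates annotated variant tables for a case (discovery) cohort and a
#' control cohort, their manifests, and a truth record stating, for every
#' emitted variant, whether it was constructed to pass each filter gate,
#' and for every gene whether it was spiked. The tables are valid input
#' for the package's readers and filter cascade; written with
#' [write_variant_tsv()] they round-trip exactly.
#'
#' @param config A [simulation_config()].
#' @return A list: `case`, `control` (variant tibbles), `case_manifest`,
#'   `control_manifest`, `truth` (list with `genes` and `variants`
#'   tibbles), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- simulated_gene_names(config$n_genes)
  bad_spike <- setdiff(names(config$spiked_genes), genes)
  if (length(bad_spike) > 0) {
    stop("spiked gene(s) not among generated genes: ",
         paste(bad_spike, collapse = ", "), call. = FALSE)
  }
  with_local_seed(config$seed, {
    rate_ind <- config$background_rate / config$n_case
    rr <- setNames(rep(1, config$n_genes), genes)
    rr[names(config$spiked_genes)] <- config$spiked_genes

    case_ids <- sprintf("S%04d", seq_len(config$n_case))
    ctrl_ids <- sprintf("C%04d", seq_len(config$n_control))
    fam_of <- function(ids, prefix) {
      fams <- paste0(prefix, seq_along(ids))
      if (!is.null(config$families)) {
        hit <- ids %in% names(config$families)
        fams[hit] <- config$families[ids[hit]]
      }
      fams
    }
    case_manifest <- tibble::tibble(
      sample_id = case_ids, cohort_id = "sim_discovery",
      role = "discovery", family_id = fam_of(case_ids, "FD")
    )
    control_manifest <- tibble::tibble(
      sample_id = ctrl_ids, cohort_id = "sim_control1",
      role = "control", family_id = fam_of(ctrl_ids, "FC")
    )

    gene_chrom <- as.character(rep_len(1:22, config$n_genes))
    gene_base <- seq_len(config$n_genes) * 1000000L

    emit <- function(sample_ids, is_case) {
      ns <- length(sample_ids)
      lam <- matrix(rate_ind, nrow = ns, ncol = config$n_genes,
                    byrow = TRUE)
      if (is_case) lam <- sweep(lam, 2, rr, `*`)
      counts <- matrix(stats::rpois(ns * config$n_genes, lam),
                       nrow = ns)
      idx <- which(counts > 0, arr.ind = TRUE)
      if (nrow(idx) == 0) return(NULL)
      n_obs <- counts[idx]
      samp <- rep(sample_ids[idx[, 1]], n_obs)
      gidx <- rep(idx[, 2], n_obs)
      n <- length(samp)

      truncating <- stats::runif(n) < config$fraction_truncating
      csq <- ifelse(
        truncating,
        sample(c("nonsense", "frameshift", "canonical_splice"), n,
               replace = TRUE),
        "missense"
      )
      conserved <- stats::runif(n) < config$p_conserved
      phylop <- ifelse(conserved, stats::runif(n, 3, 7),
                       stats::runif(n, 0, 3 - 1e-9))
      common <- stats::runif(n) < config$fraction_common
      qfail <- stats::runif(n) < config$fraction_quality_fail
      hom <- stats::runif(n) < config$fraction_homozygous

      frac <- ifelse(hom, stats::runif(n, 0.95, 1.0),
                     stats::runif(n, 0.35, 0.65))
      total <- 20L + as.integer(floor(stats::runif(n, 0, 81)))
      vr <- pmin(total, pmax(5L, as.integer(round(frac * total))))
      us <- 5L + as.integer(floor(stats::runif(n, 0, 16)))
      # force a single violated quality rule per failing record
      rule <- sample(1:4, n, replace = TRUE)
      bad_depth <- qfail & rule == 1
      total[bad_depth] <- 9L
      vr[bad_depth] <- pmin(vr[bad_depth], 9L)
      bad_vr <- qfail & rule == 2
      vr[bad_vr] <- 4L
      bad_us <- qfail & rule == 3
      us[bad_us] <- 4L
      bad_frac <- qfail & rule == 4
      total[bad_frac] <- 50L
      vr[bad_frac] <- 10L  # 20% variant reads, still >= 5 reads

      is_fs <- csq == "frameshift"
      ref <- ifelse(is_fs, "AT", "A")
      alt <- rep("G", n)
      us[is_fs] <- NA_integer_
      # a frameshift can't fail the unique-starts rule; re-route to depth
      refail <- is_fs & bad_us
      total[refail] <- 9L
      vr[refail] <- pmin(vr[refail], 9L)

      pos <- gene_base[gidx] + as.integer(floor(stats::runif(n, 0, 9e5)))

      out <- tibble::tibble(
        sample_id = samp,
        chrom = gene_chrom[gidx],
        pos = pos,
        ref = ref,
        alt = alt,
        total_reads = total,
        variant_reads = vr,
        unique_starts = us,
        gene = genes[gidx],
        transcript = paste0("NM_", sprintf("%06d", gidx)),
        cdna = paste0("c.", pos %% 3000L + 1L,
                      ifelse(is_fs, "del", "A>G")),
        prot = "p.?",
        csq = csq,
        phylop = round(phylop, 3),
        sift = NA_character_,
        pph2 = NA_character_,
        agvgd = NA_character_,
        dbsnp = NA_character_
      )
      for (p in names(config$panels)) {
        np <- config$panels[[p]]
        cap_rare <- floor(0.001 * 2 * np)
        ac_rare <- as.integer(floor(stats::runif(n, 0, cap_rare + 1)))
        ac_common <- as.integer(
          ceiling(stats::runif(n, 0.002, 0.01) * 2 * np))
        out[[paste0("ac_", p)]] <- ifelse(common, ac_common, ac_rare)
        out[[paste0("n_", p)]] <- np
      }
      truth <- tibble::tibble(
        sample_id = samp, gene = genes[gidx], pos = pos,
        true_quality_pass = !qfail,
        true_rare = !common,
        true_impact = ifelse(csq != "missense", "truncating",
                             ifelse(conserved, "conserved_missense",
                                    "excluded")),
        true_hom = hom
      )
      truth$true_pass <- truth$true_quality_pass & truth$true_rare &
        truth$true_impact != "excluded"
      list(records = out, truth = truth)
    }

    case <- emit(case_ids, is_case = TRUE)
    ctrl <- emit(ctrl_ids, is_case = FALSE)
    empty_records <- function() {
      cols <- c(variant_columns(),
                as.vector(rbind(paste0("ac_", names(config$panels)),
                                paste0("n_", names(config$panels)))))
      tpl <- tibble::as_tibble(
        setNames(rep(list(character(0)), length(cols)), cols))
      for (cc in c("pos", "total_reads", "variant_reads", "unique_starts"))
        tpl[[cc]] <- integer(0)
      for (cc in c("phylop", grep("^(ac|n)_", cols, value = TRUE)))
        tpl[[cc]] <- numeric(0)
      tpl
    }
    case_rec <- if (is.null(case)) empty_records() else case$records
    ctrl_rec <- if (is.null(ctrl)) empty_records() else ctrl$records

    list(
      case = validate_variant_table(case_rec, "simulated case cohort"),
      control = validate_variant_table(ctrl_rec,
                                       "simulated control cohort"),
      case_manifest = case_manifest,
      control_manifest = control_manifest,
      truth = list(
        genes = tibble::tibble(
          gene = genes,
          spiked = genes %in% names(config$spiked_genes),
          relative_risk = unname(rr)
        ),
        variants = dplyr::bind_rows(
          if (!is.null(case)) dplyr::mutate(case$truth, cohort = "case"),
          if (!is.null(ctrl)) dplyr::mutate(ctrl$truth, cohort = "control")
        )
      ),
      config = config
    )
  })
}

#' Type-I error and power of the burden screen by simulation
#'
#' Runs the simulate - filter - recurrence - burden pipeline `n_reps`
#' times and reports the empirical rejection rate at level `alpha`,
#' conditioned on genes that reach the test (i.e. genes recurrent in the
#' case cohort), separately for non-spiked (type-I) and spiked (power)
#' genes. Because reaching the test already requires case-cohort
#' recurrence, the conditional type-I rate is selection-biased upward
#' relative to `alpha`; it is reported with its Monte-Carlo standard
#' error and flagged, not assumed, to be near `alpha`. Replicate seeds
#' are derived from `config$seed`, so two calls differing only in
#' relative risk share common random numbers.
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicates (>= 100 recommended for usable
#'   error bars).
#' @param alpha Test level (default 0.05).
#' @return A list: `type1_rate`, `type1_se`, `type1_n_tests`,
#'   `type1_exceeds_alpha_3se` (flag), `power`, `power_se`,
#'   `power_n_tests`, `n_reps`, `alpha`.
#' @export
estimate_calibration <- function(config, n_reps, alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"), n_reps >= 1)
  lof_placeholder <- "ZZZ_NOT_A_GENE"
  fcfg <- filter_config(frequency_panels = names(config$panels))
  null_p <- list()
  spike_p <- list()
  for (rep_i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * rep_i) %% .Machine$integer.max
    sim <- simulate_cohort(cfg)
    case_f <- filter_cohort(sim$case, fcfg, lof_placeholder)
    ctrl_f <- filter_cohort(sim$control, fcfg, lof_placeholder)
    rec <- find_recurrent_genes(case_f$retained, sim$case_manifest)
    if (nrow(rec) == 0) next
    scr <- burden_screen(rec, sim$case_manifest, ctrl_f$retained,
                         sim$control_manifest, alpha = alpha)
    spiked <- scr$results$gene %in%
      sim$truth$genes$gene[sim$truth$genes$spiked]
    null_p[[rep_i]] <- scr$results$p_value[!spiked]
    spike_p[[rep_i]] <- scr$results$p_value[spiked]
  }
  rate <- function(ps) {
    ps <- unlist(ps)
    n <- length(ps)
    if (n == 0) return(list(rate = NA_real_, se = NA_real_, n = 0L))
    r <- mean(ps <= alpha)
    list(rate = r, se = sqrt(r * (1 - r) / n), n = n)
  }
  t1 <- rate(null_p)
  pw <- rate(spike_p)
  list(
    type1_rate = t1$rate, type1_se = t1$se, type1_n_tests = t1$n,
    type1_exceeds_alpha_3se = !is.na(t1$rate) &&
      t1$rate > alpha + 3 * max(t1$se, .Machine$double.eps),
    power = pw$rate, power_se = pw$se, power_n_tests = pw$n,
    n_reps = n_reps, alpha = alpha
  )
}
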