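# Orchestration: run the full trio analysis from a single configuration
# and assemble per-trio report tables plus a machine-readable manifest.

#' Default pipeline thresholds
#'
#' Every filter threshold used by the pipeline, with the package defaults:
#' depth 10-120, allele balance 0.3-0.7, genotype quality >= 50, 50%
#' reciprocal overlap, pre-phasing missing rate 10% and Mendelian-error
#' trio count 2, 1 Mb hotspot windows at the top 1% with 1 Mb
#' telomere/centromere flanks, 100 bp CNV size floor.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(dp_min = 10, dp_max = 120, ab_min = 0.3, ab_max = 0.7, gq_min = 50,
       min_recip = 0.5, cnv_min_size = 100,
       max_missing = 0.10, min_mendel_trios = 2,
       hotspot_window = 1e6, hotspot_top_frac = 0.01, hotspot_flank = 1e6)
}

#' Load a pipeline run configuration
#'
#' A YAML file (or equivalent list) with `seed`, `out_dir`, an `inputs`
#' block of file paths (`vcf`, `ped`, `masks:` named BED files,
#' `cnv_caller_a`, `cnv_caller_b`, `cnv_database`, `known_variants`,
#' `ni_table`, `chrom_sizes`, `depth_profiles`) and an optional flat
#' `thresholds` block overriding [default_thresholds()].  Any referenced
#' path must exist; sections whose inputs are absent from the config are
#' skipped.
#'
#' @param x path to a YAML file, or a list.
#' @return normalised config list of class `run_config`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  cfg$thresholds <- utils::modifyList(default_thresholds(),
                                      cfg$thresholds %||% list())
  cfg$seed <- cfg$seed %||% 1L
  cfg$out_dir <- cfg$out_dir %||% "triokit_out"
  paths <- unlist(cfg$inputs, use.names = TRUE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(names(missing), "=", missing, collapse = ", "))
  class(cfg) <- c("run_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full trio analysis pipeline
#'
#' Executes, in order and as inputs allow: de novo SNV/indel detection and
#' rate estimation, CNV ensemble merging / novelty / de novo detection /
#' sharing classification, per-sample summary statistics and hotspot
#' scanning, and trio phasing.  Writes per-trio TSV reports (mutation
#' counts and rates per trio; deletion/duplication tallies; inherited
#' novel-insertion categories; per-sample variant summaries), a phased
#' VCF, and a manifest recording the package version, seed and every
#' threshold in force.
#'
#' @param config a `run_config`, list, or YAML path.
#' @return (invisibly) list of result objects; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  th <- cfg$thresholds
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  crit <- denovo_criteria(th$dp_min, th$dp_max, th$ab_min, th$ab_max,
                          th$gq_min)
  res <- list(thresholds = th)
  outputs <- character()
  emit <- function(d, name) {
    outputs[[name]] <<- .write_tsv(d, file.path(cfg$out_dir, name))
  }

  ped <- read_ped(cfg$inputs$ped)
  res$ped <- ped
  masks <- lapply(cfg$inputs$masks, read_bed)

  calls <- NULL
  if (!is.null(cfg$inputs$vcf)) {
    calls <- read_trio_vcf(cfg$inputs$vcf)

    # --- de novo SNVs/indels and rates -------------------------------
    excl <- masks[setdiff(names(masks),
                          c("repeats", "gapseg", "telo_centro"))]
    dn <- denovo_small_analysis(calls, ped, crit, excl)
    res$denovo <- dn
    emit(dn$calls[, c("trio_id", "chrom", "pos", "ref", "alt", "vtype",
                      "child_gt", "child_ab")], "dnm_calls.tsv")

    # --- per-sample summaries ----------------------------------------
    summ <- do.call(rbind, lapply(seq_along(calls$samples), function(j) {
      g <- calls$gt[, j]
      snv <- calls$sites$vtype == "snv"
      data.frame(sample = calls$samples[j],
                 n_snv = sum(snv & !is.na(g) & g > 0),
                 n_indel = sum(!snv & !is.na(g) & g > 0),
                 titv = titv_ratio(calls$sites[snv & !is.na(g) & g > 0, ]),
                 het_prop_snv = heterozygosity_proportion(
                   sum(snv & !is.na(g) & g == 1L),
                   sum(snv & !is.na(g) & g == 2L)),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(cfg$inputs$known_variants)) {
      known <- read.delim(cfg$inputs$known_variants, stringsAsFactors = FALSE)
      summ$novelty <- vapply(seq_along(calls$samples), function(j) {
        carried <- !is.na(calls$gt[, j]) & calls$gt[, j] > 0
        novelty_rate(calls$sites[carried, , drop = FALSE], known)
      }, 0)
    }
    res$sample_summary <- summ
    emit(summ, "sample_summary.tsv")

    # --- hotspot scan ------------------------------------------------
    if (!is.null(cfg$inputs$chrom_sizes)) {
      sizes <- read_chrom_sizes(cfg$inputs$chrom_sizes)
      tc <- masks[["telo_centro"]]
      pooled <- do.call(rbind, lapply(seq_along(calls$samples), function(j) {
        sel <- !is.na(calls$gt[, j]) & calls$gt[, j] > 0
        data.frame(calls$sites[sel, c("chrom", "pos", "vtype")],
                   gq = calls$gq[sel, j], dp = calls$dp[sel, j],
                   ad_ref = calls$ad_ref[sel, j],
                   ad_alt = calls$ad_alt[sel, j])
      }))
      for (vt in c("snv", "indel")) {
        hs <- hotspot_scan(pooled[pooled$vtype == vt, , drop = FALSE],
                           sizes, tc, crit, window = th$hotspot_window,
                           top_frac = th$hotspot_top_frac,
                           flank = th$hotspot_flank)
        res[[paste0("hotspots_", vt)]] <- hs
        emit(hs, paste0("hotspots_", vt, ".tsv"))
      }
    }

    # --- phasing -----------------------------------------------------
    pf <- prephase_filter(calls, ped, th$max_missing, th$min_mendel_trios)
    phased <- phase_all_trios(pf$calls, ped)
    res$phasing <- list(prefilter = pf, phased = phased)
    emit(phased$report, "phasing_report.tsv")
    write_trio_vcf(pf$calls, file.path(cfg$out_dir, "phased.vcf"),
                   ped = ped, phase = phased$phase)
    outputs[["phased.vcf"]] <- file.path(cfg$out_dir, "phased.vcf")
  }

  # --- CNV pipeline --------------------------------------------------
  if (!is.null(cfg$inputs$cnv_caller_a) && !is.null(cfg$inputs$cnv_caller_b)) {
    ca <- cnv_calls(cfg$inputs$cnv_caller_a, th$cnv_min_size)
    cb <- cnv_calls(cfg$inputs$cnv_caller_b, th$cnv_min_size)
    samples <- unique(c(ca$sample, cb$sample))
    merged <- do.call(rbind, lapply(samples, function(s)
      merge_callsets(ca[ca$sample == s, , drop = FALSE],
                     cb[cb$sample == s, , drop = FALSE],
                     repeat_mask = masks[["repeats"]],
                     gapseg_mask = masks[["gapseg"]],
                     min_recip = th$min_recip)))
    res$cnv_merged <- merged
    emit(merged, "cnv_merged.tsv")
    emit(cnv_type_summary(merged), "cnv_summary.tsv")

    if (!is.null(cfg$inputs$cnv_database)) {
      db <- read.delim(cfg$inputs$cnv_database, stringsAsFactors = FALSE)
      merged$novel <- is_novel_cnv(merged, db, th$min_recip)
      res$cnv_merged <- merged
    }

    prof <- if (!is.null(cfg$inputs$depth_profiles))
      read.delim(cfg$inputs$depth_profiles, stringsAsFactors = FALSE)
    dn_cnv <- list()
    for (i in seq_len(nrow(ped))) {
      pick <- function(id) merged[merged$sample == id, , drop = FALSE]
      dd <- detect_denovo_cnv(pick(ped$offspring_id[i]),
                              pick(ped$father_id[i]),
                              pick(ped$mother_id[i]),
                              depth_profiles = prof,
                              min_recip = th$min_recip,
                              father_id = ped$father_id[i],
                              mother_id = ped$mother_id[i])
      dd$calls$trio_id <- if (nrow(dd$calls)) ped$trio_id[i] else character(0)
      dn_cnv[[ped$trio_id[i]]] <- dd
    }
    res$cnv_denovo <- dn_cnv
    all_dn <- do.call(rbind, c(lapply(dn_cnv, `[[`, "calls"),
                               make.row.names = FALSE))
    emit(all_dn, "cnv_denovo.tsv")

    reg <- cnv_region_presence(merged, ped, th$min_recip)
    share <- data.frame(reg$regions,
                        sharing = classify_sharing(reg$presence, ped))
    res$cnv_sharing <- share
    emit(share, "cnv_sharing.tsv")
  }

  # --- per-trio rate report (mutation counts and rates) --------------
  if (!is.null(res$denovo)) {
    r <- res$denovo$rates
    grab <- function(tid, vt, col) {
      v <- r[r$trio_id == tid & r$vtype == vt, col]
      if (length(v)) v else NA
    }
    rate_tab <- do.call(rbind, lapply(seq_len(nrow(ped)), function(i) {
      tid <- ped$trio_id[i]
      row <- data.frame(trio_id = tid, population = ped$population[i],
                        n_dnm_snv = grab(tid, "snv", "n_dnm"),
                        mu_snv = grab(tid, "snv", "mu"),
                        n_dnm_indel = grab(tid, "indel", "n_dnm"),
                        mu_indel = grab(tid, "indel", "mu"),
                        stringsAsFactors = FALSE)
      if (!is.null(res$cnv_denovo)) {
        n_total <- sum(res$cnv_merged$sample == ped$offspring_id[i])
        n_dn <- nrow(res$cnv_denovo[[tid]]$calls)
        cr <- if (n_total > 0) estimate_cnv_rate(n_dn, n_total) else
          data.frame(n_denovo = n_dn, n_total = 0, rate = NA,
                     rate_reported = NA)
        row$n_cnv_denovo <- cr$n_denovo
        row$n_cnv_total <- cr$n_total
        row$cnv_rate <- cr$rate_reported
      }
      row
    }))
    res$trio_rates <- rate_tab
    emit(rate_tab, "trio_rates.tsv")
  }

  # --- novel insertions ----------------------------------------------
  if (!is.null(cfg$inputs$ni_table)) {
    ni <- read_ni_table(cfg$inputs$ni_table)
    res$ni_summary <- ni_summary(ni, ped)
    emit(res$ni_summary, "ni_summary.tsv")
  }

  manifest <- list(package = "triokit",
                   version = as.character(packageVersion("triokit")),
                   seed = cfg$seed,
                   thresholds = th,
                   inputs = cfg$inputs,
                   outputs = as.list(outputs))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
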