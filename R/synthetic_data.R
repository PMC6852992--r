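# Synthetic trio-genome generator with known ground truth.
#
# Emulates what the detection filters assume about real trio sequencing
# data: Hardy-Weinberg parental genotypes, Mendelian transmission, planted
# germline de novo events at configurable rates, Poisson read depth around
# a 30x mean, binomial allele-balance noise, a depth-driven genotype-quality
# surrogate, and two noisy pseudo-caller CNV call sets with breakpoint
# jitter and dropout.  Every planted event is recorded in a truth table.

#' Simulation configuration
#'
#' Defaults describe a 30x short-read trio study: mean depth 30, allele
#' frequencies uniform on \[0.05, 0.95\], de novo rates in the range
#' reported for human germline SNVs (~1.2e-8) and indels (~2e-9) per site
#' per generation, ~600 CNVs per sample of which a fraction ~1e-3 arise de
#' novo, a small parental stray-read rate, and a genotype-quality model
#' GQ = min(99, round(3.3 x depth)) degraded to 20 below depth 8.
#'
#' @param n_trios number of trios.
#' @param n_sites biallelic SNV sites per genome.
#' @param n_sites_indel biallelic indel sites per genome.
#' @param chrom name of the single simulated pseudo-autosome.
#' @param chrom_length its length (bp).
#' @param af_min,af_max population allele-frequency range (uniform).
#' @param dnm_rate_snv,dnm_rate_indel de novo rate per site per generation
#'   (per transmitted haploid genome).
#' @param depth_mean mean sequencing depth.
#' @param error_rate parental stray-read rate (per read).
#' @param gq_slope,gq_cap,gq_low,gq_low_dp genotype-quality model.
#' @param n_cnv_loci size of the population CNV locus pool.
#' @param cnv_freq_mean mean population frequency of a CNV locus.
#' @param n_cnv_denovo expected de novo CNVs planted per offspring.
#' @param cnv_del_frac fraction of CNV loci that are deletions.
#' @param cnv_len_meanlog,cnv_len_sdlog log-normal CNV length model.
#' @param cnv_jitter per-caller breakpoint jitter as a fraction of CNV
#'   length.
#' @param cnv_dropout per-caller probability of missing a true CNV.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 5, n_sites = 1e6, n_sites_indel = 2e5,
                       chrom = "sim1", chrom_length = 2.5e8,
                       af_min = 0.05, af_max = 0.95,
                       dnm_rate_snv = 1.2e-8, dnm_rate_indel = 2e-9,
                       depth_mean = 30, error_rate = 1e-3,
                       gq_slope = 3.3, gq_cap = 99L, gq_low = 20L,
                       gq_low_dp = 8L,
                       n_cnv_loci = 1200, cnv_freq_mean = 0.3,
                       n_cnv_denovo = 2, cnv_del_frac = 0.8,
                       cnv_len_meanlog = log(800), cnv_len_sdlog = 0.8,
                       cnv_jitter = 0.1, cnv_dropout = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_sites > 0, cfg$dnm_rate_snv >= 0, cfg$dnm_rate_snv <= 1,
            cfg$dnm_rate_indel >= 0, cfg$dnm_rate_indel <= 1,
            cfg$af_min < cfg$af_max, cfg$chrom_length >= cfg$n_sites,
            cfg$cnv_dropout >= 0, cfg$cnv_dropout <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate site-level trio data in memory
#'
#' One trio's worth of biallelic sites: true genotypes, transmitted
#' alleles, planted de novo flags, per-member depth, alternative-read
#' count and genotype quality.  Positions and alleles are attached when
#' `positions = TRUE`; the bare table is enough for rate-recovery work at
#' large site counts.  Randomness comes from R's RNG: call `set.seed()`
#' first for reproducibility.
#'
#' @param cfg `sim_config`.
#' @param vtype `"snv"` or `"indel"` (selects the de novo rate and, with
#'   positions, the allele style).
#' @param n_sites override the configured site count.
#' @param af optional fixed allele-frequency vector (length `n_sites`),
#'   for shared sites across trios.
#' @param positions attach sorted positions and ref/alt alleles.
#' @return data.frame, one row per site.
#' @export
simulate_trio_sites <- function(cfg = sim_config(), vtype = c("snv", "indel"),
                                n_sites = NULL, af = NULL,
                                positions = TRUE) {
  vtype <- match.arg(vtype)
  n <- as.integer(if (is.null(n_sites)) {
    if (vtype == "snv") cfg$n_sites else cfg$n_sites_indel
  } else n_sites)
  rate <- if (vtype == "snv") cfg$dnm_rate_snv else cfg$dnm_rate_indel
  sim <- sim_trio_sites_cpp(n, cfg$af_min, cfg$af_max, rate,
                            cfg$depth_mean, cfg$error_rate,
                            cfg$gq_slope, as.integer(cfg$gq_cap),
                            as.integer(cfg$gq_low), as.integer(cfg$gq_low_dp),
                            if (is.null(af)) numeric(0) else af)
  out <- as.data.frame(sim)
  if (positions) {
    pos <- sort(sample.int(cfg$chrom_length, n))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- if (vtype == "snv") {
      vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    } else {
      # 1-5 bp insertions relative to a single-base ref
      ins <- vapply(sample(1:5, n, replace = TRUE), function(k)
        paste(sample(bases, k, replace = TRUE), collapse = ""), "")
      paste0(ref, ins)
    }
    out <- cbind(data.frame(chrom = cfg$chrom, pos = pos, ref = ref,
                            alt = alt, vtype = vtype,
                            stringsAsFactors = FALSE), out)
  } else {
    out$vtype <- vtype
  }
  out
}

# assemble per-sample matrices for trio i from per-trio site tables
.sim_matrices <- function(tabs, ped) {
  samples <- c(rbind(ped$father_id, ped$mother_id, ped$offspring_id))
  mk <- function(field) {
    m <- do.call(cbind, lapply(seq_along(tabs), function(i)
      cbind(tabs[[i]][[paste0("father_", field)]],
            tabs[[i]][[paste0("mother_", field)]],
            tabs[[i]][[paste0("child_", field)]])))
    colnames(m) <- samples
    m
  }
  gt <- mk("gt"); ad_alt <- mk("ad_alt"); dp <- mk("dp"); gq <- mk("gq")
  list(gt = gt, ad_alt = ad_alt, dp = dp, gq = gq,
       ad_ref = dp - ad_alt, samples = samples)
}

#' Simulate a multi-trio call set with truth tables
#'
#' Draws a shared set of segregating sites (SNVs and indels), simulates
#' each trio independently at those sites, and assembles a `trio_calls`
#' object plus a pedigree and a truth table of planted de novo events and
#' transmitted haplotypes.  Optionally writes VCF, PED and truth TSV to
#' `dir`.
#'
#' @param cfg `sim_config`.
#' @param dir output directory, or NULL for in-memory only.
#' @return list: `calls` (`trio_calls`), `ped` (`trio_ped`), `truth`
#'   (data.frame of planted de novo events), `haplotypes` (per-trio list
#'   of transmitted-allele data.frames), and `files` when written.
#' @export
simulate_trio_cohort <- function(cfg = sim_config(), dir = NULL) {
  pops <- malaysian_populations()$population
  n_tr <- cfg$n_trios
  pop <- if (n_tr <= length(pops)) pops[seq_len(n_tr)] else
    sprintf("POP%02d", seq_len(n_tr))
  popmap <- if (n_tr <= length(pops)) malaysian_populations() else
    data.frame(population = pop, group = rep(c("OA", "NB"), length.out = n_tr))
  ped <- trio_pedigree(trio_id = pop,
                       father_id = paste0(pop, "_F"),
                       mother_id = paste0(pop, "_M"),
                       offspring_id = paste0(pop, "_C"),
                       population = pop, populations = popmap)

  sim_block <- function(vtype, n) {
    af <- runif(n, cfg$af_min, cfg$af_max)
    first <- simulate_trio_sites(cfg, vtype, n_sites = n, af = af,
                                 positions = TRUE)
    tabs <- c(list(first[, -(1:5)]),
              lapply(seq_len(n_tr - 1L), function(i) {
                t <- simulate_trio_sites(cfg, vtype, n_sites = n, af = af,
                                         positions = FALSE)
                t$vtype <- NULL
                t
              }))
    list(sites = first[, 1:5], tabs = tabs)
  }
  snv <- sim_block("snv", cfg$n_sites)
  ind <- sim_block("indel", cfg$n_sites_indel)
  sites <- rbind(snv$sites, ind$sites)
  tabs <- lapply(seq_len(n_tr), function(i) rbind(snv$tabs[[i]], ind$tabs[[i]]))

  mats <- .sim_matrices(tabs, ped)
  calls <- trio_calls(sites, mats$gt, mats$ad_ref, mats$ad_alt,
                      mats$dp, mats$gq)

  truth <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
    t <- tabs[[i]]
    hit <- which(t$dnm_paternal | t$dnm_maternal)
    if (length(hit) == 0L) return(NULL)
    data.frame(trio_id = ped$trio_id[i], sites[hit, c("chrom", "pos", "vtype")],
               parent = ifelse(t$dnm_paternal[hit], "father", "mother"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(trio_id = character(), chrom = character(),
                        pos = integer(), vtype = character(),
                        parent = character(), stringsAsFactors = FALSE)
  haplotypes <- setNames(lapply(tabs, function(t)
    data.frame(paternal = t$paternal_allele, maternal = t$maternal_allele)),
    ped$trio_id)

  out <- list(calls = calls, ped = ped, truth = truth, haplotypes = haplotypes)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(dir, "trios.vcf")
    pedf <- file.path(dir, "trios.ped")
    truthf <- file.path(dir, "dnm_truth.tsv")
    write_trio_vcf(calls, vcf)
    ped_rows <- do.call(rbind, lapply(seq_len(n_tr), function(i) rbind(
      c(ped$trio_id[i], ped$father_id[i], "0", "0", "1", "-9"),
      c(ped$trio_id[i], ped$mother_id[i], "0", "0", "2", "-9"),
      c(ped$trio_id[i], ped$offspring_id[i], ped$father_id[i],
        ped$mother_id[i], "1", "-9"))))
    write.table(ped_rows, pedf, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(truth, truthf, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- c(vcf = vcf, ped = pedf, truth = truthf)
  }
  out
}

# draw CNV intervals avoiding overlap within a sample is not enforced;
# loci are spaced on a grid so same-locus calls coincide across samples
.cnv_locus_pool <- function(cfg) {
  len <- pmax(150, round(rlnorm(cfg$n_cnv_loci, cfg$cnv_len_meanlog,
                                cfg$cnv_len_sdlog)))
  gap <- max(len) * 4
  start <- round(seq(1e5, cfg$chrom_length - gap, length.out = cfg$n_cnv_loci))
  data.frame(locus = seq_len(cfg$n_cnv_loci), chrom = cfg$chrom,
             start = start, end = start + len,
             svtype = ifelse(runif(cfg$n_cnv_loci) < cfg$cnv_del_frac,
                             "DEL", "DUP"),
             freq = pmin(0.9, pmax(0.02, rlnorm(cfg$n_cnv_loci,
                                                log(cfg$cnv_freq_mean), 0.6))),
             stringsAsFactors = FALSE)
}

#' Simulate per-caller CNV call sets with truth and depth profiles
#'
#' Plants inherited CNVs from a shared population locus pool (parents carry
#' a locus with its population frequency; carriers are heterozygous and
#' transmit with probability 1/2) and de novo deletion CNVs in each
#' offspring at loci private to that offspring.  Emits two pseudo-caller
#' call sets per sample, subject to per-caller breakpoint jitter
#' (uniform within +/- `cnv_jitter` of the CNV length, per breakpoint) and
#' dropout, together with windowed depth profiles around every offspring
#' CNV so that depth-based parental re-genotyping is exercisable.
#'
#' @param cfg `sim_config`.
#' @param ped `trio_ped` (defaults to the cohort layout of
#'   [simulate_trio_cohort()]).
#' @param jitter,dropout override the configured caller noise; a length-2
#'   vector sets caller A and caller B separately.
#' @return list: `caller_a`, `caller_b` (call data.frames), `truth`
#'   (planted CNVs per sample with an `origin` column), `depth_profiles`,
#'   `mean_depths`.
#' @export
simulate_cnv_callsets <- function(cfg = sim_config(), ped = NULL,
                                  jitter = cfg$cnv_jitter,
                                  dropout = cfg$cnv_dropout) {
  jitter <- rep(jitter, length.out = 2)
  dropout <- rep(dropout, length.out = 2)
  if (is.null(ped)) {
    pops <- malaysian_populations()$population[seq_len(cfg$n_trios)]
    ped <- trio_pedigree(pops, paste0(pops, "_F"), paste0(pops, "_M"),
                         paste0(pops, "_C"), pops)
  }
  pool <- .cnv_locus_pool(cfg)
  truth <- list()
  for (i in seq_len(nrow(ped))) {
    fa <- runif(nrow(pool)) < pool$freq
    mo <- runif(nrow(pool)) < pool$freq
    ch_fa <- fa & runif(nrow(pool)) < 0.5
    ch_mo <- mo & runif(nrow(pool)) < 0.5
    ch <- ch_fa | ch_mo
    add <- function(sample, carry, origin) {
      if (!any(carry)) return(NULL)
      data.frame(sample = sample, pool[carry, c("chrom", "start", "end",
                                                "svtype"), drop = FALSE],
                 copy_number = ifelse(pool$svtype[carry] == "DEL", 1L, 3L),
                 origin = origin, stringsAsFactors = FALSE)
    }
    n_dn <- rpois(1, cfg$n_cnv_denovo)
    dn <- NULL
    if (n_dn > 0) {
      # de novo deletions at fresh loci between pool loci
      len <- pmax(200, round(rlnorm(n_dn, log(1000), 0.5)))
      anchor <- sample(nrow(pool) - 1L, n_dn)
      start <- round((pool$end[anchor] + pool$start[anchor + 1L]) / 2)
      dn <- data.frame(sample = ped$offspring_id[i], chrom = cfg$chrom,
                       start = start, end = start + len, svtype = "DEL",
                       copy_number = 1L, origin = "denovo",
                       stringsAsFactors = FALSE)
    }
    truth[[i]] <- rbind(add(ped$father_id[i], fa, "inherited"),
                        add(ped$mother_id[i], mo, "inherited"),
                        add(ped$offspring_id[i], ch, "inherited"), dn)
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))

  emit_caller <- function(label, jit, drp) {
    keep <- runif(nrow(truth)) >= drp
    calls <- truth[keep, , drop = FALSE]
    if (jit > 0 && nrow(calls)) {
      len <- calls$end - calls$start
      calls$start <- pmax(0, round(calls$start + runif(nrow(calls), -jit, jit) * len))
      calls$end <- round(calls$end + runif(nrow(calls), -jit, jit) * len)
      calls$end <- pmax(calls$end, calls$start + 101)
    }
    calls$origin <- NULL
    calls$caller <- rep(label, nrow(calls))
    rownames(calls) <- NULL
    calls
  }
  caller_a <- emit_caller("caller_A", jitter[1], dropout[1])
  caller_b <- emit_caller("caller_B", jitter[2], dropout[2])

  # windowed depth around every offspring interval, for all trio members:
  # CN 2 -> depth_mean, CN 1 -> half, CN 3 -> 1.5x
  prof <- list()
  for (i in seq_len(nrow(ped))) {
    members <- c(ped$father_id[i], ped$mother_id[i], ped$offspring_id[i])
    regions <- truth[truth$sample == ped$offspring_id[i], , drop = FALSE]
    for (s in members) {
      own <- truth[truth$sample == s, , drop = FALSE]
      rows <- lapply(seq_len(nrow(regions)), function(r) {
        edges <- unique(round(seq(regions$start[r], regions$end[r],
                                  length.out = 5)))
        w <- data.frame(sample = s, chrom = regions$chrom[r],
                        start = edges[-length(edges)], end = edges[-1],
                        stringsAsFactors = FALSE)
        mid <- (w$start + w$end) / 2
        cn <- rep(2, nrow(w))
        for (k in seq_len(nrow(own))) {
          inside <- mid >= own$start[k] & mid < own$end[k]
          cn[inside] <- own$copy_number[k]
        }
        w$depth <- cfg$depth_mean * cn / 2
        w
      })
      prof[[paste(s, i)]] <- do.call(rbind, rows)
    }
  }
  depth_profiles <- do.call(rbind, c(prof, make.row.names = FALSE))
  samples <- c(rbind(ped$father_id, ped$mother_id, ped$offspring_id))
  mean_depths <- setNames(rep(cfg$depth_mean, length(samples)), samples)
  list(caller_a = caller_a, caller_b = caller_b, truth = truth,
       depth_profiles = depth_profiles, mean_depths = mean_depths)
}
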