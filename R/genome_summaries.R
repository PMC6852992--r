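# Per-sample and per-population summary statistics: heterozygosity
# proportion, Ti/Tv, novelty rates, variant-density hotspots, and
# novel-insertion inheritance / archaic-hominin classification.

#' Heterozygosity proportion
#'
#' Heterozygous calls divided by heterozygous plus homozygous-alternative
#' calls; a standard per-genome homogeneity summary.
#'
#' @param n_het,n_homalt counts (vectorised).
#' @return numeric fractions.
#' @export
heterozygosity_proportion <- function(n_het, n_homalt) {
  stopifnot(all(n_het >= 0), all(n_homalt >= 0))
  if (any(n_het + n_homalt == 0))
    stop("heterozygosity proportion undefined: no non-reference calls")
  n_het / (n_het + n_homalt)
}

#' Transition/transversion ratio of a set of SNVs
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine
#' substitutions (A<->G, C<->T); everything else is a transversion.
#' Whole-genome human call sets sit near 2.1.
#'
#' @param ref,alt single-base allele vectors, or a data.frame with `ref`
#'   and `alt` columns as the first argument.
#' @return the Ti/Tv ratio (scalar).
#' @export
titv_ratio <- function(ref, alt = NULL) {
  if (is.data.frame(ref)) { alt <- ref$alt; ref <- ref$ref }
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  if (!all(snv)) {
    message("ignoring ", sum(!snv), " non-SNV record(s)")
    ref <- ref[snv]; alt <- alt[snv]
  }
  pair <- paste0(toupper(ref), toupper(alt))
  ti <- pair %in% c("AG", "GA", "CT", "TC")
  if (sum(!ti) == 0L) stop("Ti/Tv undefined: no transversions")
  sum(ti) / sum(!ti)
}

#' Fraction of variants absent from a known-variant set
#'
#' Novelty is exact identity on (chrom, pos, ref, alt); no position-fuzzy
#' matching.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param known data.frame with the same columns (e.g. a dbSNP extract).
#' @return fraction of `variants` rows not present in `known`.
#' @export
novelty_rate <- function(variants, known) {
  if (nrow(variants) == 0L) stop("no variants supplied")
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  mean(!(key(variants) %in% key(known)))
}

#' Read a chromosome-sizes table (two-column TSV: chrom, length)
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(d[[2]]), d[[1]])
}

#' Scan the genome for variant-density hotspot windows
#'
#' Tiles each chromosome with non-overlapping windows from position 0 (the
#' final partial window is kept when at least half a window long), drops
#' windows overlapping the telomere/centromere intervals extended by
#' `flank` on each side, counts the variants passing quality control
#' (genotype quality, depth and allele-balance thresholds from `qc`), and
#' returns the top `ceiling(top_frac x eligible windows)` windows by count,
#' extended through ties at the cutoff count so the result does not depend
#' on input order.  SNVs and indels should be scanned in separate calls.
#'
#' @param variants data.frame with `chrom`, `pos` and, when QC is to be
#'   applied, `gq`, `dp`, `ad_ref`, `ad_alt` columns (one row per variant
#'   per sample when pooling across samples).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param telo_centro `genome_mask` of telomere/centromere intervals, or
#'   NULL.
#' @param qc `denovo_criteria`-style thresholds, or NULL to skip QC.
#' @param window window size in bp.
#' @param top_frac fraction of eligible windows to report.
#' @param flank exclusion flank around telomeres/centromeres, bp.
#' @return data.frame of hotspot windows: `chrom`, `start`, `end`
#'   (0-based half-open), `n_pass`, sorted by decreasing count.
#' @export
hotspot_scan <- function(variants, chrom_sizes, telo_centro = NULL,
                         qc = denovo_criteria(), window = 1e6,
                         top_frac = 0.01, flank = 1e6) {
  wins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    keep <- (ends - starts) >= window / 2
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(telo_centro) && nrow(telo_centro)) {
    flanked <- genome_mask(telo_centro$chrom,
                           pmax(0, telo_centro$start - flank),
                           telo_centro$end + flank,
                           name = "telo_centro_flanked")
    wins <- wins[mask_overlap_fraction(wins, flanked) == 0, , drop = FALSE]
  }
  if (nrow(wins) == 0L) stop("no eligible windows")

  v <- variants
  if (!is.null(qc)) {
    tot <- v$ad_ref + v$ad_alt
    ab <- ifelse(tot > 0, v$ad_alt / tot, NA_real_)
    keep <- !is.na(v$gq) & v$gq >= qc$gq_min &
      !is.na(v$dp) & v$dp >= qc$dp_min & v$dp <= qc$dp_max &
      !is.na(ab) & ab >= qc$ab_min & ab <= qc$ab_max
    v <- v[keep, , drop = FALSE]
  }
  wins$n_pass <- 0L
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    pos0 <- v$pos[v$chrom == ch] - 1  # to 0-based
    if (length(pos0) == 0L) next
    # windows may be non-contiguous after exclusion: assign by interval id
    hit <- findInterval(pos0, wins$start[wi])
    inside <- hit >= 1L & pos0 < wins$end[wi][pmax(hit, 1L)]
    tab <- table(hit[inside])
    wins$n_pass[wi[as.integer(names(tab))]] <- as.integer(tab)
  }
  k <- ceiling(top_frac * nrow(wins))
  ord <- order(-wins$n_pass, wins$chrom, wins$start)
  cutoff <- wins$n_pass[ord[k]]
  out <- wins[ord, , drop = FALSE][seq_len(sum(wins$n_pass >= cutoff)), ,
                                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a novel-insertion presence table
#'
#' TSV with columns `ni_id`, one 0/1 presence column per sample, and
#' `in_neanderthal`, `in_denisovan` flags.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ni_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("ni_id", "in_neanderthal", "in_denisovan") %in% names(d)))
  d
}

ARCHAIC_LEVELS <- c("none", "neanderthal_specific", "denisovan_specific", "both")

#' Classify novel insertions by inheritance and archaic sharing
#'
#' An insertion is inherited in a trio when it is present in the offspring
#' and in at least one parent (offspring-only presence is more likely a
#' calling artefact).  Archaic sharing comes from the Neanderthal/Denisovan
#' presence flags: specific to one archaic genome, found in both, or
#' neither.  "Archaic-like" covers the union of the three non-`none`
#' classes, so the archaic-like count always equals
#' Neanderthal-specific + Denisovan-specific + both.
#'
#' @param ni data.frame as from [read_ni_table()].
#' @param trio one row of a `trio_ped`.
#' @return data.frame per insertion: `ni_id`, `inherited`,
#'   `archaic_class`, `archaic_like`.
#' @export
classify_ni <- function(ni, trio) {
  need <- c(trio$father_id, trio$mother_id, trio$offspring_id)
  if (!all(need %in% names(ni)))
    stop("presence flags missing for trio members: ",
         paste(setdiff(need, names(ni)), collapse = ", "))
  child <- ni[[trio$offspring_id]] > 0
  parent <- ni[[trio$father_id]] > 0 | ni[[trio$mother_id]] > 0
  inherited <- child & parent
  nea <- ni$in_neanderthal > 0
  den <- ni$in_denisovan > 0
  cls <- ifelse(nea & den, "both",
         ifelse(nea, "neanderthal_specific",
         ifelse(den, "denisovan_specific", "none")))
  data.frame(ni_id = ni$ni_id, inherited = inherited,
             archaic_class = factor(cls, levels = ARCHAIC_LEVELS),
             archaic_like = cls != "none",
             stringsAsFactors = FALSE)
}

#' Per-trio tallies of inherited novel insertions
#'
#' Counts inherited insertions and their archaic categories for every trio,
#' in the layout used to report archaic sharing per population.
#'
#' @param ni presence table (see [read_ni_table()]).
#' @param ped `trio_ped`.
#' @return data.frame: `trio_id`, `population`, `n_inherited`,
#'   `n_archaic_like`, `n_neanderthal_specific`, `n_denisovan_specific`,
#'   `n_both`.
#' @export
ni_summary <- function(ni, ped) {
  rows <- lapply(seq_len(nrow(ped)), function(i) {
    trio <- ped[i, ]
    cl <- classify_ni(ni, trio)
    inh <- cl[cl$inherited, , drop = FALSE]
    data.frame(trio_id = trio$trio_id, population = trio$population,
               n_inherited = nrow(inh),
               n_archaic_like = sum(inh$archaic_like),
               n_neanderthal_specific = sum(inh$archaic_class == "neanderthal_specific"),
               n_denisovan_specific = sum(inh$archaic_class == "denisovan_specific"),
               n_both = sum(inh$archaic_class == "both"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
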