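# Shared fixtures and independent brute-force oracles.

# --- compact trio_calls builder -------------------------------------------
# Builds one F/M/C trio call set, one site per element of the gt vectors:
# gt codes, and optional per-member dp/ad_alt/gq (defaults: clean 30x calls
# with GQ 99 and genotype-consistent allele depths).
make_trio_calls <- function(f_gt, m_gt, c_gt,
                            c_dp = 30L, c_ad_alt = NULL,
                            f_ad_alt = NULL, m_ad_alt = NULL,
                            f_dp = 30L, m_dp = 30L,
                            gq = 99L, c_gq = gq, f_gq = gq, m_gq = gq,
                            chrom = "chr1", pos = NULL,
                            ref = "A", alt = "G") {
  n <- length(c_gt)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  expand <- function(x) rep_len(as.integer(x), n)
  gt <- cbind(F = expand(f_gt), M = expand(m_gt), C = expand(c_gt))
  dp <- cbind(F = expand(f_dp), M = expand(m_dp), C = expand(c_dp))
  default_ad <- function(g, d) as.integer(round(d * c(0, 0.5, 1)[g + 1L]))
  ad_alt <- cbind(
    F = if (is.null(f_ad_alt)) default_ad(gt[, "F"], dp[, "F"]) else expand(f_ad_alt),
    M = if (is.null(m_ad_alt)) default_ad(gt[, "M"], dp[, "M"]) else expand(m_ad_alt),
    C = if (is.null(c_ad_alt)) default_ad(gt[, "C"], dp[, "C"]) else expand(c_ad_alt))
  gqm <- cbind(F = expand(f_gq), M = expand(m_gq), C = expand(c_gq))
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  trio_calls(sites, gt, dp - ad_alt, ad_alt, dp, gqm)
}

test_trio <- function() trio_pedigree("T1", "F", "M", "C", "BTQ")[1, ]

# --- brute-force oracles ---------------------------------------------------

# Mendelian consistency by enumerating the 2x2 parental transmissions
mendel_brute <- function(f, m, c) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  any(outer(alleles(f), alleles(m), `+`) == c)
}

# masked-base count by per-base membership test (0-based half-open)
mask_frac_brute <- function(chrom, start, end, mask) {
  bases <- start:(end - 1)
  inside <- rep(FALSE, length(bases))
  for (k in seq_len(nrow(mask))) {
    if (mask$chrom[k] != chrom) next
    inside <- inside | (bases >= mask$start[k] & bases < mask$end[k])
  }
  sum(inside) / (end - start)
}

# P(ab in [lo, hi]) for a true het at depth d by enumeration over alt-read
# counts
ab_prob_brute <- function(d, lo = 0.3, hi = 0.7) {
  x <- 0:d
  keep <- (x / d) >= lo & (x / d) <= hi
  sum(choose(d, x[keep])) / 2^d
}

# concordance-merge by direct double loop (criterion i only)
merge_brute <- function(a, b, min_recip = 0.5) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$svtype[i] != b$svtype[j] || a$chrom[i] != b$chrom[j]) next
      ov <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
      if (ov / (a$end[i] - a$start[i]) >= min_recip &&
          ov / (b$end[j] - b$start[j]) >= min_recip) keep[i] <- TRUE
    }
  }
  a[keep, , drop = FALSE]
}

# top-fraction windows by explicit sort-and-slice with tie extension
hotspot_brute <- function(counts, top_frac = 0.01) {
  k <- ceiling(top_frac * length(counts))
  cutoff <- sort(counts, decreasing = TRUE)[k]
  which(counts >= cutoff)
}

random_cnv_set <- function(n, sample = "S1", chrom = "chr1",
                           max_pos = 1e6) {
  start <- sample.int(max_pos, n)
  len <- sample(101:5000, n, replace = TRUE)
  data.frame(sample = sample, chrom = chrom, start = start,
             end = start + len,
             svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
             copy_number = NA_integer_, caller = "X",
             stringsAsFactors = FALSE)
}

# reference per-population inherited novel-insertion tallies
# (total, archaic-like, Neanderthal-specific, Denisovan-specific)
ni_reference_rows <- function() {
  data.frame(
    population = c("BTQ", "MDQ", "SMI", "DSN", "MRT"),
    n_total = c(5984, 6145, 6010, 5991, 5979),
    n_archaic = c(2765, 2776, 2790, 2741, 2742),
    n_nea = c(1873, 1889, 1920, 1862, 1859),
    n_den = c(48, 49, 47, 49, 52),
    stringsAsFactors = FALSE
  )
}
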