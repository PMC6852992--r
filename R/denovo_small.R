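# De novo SNV/indel identification and callability-based mutation-rate
# estimation.
#
# A candidate de novo variant must satisfy, in order:
#   i)   the locus lies outside every exclusion mask (poor mappability,
#        low complexity, aberrant-SNP enrichment);
#   ii)  offspring read depth in [10, 120] and allele balance in [0.3, 0.7]
#        (guards against collapsed paralogs / CNV regions);
#   iii) genotype quality >= 50 in offspring AND both parents;
#   iv)  zero reads supporting the alternative allele in each parent;
#   v)   both parents homozygous reference, offspring carries the
#        alternative allele.

#' Filter thresholds for de novo variant detection
#'
#' Defaults are the stringent trio-sequencing thresholds used throughout
#' the package: depth 10-120x, allele balance 0.3-0.7 (closed intervals),
#' genotype quality >= 50.
#'
#' @param dp_min,dp_max offspring (and callability) depth bounds.
#' @param ab_min,ab_max allele-balance bounds, inclusive.
#' @param gq_min minimum Phred genotype quality for all three members.
#' @return list of class `denovo_criteria`.
#' @export
denovo_criteria <- function(dp_min = 10, dp_max = 120,
                            ab_min = 0.3, ab_max = 0.7, gq_min = 50) {
  stopifnot(0 <= ab_min, ab_min < ab_max, ab_max <= 1, dp_min < dp_max)
  structure(list(dp_min = dp_min, dp_max = dp_max,
                 ab_min = ab_min, ab_max = ab_max, gq_min = gq_min),
            class = "denovo_criteria")
}

REJECT_LEVELS <- c("missing", "criterion_i", "criterion_ii", "criterion_iii",
                   "criterion_iv", "criterion_v", "pass")

#' Classify candidate de novo variants in one trio
#'
#' Applies the five-criterion cascade to every site of a call set and
#' returns a per-site audit table.  A site is emitted as de novo only when
#' every criterion passes; the rejection reason is the first failed
#' criterion in the order i -> v (sites with any missing member genotype
#' are not evaluable and rejected as `"missing"`).
#'
#' @param calls `trio_calls` containing the three trio members.
#' @param trio one row of a `trio_ped`.
#' @param criteria `denovo_criteria`.
#' @param masks list of `genome_mask`s defining excluded regions.
#' @return data.frame: site columns, per-criterion logicals
#'   `crit_i`..`crit_v`, `child_ab`, `child_gt`, `pass` and `reason`.
#' @export
classify_denovo <- function(calls, trio, criteria = denovo_criteria(),
                            masks = list()) {
  stopifnot(inherits(calls, "trio_calls"))
  ids <- c(trio$father_id, trio$mother_id, trio$offspring_id)
  if (!all(ids %in% calls$samples))
    stop("trio members absent from call set: ",
         paste(setdiff(ids, calls$samples), collapse = ", "))
  f <- match(trio$father_id, calls$samples)
  m <- match(trio$mother_id, calls$samples)
  o <- match(trio$offspring_id, calls$samples)

  s <- calls$sites
  missing <- is.na(calls$gt[, f]) | is.na(calls$gt[, m]) | is.na(calls$gt[, o])

  crit_i <- !position_masked(s$chrom, s$pos, masks)

  tot <- calls$ad_ref[, o] + calls$ad_alt[, o]
  ab <- ifelse(tot > 0, calls$ad_alt[, o] / tot, NA_real_)
  crit_ii <- !is.na(calls$dp[, o]) & calls$dp[, o] >= criteria$dp_min &
    calls$dp[, o] <= criteria$dp_max &
    !is.na(ab) & ab >= criteria$ab_min & ab <= criteria$ab_max

  gq_ok <- function(j) !is.na(calls$gq[, j]) & calls$gq[, j] >= criteria$gq_min
  crit_iii <- gq_ok(f) & gq_ok(m) & gq_ok(o)

  crit_iv <- !is.na(calls$ad_alt[, f]) & calls$ad_alt[, f] == 0L &
    !is.na(calls$ad_alt[, m]) & calls$ad_alt[, m] == 0L

  crit_v <- !missing & calls$gt[, f] == 0L & calls$gt[, m] == 0L &
    calls$gt[, o] >= 1L

  pass <- !missing & crit_i & crit_ii & crit_iii & crit_iv & crit_v
  reason <- rep("pass", nrow(s))
  reason[!crit_v] <- "criterion_v"
  reason[!crit_iv] <- "criterion_iv"
  reason[!crit_iii] <- "criterion_iii"
  reason[!crit_ii] <- "criterion_ii"
  reason[!crit_i] <- "criterion_i"
  reason[missing] <- "missing"

  data.frame(trio_id = trio$trio_id, s,
             child_gt = calls$gt[, o], child_ab = ab,
             crit_i = crit_i, crit_ii = crit_ii, crit_iii = crit_iii,
             crit_iv = crit_iv, crit_v = crit_v,
             pass = pass,
             reason = factor(reason, levels = REJECT_LEVELS),
             stringsAsFactors = FALSE)
}

# P(allele balance within [ab_min, ab_max]) for a true heterozygote at
# depth d: exact Binomial(d, 1/2) mass on ab_min*d <= X <= ab_max*d,
# inclusive bounds.  Memoised over the depth range in use.
.ab_pass_prob <- function(d, ab_min, ab_max) {
  dmax <- max(d, 1L)
  lo <- ceiling(ab_min * (0:dmax) - 1e-9)
  hi <- floor(ab_max * (0:dmax) + 1e-9)
  tab <- pbinom(hi, 0:dmax, 0.5) - pbinom(lo - 1, 0:dmax, 0.5)
  tab[1L] <- 0  # depth 0: no informative reads
  out <- numeric(length(d))
  pos <- d >= 0
  out[pos] <- tab[d[pos] + 1L]
  out
}

#' Callability of a site for de novo mutation detection
#'
#' The probability that a true de novo mutation at this site in this family
#' would survive the detection filters.  Deterministic conditions (mask,
#' depth and genotype-quality windows in all members, zero parental
#' alternative reads) gate the site entirely; conditional on passing them,
#' the remaining randomness is the offspring's allele balance, modelled as
#' the exact Binomial(dp, 1/2) probability of landing inside the
#' allele-balance window for a true heterozygote at the observed offspring
#' depth.  The genome-wide sum of callabilities is the denominator of the
#' mutation-rate estimator.
#'
#' @param father_dp,father_gq,father_ad_alt father's depth, genotype
#'   quality, alternative read count (vectorised).
#' @param mother_dp,mother_gq,mother_ad_alt likewise for the mother.
#' @param child_dp offspring depth.
#' @param child_gq offspring genotype quality; `NULL` leaves the offspring
#'   quality gate out (the quality a de novo call would get is not always
#'   observable at non-variant sites).
#' @param masked logical: site falls inside an exclusion mask.
#' @param criteria `denovo_criteria`.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
site_callability <- function(father_dp, father_gq, father_ad_alt,
                             mother_dp, mother_gq, mother_ad_alt,
                             child_dp, child_gq = NULL, masked = FALSE,
                             criteria = denovo_criteria()) {
  stopifnot(all(child_dp >= 0, na.rm = TRUE))
  in_dp <- function(d) !is.na(d) & d >= criteria$dp_min & d <= criteria$dp_max
  ok <- !masked &
    in_dp(father_dp) & in_dp(mother_dp) & in_dp(child_dp) &
    !is.na(father_gq) & father_gq >= criteria$gq_min &
    !is.na(mother_gq) & mother_gq >= criteria$gq_min &
    !is.na(father_ad_alt) & father_ad_alt == 0L &
    !is.na(mother_ad_alt) & mother_ad_alt == 0L
  if (!is.null(child_gq))
    ok <- ok & !is.na(child_gq) & child_gq >= criteria$gq_min
  p <- numeric(length(ok))
  if (any(ok))
    p[ok] <- .ab_pass_prob(as.integer(child_dp[ok]),
                           criteria$ab_min, criteria$ab_max)
  p
}

#' Sum site callabilities for one trio over a call set
#'
#' Convenience wrapper applying [site_callability()] to every site of a
#' `trio_calls` object for the given trio.
#'
#' @inheritParams classify_denovo
#' @return the callability sum (numeric scalar).
#' @export
callability_sum <- function(calls, trio, criteria = denovo_criteria(),
                            masks = list()) {
  f <- match(trio$father_id, calls$samples)
  m <- match(trio$mother_id, calls$samples)
  o <- match(trio$offspring_id, calls$samples)
  masked <- position_masked(calls$sites$chrom, calls$sites$pos, masks)
  sum(site_callability(calls$dp[, f], calls$gq[, f], calls$ad_alt[, f],
                       calls$dp[, m], calls$gq[, m], calls$ad_alt[, m],
                       calls$dp[, o], calls$gq[, o], masked, criteria))
}

#' Callability-based germline mutation rate
#'
#' The per-site per-generation mutation rate of a family is the de novo
#' mutation count divided by twice the genome-wide callability sum; the
#' factor 2 accounts for the two transmitted haploid genomes.
#'
#' @param n_dnm number of de novo mutations detected in the family.
#' @param callability_sum sum over sites of the family's callability.
#' @param trio_id,vtype optional labels carried into the result.
#' @return data.frame with columns `trio_id`, `vtype`, `n_dnm`,
#'   `callability_sum`, `mu`.
#' @export
estimate_dnm_rate <- function(n_dnm, callability_sum,
                              trio_id = NA_character_, vtype = NA_character_) {
  if (any(callability_sum <= 0))
    stop("callability sum must be positive")
  stopifnot(all(n_dnm >= 0))
  data.frame(trio_id = trio_id, vtype = vtype,
             n_dnm = n_dnm, callability_sum = callability_sum,
             mu = n_dnm / (2 * callability_sum),
             stringsAsFactors = FALSE)
}

#' Full de novo analysis of a call set: calls plus rates per trio and type
#'
#' Runs [classify_denovo()] and [callability_sum()] for every trio, split
#' by variant type (SNV / indel), and assembles per-trio rate estimates.
#'
#' @inheritParams classify_denovo
#' @param ped `trio_ped` with one row per trio.
#' @return list with `calls` (de novo calls across trios) and `rates`
#'   (per trio x vtype data.frame from [estimate_dnm_rate()]).
#' @export
denovo_small_analysis <- function(calls, ped, criteria = denovo_criteria(),
                                  masks = list()) {
  res_calls <- list(); res_rates <- list()
  for (i in seq_len(nrow(ped))) {
    trio <- ped[i, ]
    audit <- classify_denovo(calls, trio, criteria, masks)
    for (vt in unique(calls$sites$vtype)) {
      sel <- calls$sites$vtype == vt
      cs <- callability_sum(subset_sites(calls, sel), trio, criteria, masks)
      n <- sum(audit$pass & audit$vtype == vt)
      res_rates[[paste(trio$trio_id, vt)]] <-
        estimate_dnm_rate(n, cs, trio$trio_id, vt)
    }
    res_calls[[trio$trio_id]] <- audit[audit$pass, , drop = FALSE]
  }
  list(calls = do.call(rbind, c(res_calls, make.row.names = FALSE)),
       rates = do.call(rbind, c(res_rates, make.row.names = FALSE)))
}
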