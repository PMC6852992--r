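# CNV ensemble merging, novelty, de novo detection, rate and cross-trio
# sharing classification.
#
# A CNV here is a deleted (CN < 2) or duplicated (CN > 2) autosomal segment
# larger than 100 bp; anything at or below 100 bp is indel territory and is
# excluded at load time.  Concordance between callers, novelty against a
# reference database, and per-trio presence all use 50% reciprocal overlap.

#' Validate and load a CNV call table
#'
#' Expected columns: `sample`, `chrom`, `start`, `end` (0-based half-open),
#' `svtype` ("DEL"/"DUP"), `copy_number`, `caller`.  Calls with length
#' <= `min_size` or on sex chromosomes are dropped; DEL calls must have
#' copy number < 2 and DUP calls > 2 where the copy number is known.
#'
#' @param x data.frame or path to a TSV with the columns above.
#' @param min_size minimum retained segment length (bp), exclusive.
#' @return validated data.frame of CNV calls.
#' @export
cnv_calls <- function(x, min_size = 100) {
  if (is.character(x)) x <- read.delim(x, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "svtype")
  if (!all(need %in% names(x)))
    stop("CNV table must have columns: ", paste(need, collapse = ", "))
  if (is.null(x$copy_number)) x$copy_number <- NA_integer_
  if (is.null(x$caller)) x$caller <- "unknown"
  stopifnot(all(x$end > x$start), all(x$svtype %in% c("DEL", "DUP")))
  cn <- x$copy_number
  bad_cn <- !is.na(cn) &
    ((x$svtype == "DEL" & cn >= 2) | (x$svtype == "DUP" & cn <= 2))
  if (any(bad_cn))
    stop("copy number inconsistent with svtype in ", sum(bad_cn), " call(s)")
  keep <- (x$end - x$start) > min_size & !(x$chrom %in% SEX_CHROMS)
  if (!all(keep))
    message("dropping ", sum(!keep), " call(s) <= ", min_size,
            " bp or on sex chromosomes")
  out <- x[keep, c("sample", "chrom", "start", "end", "svtype",
                   "copy_number", "caller"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# indices in `b` reciprocally overlapping each row of `a` (same chrom and
# svtype handled by caller); returns logical: any partner at >= min_recip
.has_recip_partner <- function(a, b, min_recip) {
  out <- logical(nrow(a))
  if (nrow(b) == 0L) return(out)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch); bi <- which(b$chrom == ch)
    if (length(bi) == 0L) next
    for (i in ai) {
      ov <- pmax(0, pmin(a$end[i], b$end[bi]) - pmax(a$start[i], b$start[bi]))
      fa <- ov / (a$end[i] - a$start[i])
      fb <- ov / (b$end[bi] - b$start[bi])
      out[i] <- any(fa >= min_recip & fb >= min_recip)
    }
  }
  out
}

#' Merge two per-caller CNV call sets into a concordant filtered set
#'
#' Ensemble filter for one sample's calls from two independent CNV callers.
#' A call is retained iff (i) a call of the same type in the other caller's
#' set attains >= 50% reciprocal overlap; (ii) it does not overlap (by even
#' one base) any repetitive/low-complexity mask interval; and (iii) less
#' than 50% of its length is covered by the union of the gap and
#' segmental-duplication masks.  Each concordant pair is emitted once, with
#' the breakpoints of the preferred caller's member (the two callers'
#' breakpoints rarely agree exactly; which to keep is a presentation
#' choice).
#'
#' @param calls_a,calls_b CNV call data.frames, one sample each, same
#'   sample in both.
#' @param repeat_mask `genome_mask` of repetitive/low-complexity regions
#'   (criterion ii), or NULL.
#' @param gapseg_mask `genome_mask` of assembly gaps plus segmental
#'   duplications (criterion iii), or NULL.
#' @param min_recip reciprocal-overlap threshold for concordance.
#' @param prefer_caller `"A"` or `"B"`: whose breakpoints represent a
#'   concordant pair.
#' @return filtered CNV call data.frame.
#' @export
merge_callsets <- function(calls_a, calls_b, repeat_mask = NULL,
                           gapseg_mask = NULL, min_recip = 0.5,
                           prefer_caller = c("A", "B")) {
  prefer_caller <- match.arg(prefer_caller)
  for (cs in list(calls_a, calls_b))
    if (length(unique(cs$sample)) > 1L)
      stop("each call set must contain a single sample")
  if (nrow(calls_a) && nrow(calls_b) &&
      calls_a$sample[1] != calls_b$sample[1])
    stop("call sets are from different samples")
  if (prefer_caller == "B") { tmp <- calls_a; calls_a <- calls_b; calls_b <- tmp }

  keep <- logical(nrow(calls_a))
  for (ty in c("DEL", "DUP")) {
    sel <- calls_a$svtype == ty
    keep[sel] <- .has_recip_partner(calls_a[sel, , drop = FALSE],
                                    calls_b[calls_b$svtype == ty, , drop = FALSE],
                                    min_recip)
  }
  out <- calls_a[keep, , drop = FALSE]
  if (nrow(out) && !is.null(repeat_mask) && nrow(repeat_mask))
    out <- out[mask_overlap_fraction(out, repeat_mask) == 0, , drop = FALSE]
  if (nrow(out) && !is.null(gapseg_mask) && nrow(gapseg_mask))
    out <- out[mask_overlap_fraction(out, gapseg_mask) < 0.5, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Novelty of CNV regions against a reference database
#'
#' A CNV is novel iff no database record attains 50% reciprocal overlap
#' with it.  By default records of any type are compared (matching the
#' permissive reading of database comparison); set `match_svtype = TRUE`
#' to require the same DEL/DUP type.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `svtype`.
#' @param database data.frame with `chrom`, `start`, `end` and optionally
#'   `svtype`.
#' @param min_recip reciprocal-overlap threshold.
#' @param match_svtype require matching svtype in the database record.
#' @return logical vector: TRUE where the region is novel.
#' @export
is_novel_cnv <- function(regions, database, min_recip = 0.5,
                         match_svtype = FALSE) {
  if (nrow(database) == 0L) return(rep(TRUE, nrow(regions)))
  if (match_svtype) {
    out <- logical(nrow(regions))
    for (ty in unique(regions$svtype)) {
      sel <- regions$svtype == ty
      db <- database[database$svtype == ty, , drop = FALSE]
      out[sel] <- !.has_recip_partner(regions[sel, , drop = FALSE], db, min_recip)
    }
    out
  } else {
    !.has_recip_partner(regions, database, min_recip)
  }
}

# length-weighted mean depth of `profile` rows (chrom/start/end/depth)
# inside an interval; NA when the profile does not cover it
.interval_mean_depth <- function(chrom, start, end, profile) {
  p <- profile[profile$chrom == chrom, , drop = FALSE]
  if (nrow(p) == 0L) return(NA_real_)
  ov <- pmax(0, pmin(end, p$end) - pmax(start, p$start))
  if (sum(ov) == 0) return(NA_real_)
  sum(p$depth * ov) / sum(ov)
}

#' Detect de novo CNVs in an offspring
#'
#' Three-step cascade mirroring a stringent trio CNV workflow:
#' step (i) drops offspring calls matched in either parent by a same-type
#' call at >= 50% reciprocal overlap; step (ii) re-genotypes each surviving
#' interval in both parents from windowed read depth -- estimated copy
#' number = round(2 x mean depth in the interval / the parent's autosomal
#' mean depth) -- and drops the call when a parent's estimated copy number
#' is consistent with the offspring's type (CN < 2 for DEL, CN > 2 for
#' DUP); step (iii) emits the survivors together with a per-call evidence
#' report (parental depth ratios and copy numbers) supporting manual
#' review.
#'
#' @param offspring_calls,father_calls,mother_calls post-merge CNV call
#'   data.frames (single sample each).
#' @param depth_profiles data.frame `sample`, `chrom`, `start`, `end`,
#'   `depth` of windowed depth, or NULL (step ii is then skipped and calls
#'   are marked unverified, with a warning).
#' @param mean_depths named numeric vector of per-sample autosomal mean
#'   depth; computed from `depth_profiles` when missing.
#' @param min_recip reciprocal-overlap threshold for step (i).
#' @param father_id,mother_id parent sample names for the depth lookup;
#'   taken from the parental call sets when those are non-empty.
#' @return list: `calls` (de novo calls with `father_cn`, `mother_cn`,
#'   `verified` columns) and `report` (one row per candidate surviving
#'   step i, including those removed at step ii).
#' @export
detect_denovo_cnv <- function(offspring_calls, father_calls, mother_calls,
                              depth_profiles = NULL, mean_depths = NULL,
                              min_recip = 0.5,
                              father_id = NULL, mother_id = NULL) {
  cand <- offspring_calls
  matched <- logical(nrow(cand))
  for (ty in c("DEL", "DUP")) {
    sel <- cand$svtype == ty
    if (!any(sel)) next
    matched[sel] <-
      .has_recip_partner(cand[sel, , drop = FALSE],
                         father_calls[father_calls$svtype == ty, , drop = FALSE],
                         min_recip) |
      .has_recip_partner(cand[sel, , drop = FALSE],
                         mother_calls[mother_calls$svtype == ty, , drop = FALSE],
                         min_recip)
  }
  cand <- cand[!matched, , drop = FALSE]

  n <- nrow(cand)
  father_cn <- mother_cn <- rep(NA_real_, n)
  father_ratio <- mother_ratio <- rep(NA_real_, n)
  verified <- rep(FALSE, n)
  drop_ii <- rep(FALSE, n)

  fid <- father_id %||% unique(father_calls$sample)
  mid <- mother_id %||% unique(mother_calls$sample)
  if (is.null(depth_profiles) || length(fid) != 1L || length(mid) != 1L) {
    if (n > 0L)
      warning("no depth profiles (or parent ids) available: parental ",
              "re-genotyping skipped, de novo CNV calls are unverified")
  } else if (n > 0L) {
    if (is.null(mean_depths)) {
      mean_depths <- vapply(split(depth_profiles, depth_profiles$sample),
                            function(p) sum(p$depth * (p$end - p$start)) /
                              sum(p$end - p$start), 0)
    }
    fp <- depth_profiles[depth_profiles$sample == fid, , drop = FALSE]
    mp <- depth_profiles[depth_profiles$sample == mid, , drop = FALSE]
    for (i in seq_len(n)) {
      fdep <- .interval_mean_depth(cand$chrom[i], cand$start[i], cand$end[i], fp)
      mdep <- .interval_mean_depth(cand$chrom[i], cand$start[i], cand$end[i], mp)
      father_ratio[i] <- fdep / mean_depths[[fid]]
      mother_ratio[i] <- mdep / mean_depths[[mid]]
      father_cn[i] <- round(2 * father_ratio[i])
      mother_cn[i] <- round(2 * mother_ratio[i])
      if (!is.na(father_cn[i]) && !is.na(mother_cn[i])) {
        verified[i] <- TRUE
        consistent <- if (cand$svtype[i] == "DEL")
          father_cn[i] < 2 || mother_cn[i] < 2
        else
          father_cn[i] > 2 || mother_cn[i] > 2
        drop_ii[i] <- consistent
      }
    }
  }

  report <- cbind(cand,
                  father_ratio = father_ratio, mother_ratio = mother_ratio,
                  father_cn = father_cn, mother_cn = mother_cn,
                  verified = verified,
                  removed_step_ii = drop_ii)
  rownames(report) <- NULL
  calls <- report[!drop_ii, , drop = FALSE]
  calls$removed_step_ii <- NULL
  rownames(calls) <- NULL
  list(calls = calls, report = report)
}

#' De novo CNV mutation rate
#'
#' The de novo CNV rate of a trio: de novo calls divided by the total CNVs
#' in the offspring.  Also reports the value rounded to one significant
#' digit, the presentation convention for CNV rates.
#'
#' @param n_denovo,n_total de novo and total CNV counts.
#' @return data.frame with `n_denovo`, `n_total`, `rate`, `rate_reported`.
#' @export
estimate_cnv_rate <- function(n_denovo, n_total) {
  if (any(n_total <= 0)) stop("total CNV count must be positive")
  if (any(n_denovo > n_total)) stop("de novo count exceeds total")
  rate <- n_denovo / n_total
  data.frame(n_denovo = n_denovo, n_total = n_total,
             rate = rate, rate_reported = signif(rate, 1))
}

#' Deletion/duplication tally of a CNV call set
#' @param calls CNV call data.frame.
#' @return data.frame with `n_del`, `n_dup`, `n_total` (their sum).
#' @export
cnv_type_summary <- function(calls) {
  n_del <- sum(calls$svtype == "DEL")
  n_dup <- sum(calls$svtype == "DUP")
  data.frame(n_del = n_del, n_dup = n_dup, n_total = n_del + n_dup)
}

#' Cluster CNV calls across trios into regions with per-trio presence
#'
#' Same-type calls linked at >= 50% reciprocal overlap (single linkage)
#' form one region, represented by the earliest member call's interval.
#' A trio is present in a region when any of its members contributed a
#' call.
#'
#' @param calls pooled CNV call data.frame across samples.
#' @param ped `trio_ped` mapping samples to trios.
#' @param min_recip reciprocal-overlap threshold.
#' @return list: `regions` (chrom/start/end/svtype) and `presence`
#'   (logical matrix regions x trios).
#' @export
cnv_region_presence <- function(calls, ped, min_recip = 0.5) {
  sample2trio <- with(ped, setNames(rep(trio_id, 3),
                                    c(father_id, mother_id, offspring_id)))
  if (!all(calls$sample %in% names(sample2trio)))
    stop("calls contain samples absent from the pedigree")
  n <- nrow(calls)
  comp <- seq_len(n)  # union-find, path-halving
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (ty in c("DEL", "DUP")) for (ch in unique(calls$chrom)) {
    idx <- which(calls$svtype == ty & calls$chrom == ch)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      ov <- max(0, min(calls$end[i], calls$end[j]) -
                   max(calls$start[i], calls$start[j]))
      if (ov / (calls$end[i] - calls$start[i]) >= min_recip &&
          ov / (calls$end[j] - calls$start[j]) >= min_recip) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  reps <- sort(unique(root))
  regions <- calls[reps, c("chrom", "start", "end", "svtype"), drop = FALSE]
  rownames(regions) <- NULL
  presence <- matrix(FALSE, length(reps), nrow(ped),
                     dimnames = list(NULL, ped$trio_id))
  trio_of_call <- sample2trio[calls$sample]
  for (k in seq_along(reps)) {
    members <- trio_of_call[root == reps[k]]
    presence[k, unique(members)] <- TRUE
  }
  list(regions = regions, presence = presence)
}

SHARING_LEVELS <- c("MLS", "OA", "NGO", "NB", "private", "other")

#' Classify cross-trio sharing of CNV regions
#'
#' Assigns each region exactly one sharing class from its per-trio presence
#' pattern, in precedence order: `MLS` (Malaysian: present in at least one
#' Orang Asli and one North Bornean trio), `OA` (all of BTQ, MDQ and SMI),
#' `NGO` (Negrito: BTQ and MDQ), `NB` (North Bornean: DSN and MRT),
#' `private` (exactly one trio), else `other`.
#'
#' @param presence logical matrix (regions x trios) with trio_id colnames,
#'   or a logical vector for one region.
#' @param ped `trio_ped` giving each trio's population and group.
#' @return factor of sharing classes, one per region.
#' @export
classify_sharing <- function(presence, ped) {
  if (is.vector(presence)) presence <- matrix(presence, nrow = 1,
                                              dimnames = list(NULL, ped$trio_id))
  stopifnot(identical(colnames(presence), ped$trio_id))
  pop <- ped$population; grp <- ped$group
  in_pop <- function(p) {
    j <- which(pop == p)
    if (length(j) == 0L) rep(FALSE, nrow(presence))
    else rowSums(presence[, j, drop = FALSE]) > 0
  }
  any_oa <- rowSums(presence[, grp == "OA", drop = FALSE]) > 0
  any_nb <- rowSums(presence[, grp == "NB", drop = FALSE]) > 0
  n_trios <- rowSums(presence)
  out <- rep("other", nrow(presence))
  out[n_trios == 1L] <- "private"
  out[in_pop("DSN") & in_pop("MRT")] <- "NB"
  out[in_pop("BTQ") & in_pop("MDQ")] <- "NGO"
  out[in_pop("BTQ") & in_pop("MDQ") & in_pop("SMI")] <- "OA"
  out[any_oa & any_nb] <- "MLS"
  factor(out, levels = SHARING_LEVELS)
}
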