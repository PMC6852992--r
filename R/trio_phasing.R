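# Pre-phasing quality filters and deterministic transmission-based phasing.
#
# With both parents genotyped, every trio genotype configuration that is not
# triply heterozygous determines the offspring's transmitted alleles
# exactly (identity by descent); the triple-heterozygous residue would need
# a statistical population model and is emitted unphased.

#' Pre-phasing site filters
#'
#' Removes sites with a missing-genotype fraction above `max_missing`
#' across all samples, or exhibiting a Mendelian error in at least
#' `min_mendel_trios` trios.  The removal log records the triggering rule
#' per site (missing rate is checked first).
#'
#' @param calls `trio_calls` covering all trio members.
#' @param ped `trio_ped`.
#' @param max_missing maximum tolerated missing-genotype fraction.
#' @param min_mendel_trios number of Mendelian-error trios that triggers
#'   removal.
#' @return list: `calls` (retained `trio_calls`), `removed` (data.frame of
#'   removed sites with a `rule` column), `mendel_errors` (trio-count of
#'   Mendelian errors per retained site).
#' @export
prephase_filter <- function(calls, ped, max_missing = 0.10,
                            min_mendel_trios = 2L) {
  miss_frac <- rowMeans(is.na(calls$gt))
  n_err <- integer(nrow(calls$sites))
  for (i in seq_len(nrow(ped))) {
    mc <- mendelian_consistent(calls$gt[, ped$father_id[i]],
                               calls$gt[, ped$mother_id[i]],
                               calls$gt[, ped$offspring_id[i]])
    n_err <- n_err + (!is.na(mc) & !mc)
  }
  drop_miss <- miss_frac > max_missing
  drop_mendel <- !drop_miss & n_err >= min_mendel_trios
  drop <- drop_miss | drop_mendel
  removed <- data.frame(calls$sites[drop, , drop = FALSE],
                        rule = ifelse(drop_miss[drop], "missing_rate",
                                      "mendelian_error"),
                        stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  list(calls = if (all(!drop)) calls else subset_sites(calls, !drop),
       removed = removed,
       mendel_errors = n_err[!drop])
}

#' Phase one trio's genotypes at single sites by transmission
#'
#' Deterministic IBD phasing: offspring homozygotes phase trivially; an
#' offspring heterozygote phases whenever at least one parent is
#' homozygous, since that parent's transmitted allele is forced.  Triply
#' heterozygous configurations are returned unphased.  Allele order in the
#' output is paternal then maternal.
#'
#' @param father,mother,child genotype codes (0/1/2/NA) or labels,
#'   vectorised over sites.  Sites must be Mendelian-consistent; an
#'   inconsistent configuration is an error (filter first, see
#'   [prephase_filter()]).  Missing genotypes return unphased.
#' @return data.frame: `paternal`, `maternal` (allele indices, NA when
#'   unphased) and `phased`.
#' @export
phase_trio_site <- function(father, mother, child) {
  f <- gt_code(father); m <- gt_code(mother); c <- gt_code(child)
  n <- max(length(f), length(m), length(c))
  f <- rep_len(f, n); m <- rep_len(m, n); c <- rep_len(c, n)
  mc <- mendelian_consistent(f, m, c)
  if (any(!mc, na.rm = TRUE))
    stop("Mendelian-inconsistent site(s) cannot be phased; filter first")
  pat <- mat <- rep(NA_integer_, n)
  phased <- rep(FALSE, n)
  evaluable <- !is.na(mc)

  hom <- evaluable & c != 1L           # child homozygote: trivial
  pat[hom] <- mat[hom] <- c[hom] %/% 2L
  phased[hom] <- TRUE

  het <- evaluable & c == 1L
  # mother homozygous forces the maternal allele, paternal is the other
  mm <- het & m != 1L
  mat[mm] <- m[mm] %/% 2L
  pat[mm] <- 1L - mat[mm]
  phased[mm] <- TRUE
  # father homozygous forces the paternal allele
  ff <- het & f != 1L & !phased
  pat[ff] <- f[ff] %/% 2L
  mat[ff] <- 1L - pat[ff]
  phased[ff] <- TRUE
  # triple heterozygous: ambiguous without a population model

  data.frame(paternal = pat, maternal = mat, phased = phased)
}

#' Phase all sites of a call set for one trio
#'
#' Checks Mendelian consistency per site, phases the consistent sites by
#' transmission and flags the rest.
#'
#' @param calls `trio_calls`.
#' @param trio one row of a `trio_ped`.
#' @return data.frame per site: `paternal`, `maternal`, `phased`,
#'   `mendel_error`.
#' @export
phase_trio <- function(calls, trio) {
  f <- calls$gt[, trio$father_id]
  m <- calls$gt[, trio$mother_id]
  c <- calls$gt[, trio$offspring_id]
  mc <- mendelian_consistent(f, m, c)
  err <- !is.na(mc) & !mc
  out <- data.frame(paternal = rep(NA_integer_, length(f)),
                    maternal = rep(NA_integer_, length(f)),
                    phased = FALSE, mendel_error = err)
  ok <- which(!err)
  if (length(ok)) {
    ph <- phase_trio_site(f[ok], m[ok], c[ok])
    out$paternal[ok] <- ph$paternal
    out$maternal[ok] <- ph$maternal
    out$phased[ok] <- ph$phased
  }
  out
}

#' Phasing summary across trios
#'
#' @param calls `trio_calls` (after [prephase_filter()]).
#' @param ped `trio_ped`.
#' @return list: `phase` (named list per trio of [phase_trio()] results)
#'   and `report` (per-trio counts of phased / triple-het unphased /
#'   Mendelian-error / missing sites).
#' @export
phase_all_trios <- function(calls, ped) {
  phase <- list(); rows <- list()
  for (i in seq_len(nrow(ped))) {
    trio <- ped[i, ]
    ph <- phase_trio(calls, trio)
    gts <- cbind(calls$gt[, trio$father_id], calls$gt[, trio$mother_id],
                 calls$gt[, trio$offspring_id])
    n_missing <- sum(rowSums(is.na(gts)) > 0)
    triple_het <- !ph$phased & !ph$mendel_error &
      rowSums(is.na(gts)) == 0 & rowSums(gts == 1L) == 3
    phase[[trio$trio_id]] <- ph
    rows[[i]] <- data.frame(trio_id = trio$trio_id,
                            n_sites = nrow(ph),
                            n_phased = sum(ph$phased),
                            n_triple_het = sum(triple_het),
                            n_mendel_error = sum(ph$mendel_error),
                            n_missing = n_missing,
                            stringsAsFactors = FALSE)
  }
  list(phase = phase, report = do.call(rbind, rows))
}
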