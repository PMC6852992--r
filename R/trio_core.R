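# Core data model: pedigrees, interval algebra, Mendelian-consistency logic.

#' Built-in population-to-group map for the five native Malaysian trios
#'
#' The three Orang Asli (OA) populations from Peninsular Malaysia -- Bateq
#' (BTQ), Mendriq (MDQ) and Semai (SMI) -- and the two North Bornean (NB)
#' populations, Dusun (DSN) and Murut (MRT).
#'
#' @return data.frame with columns `population` and `group`.
#' @export
malaysian_populations <- function() {
  data.frame(
    population = c("BTQ", "MDQ", "SMI", "DSN", "MRT"),
    group      = c("OA",  "OA",  "OA",  "NB",  "NB"),
    stringsAsFactors = FALSE
  )
}

#' Construct a trio pedigree table
#'
#' One row per father-mother-offspring trio.  Populations are mapped to
#' groups through `populations`; the default map covers the five native
#' Malaysian populations (BTQ/MDQ/SMI -> OA, DSN/MRT -> NB).  User-defined
#' populations must come with their own map.
#'
#' @param trio_id trio labels.
#' @param father_id,mother_id,offspring_id sample labels; must be distinct
#'   within each trio.
#' @param population population label per trio.
#' @param populations data.frame with columns `population`, `group` giving a
#'   total population-to-group mapping.
#' @return data.frame of class `trio_ped`.
#' @export
trio_pedigree <- function(trio_id, father_id, mother_id, offspring_id,
                          population,
                          populations = malaysian_populations()) {
  n <- length(trio_id)
  stopifnot(length(father_id) == n, length(mother_id) == n,
            length(offspring_id) == n, length(population) == n)
  for (i in seq_len(n)) {
    ids <- c(father_id[i], mother_id[i], offspring_id[i])
    if (anyDuplicated(ids))
      stop("trio ", trio_id[i], ": father, mother and offspring ids must be distinct")
  }
  grp <- populations$group[match(population, populations$population)]
  if (anyNA(grp))
    stop("population(s) without a group mapping: ",
         paste(unique(population[is.na(grp)]), collapse = ", "))
  ped <- data.frame(trio_id = as.character(trio_id),
                    father_id = as.character(father_id),
                    mother_id = as.character(mother_id),
                    offspring_id = as.character(offspring_id),
                    population = as.character(population),
                    group = grp,
                    stringsAsFactors = FALSE)
  class(ped) <- c("trio_ped", "data.frame")
  ped
}

#' Read a 6-column PED file into a trio pedigree
#'
#' Standard PED columns: family, individual, father, mother, sex, phenotype.
#' Offspring are the individuals whose father and mother ids both appear in
#' the file; each family must contain exactly one such individual.  The
#' family id doubles as the trio id, and its leading letters as the
#' population label unless `population` is supplied.
#'
#' @param path PED file.
#' @param populations population-to-group map (see [trio_pedigree()]).
#' @param population optional named vector mapping family id to population.
#' @return `trio_ped` data.frame.
#' @export
read_ped <- function(path, populations = malaysian_populations(),
                     population = NULL) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  out <- lapply(split(ped, ped$fid), function(fam) {
    child <- fam$pat %in% fam$iid & fam$mat %in% fam$iid
    if (sum(child) != 1L)
      stop("family ", fam$fid[1], ": expected exactly one offspring with both parents present")
    data.frame(trio_id = fam$fid[1],
               father_id = fam$pat[child],
               mother_id = fam$mat[child],
               offspring_id = fam$iid[child],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  pop <- if (is.null(population)) {
    # family ids like "BTQ" or "BTQ1" carry the population prefix
    sub("[0-9_].*$", "", out$trio_id)
  } else {
    unname(population[out$trio_id])
  }
  trio_pedigree(out$trio_id, out$father_id, out$mother_id, out$offspring_id,
                pop, populations)
}

#' Allele balance of a genotype call
#'
#' Fraction of informative reads supporting the alternative allele,
#' `ad_alt / (ad_ref + ad_alt)`.  A true heterozygote is expected near 0.5.
#'
#' @param ad_ref,ad_alt reference / alternative read counts (vectorised).
#' @return numeric vector of fractions in \[0, 1\].
#' @export
allele_balance <- function(ad_ref, ad_alt) {
  stopifnot(all(ad_ref >= 0, na.rm = TRUE), all(ad_alt >= 0, na.rm = TRUE))
  tot <- ad_ref + ad_alt
  if (any(!is.na(tot) & tot == 0))
    stop("allele balance undefined: zero informative reads")
  ad_alt / tot
}

# All 27 genotype triples, evaluated once: consistency of (father, mother,
# child) under biparental transmission.  child must equal one transmissible
# paternal allele plus one transmissible maternal allele.
.mendel_table <- local({
  tab <- array(FALSE, dim = c(3, 3, 3))
  alleles <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  for (f in 0:2) for (m in 0:2) for (c in 0:2) {
    poss <- outer(alleles[[f + 1L]], alleles[[m + 1L]], `+`)
    tab[f + 1L, m + 1L, c + 1L] <- c %in% poss
  }
  tab
})

#' Mendelian consistency of a trio genotype configuration
#'
#' TRUE iff the child genotype can be formed from one allele of each parent
#' at an autosomal biallelic site.  Missing genotypes in any member make the
#' configuration non-evaluable (`NA`).
#'
#' @param father,mother,child genotype codes (0/1/2/NA) or labels.
#' @return logical vector (TRUE/FALSE/NA), vectorised over sites.
#' @export
mendelian_consistent <- function(father, mother, child) {
  f <- gt_code(father); m <- gt_code(mother); c <- gt_code(child)
  n <- max(length(f), length(m), length(c))
  f <- rep_len(f, n); m <- rep_len(m, n); c <- rep_len(c, n)
  out <- rep(NA, n)
  ok <- !is.na(f) & !is.na(m) & !is.na(c)
  out[ok] <- .mendel_table[cbind(f[ok] + 1L, m[ok] + 1L, c[ok] + 1L)]
  out
}

#' Reciprocal overlap between two genomic intervals
#'
#' Two intervals overlap reciprocally at threshold t when the shared span
#' covers at least t of BOTH interval lengths.  Coordinates are 0-based
#' half-open.  Intervals on different chromosomes share nothing.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end` (recycled to
#'   a common length and compared row-wise).
#' @return data.frame with columns `frac_a`, `frac_b`: the overlap length
#'   divided by each interval's own length.
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  as_ <- a$start[ai]; ae <- a$end[ai]; bs <- b$start[bi]; be <- b$end[bi]
  stopifnot(all(ae > as_), all(be > bs))
  ov <- pmax(0, pmin(ae, be) - pmax(as_, bs))
  ov[as.character(a$chrom[ai]) != as.character(b$chrom[bi])] <- 0
  data.frame(frac_a = ov / (ae - as_), frac_b = ov / (be - bs))
}

#' Construct a genome mask
#'
#' A named set of genomic intervals (0-based half-open) used for
#' inclusion/exclusion filtering: repeat and low-complexity tracks,
#' assembly gaps, segmental duplications, telomere/centromere coordinates.
#'
#' @param chrom,start,end interval coordinates.
#' @param name mask label.
#' @return data.frame of class `genome_mask`, sorted by chromosome and start.
#' @export
genome_mask <- function(chrom = character(), start = integer(),
                        end = integer(), name = "mask") {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            all(start >= 0), all(end > start))
  m <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "mask_name") <- name
  class(m) <- c("genome_mask", "data.frame")
  m
}

#' Read a BED file as a genome mask
#'
#' First three columns are used; BED is 0-based half-open, matching the
#' package's internal convention.
#'
#' @param path BED file.
#' @param name mask label (defaults to the file name).
#' @return `genome_mask`.
#' @export
read_bed <- function(path, name = basename(path)) {
  bed <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genome_mask(bed[[1]], bed[[2]], bed[[3]], name = name)
}

#' Write intervals to a BED file
#' @param x data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# per-chromosome reduced IRanges view of a mask (1-based closed, as IRanges)
.mask_iranges <- function(mask) {
  lapply(split(mask[, c("start", "end")], mask$chrom), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
}

#' Fraction of an interval covered by a mask
#'
#' Total masked bases within each query interval divided by the interval
#' length; overlapping mask intervals are counted once (union).
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param mask a `genome_mask` (or any chrom/start/end data.frame).
#' @return numeric vector of covered fractions in \[0, 1\].
#' @export
mask_overlap_fraction <- function(intervals, mask) {
  out <- numeric(nrow(intervals))
  if (nrow(mask) == 0L || nrow(intervals) == 0L) return(out)
  mr <- .mask_iranges(mask)
  for (ch in unique(intervals$chrom)) {
    sel <- which(intervals$chrom == ch)
    if (is.null(mr[[ch]])) next
    q <- IRanges::IRanges(start = intervals$start[sel] + 1L,
                          end = intervals$end[sel])
    hits <- IRanges::findOverlaps(q, mr[[ch]])
    if (length(hits) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(hits)], mr[[ch]][S4Vectors::subjectHits(hits)]))
    cov <- tapply(w, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(cov))
    out[sel[idx]] <- as.numeric(cov) / (intervals$end[sel[idx]] - intervals$start[sel[idx]])
  }
  out
}

#' Test whether 1-based positions fall inside any mask interval
#'
#' @param chrom,pos chromosome and 1-based position vectors (VCF convention).
#' @param masks a `genome_mask` or list of them.
#' @return logical vector.
#' @export
position_masked <- function(chrom, pos, masks) {
  if (inherits(masks, "data.frame")) masks <- list(masks)
  hit <- logical(length(pos))
  for (m in masks) {
    if (is.null(m) || nrow(m) == 0L) next
    frac <- mask_overlap_fraction(
      data.frame(chrom = chrom, start = pos - 1, end = pos), m)
    hit <- hit | frac > 0
  }
  hit
}
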