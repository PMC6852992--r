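# Multi-sample genotype container and VCF input/output.

SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24")

#' Construct a multi-sample genotype call set
#'
#' Container for biallelic variant sites and per-sample call-level fields.
#' Sites are 1-based (VCF convention).  All analysis in the package is
#' autosomal: records on X/Y are dropped with a message.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, and
#'   optionally `vtype` ("snv"/"indel"; derived from allele lengths when
#'   absent).
#' @param gt integer matrix (sites x samples) of genotype codes 0/1/2/NA.
#' @param ad_ref,ad_alt,dp,gq matching matrices of reference / alternative
#'   read counts, total depth and Phred genotype quality.  When `dp` is `NA`
#'   for a call it is filled with `ad_ref + ad_alt` (caller dialects differ
#'   on whether DP counts uninformative reads; the explicit precedence keeps
#'   downstream filters deterministic).
#' @return object of class `trio_calls`: a list with elements `sites`,
#'   `samples`, `gt`, `ad_ref`, `ad_alt`, `dp`, `gq`.
#' @export
trio_calls <- function(sites, gt, ad_ref, ad_alt, dp, gq) {
  stopifnot(is.matrix(gt), nrow(gt) == nrow(sites))
  samples <- colnames(gt)
  if (is.null(samples)) stop("gt matrix must have sample column names")
  for (m in list(ad_ref, ad_alt, dp, gq))
    stopifnot(identical(dim(m), dim(gt)))
  if (is.null(sites$vtype))
    sites$vtype <- ifelse(nchar(sites$ref) == nchar(sites$alt), "snv", "indel")
  bad <- nchar(sites$ref) >= 100 | nchar(sites$alt) >= 100
  autosomal <- !(sites$chrom %in% SEX_CHROMS)
  keep <- autosomal & !bad
  if (!all(keep)) {
    message("dropping ", sum(!keep),
            " record(s): sex-chromosome or allele length >= 100 bp")
    sites <- sites[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]; ad_ref <- ad_ref[keep, , drop = FALSE]
    ad_alt <- ad_alt[keep, , drop = FALSE]; dp <- dp[keep, , drop = FALSE]
    gq <- gq[keep, , drop = FALSE]
  }
  fill <- is.na(dp)
  dp[fill] <- ad_ref[fill] + ad_alt[fill]
  rownames(sites) <- NULL
  structure(list(sites = sites, samples = samples, gt = gt,
                 ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq),
            class = "trio_calls")
}

#' @export
print.trio_calls <- function(x, ...) {
  cat("trio_calls:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  cat("  samples:", paste(x$samples, collapse = ", "), "\n")
  cat("  vtypes:", paste(names(table(x$sites$vtype)),
                         table(x$sites$vtype), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a call set by site index
#' @param x `trio_calls`; @param i site indices or logical vector.
#' @export
subset_sites <- function(x, i) {
  trio_calls(x$sites[i, , drop = FALSE], x$gt[i, , drop = FALSE],
             x$ad_ref[i, , drop = FALSE], x$ad_alt[i, , drop = FALSE],
             x$dp[i, , drop = FALSE], x$gq[i, , drop = FALSE])
}

#' Read a multi-sample VCF into a `trio_calls` object
#'
#' Uses \pkg{vcfR} for parsing (plain or gzip).  Multiallelic records are
#' split into one biallelic record per alternative allele before any
#' filtering; genotype alleles other than the focal alternative are recoded
#' as reference, and AD fields are re-indexed accordingly.  Records whose
#' genotypes cannot be resolved to biallelic are dropped with a warning.
#' Sex chromosomes are excluded.
#'
#' @param path VCF file (.vcf or .vcf.gz).
#' @return `trio_calls`.
#' @export
read_trio_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  dp_raw <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq_raw <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  samples <- colnames(gt_raw)

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_along(n_alt), n_alt)      # source record per output row
  alt_k <- sequence(n_alt)                 # which ALT allele this row is

  n <- length(rec)
  gt <- matrix(NA_integer_, n, length(samples), dimnames = list(NULL, samples))
  ad_ref <- gt; ad_alt <- gt
  for (j in seq_along(samples)) {
    g <- sub(":.*$", "", gt_raw[rec, j])
    g <- sub("\\|", "/", g)
    parts <- strsplit(g, "/", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) > 1L) p[2L] else NA_character_, "")))
    code <- (a1 == alt_k) + (a2 == alt_k)  # other alts count as ref
    code[is.na(a1) | is.na(a2)] <- NA_integer_
    gt[, j] <- code
    adp <- strsplit(ad_raw[rec, j], ",", fixed = TRUE)
    ad_ref[, j] <- suppressWarnings(as.integer(vapply(adp, function(p)
      if (length(p) >= 1L) p[1L] else NA_character_, "")))
    ad_alt[, j] <- suppressWarnings(as.integer(mapply(function(p, k)
      if (length(p) >= k + 1L) p[k + 1L] else NA_character_,
      adp, alt_k)))
  }
  dp <- matrix(as.integer(dp_raw[rec, , drop = FALSE]), n,
               dimnames = list(NULL, samples))
  gq <- matrix(as.integer(gq_raw[rec, , drop = FALSE]), n,
               dimnames = list(NULL, samples))
  if (any(n_alt > 1L))
    warning(sum(n_alt > 1L), " multiallelic record(s) split into biallelic records")
  sites <- data.frame(chrom = fix$CHROM[rec],
                      pos = as.integer(fix$POS[rec]),
                      ref = fix$REF[rec],
                      alt = unlist(alt_list),
                      stringsAsFactors = FALSE)
  trio_calls(sites, gt, ad_ref, ad_alt, dp, gq)
}

#' Write a `trio_calls` object as a multi-sample VCF
#'
#' Emits GT:AD:DP:GQ per sample.  When `phase` is supplied (a list per trio
#' of data.frames from [phase_trio()]), offspring genotypes that phased are
#' written with the pipe separator in paternal|maternal order.
#'
#' @param x `trio_calls`.
#' @param path output path (plain text `.vcf`).
#' @param ped optional `trio_ped`, required with `phase`.
#' @param phase optional named list (by trio_id) of phasing data.frames.
#' @return the path, invisibly.
#' @export
write_trio_vcf <- function(x, path, ped = NULL, phase = NULL) {
  gt_str <- matrix("", nrow(x$sites), length(x$samples),
                   dimnames = list(NULL, x$samples))
  base_gt <- c("0/0", "0/1", "1/1")
  for (j in seq_along(x$samples)) {
    g <- x$gt[, j]
    s <- ifelse(is.na(g), "./.", base_gt[g + 1L])
    gt_str[, j] <- s
  }
  if (!is.null(phase)) {
    stopifnot(!is.null(ped))
    for (tid in names(phase)) {
      ph <- phase[[tid]]
      child <- ped$offspring_id[ped$trio_id == tid]
      sel <- which(ph$phased)
      gt_str[sel, child] <- paste0(ph$paternal[sel], "|", ph$maternal[sel])
    }
  }
  fmt <- matrix(paste0(gt_str, ":",
                       x$ad_ref, ",", x$ad_alt, ":", x$dp, ":", x$gq),
                nrow(x$sites))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                ".", "PASS", ".", "GT:AD:DP:GQ",
                apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
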