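test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(n_trios = 2, n_sites = 2000, n_sites_indel = 500,
                    chrom_length = 1e6, dnm_rate_snv = 1e-3)
  set.seed(100); a <- simulate_trio_cohort(cfg)
  set.seed(100); b <- simulate_trio_cohort(cfg)
  expect_identical(a$calls$gt, b$calls$gt)
  expect_identical(a$calls$ad_alt, b$calls$ad_alt)
  expect_identical(a$truth, b$truth)
  # and the written files are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  set.seed(100); simulate_trio_cohort(cfg, dir = d1)
  set.seed(100); simulate_trio_cohort(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "trios.vcf")),
                   readLines(file.path(d2, "trios.vcf")))
})

test_that("zero de novo rate plants nothing; all non-planted sites are Mendelian-consistent", {
  cfg <- sim_config(n_trios = 2, n_sites = 5000, n_sites_indel = 1000,
                    chrom_length = 1e6, dnm_rate_snv = 0, dnm_rate_indel = 0)
  set.seed(101)
  coh <- simulate_trio_cohort(cfg)
  expect_equal(nrow(coh$truth), 0)
  for (i in 1:2) {
    trio <- coh$ped[i, ]
    mc <- mendelian_consistent(coh$calls$gt[, trio$father_id],
                               coh$calls$gt[, trio$mother_id],
                               coh$calls$gt[, trio$offspring_id])
    expect_true(all(mc))
  }
})

test_that("planted de novo counts follow the configured rate", {
  # expected count per trio = n_sites x rate (two transmissions, each ref
  # with average probability 1/2 under the symmetric frequency prior)
  cfg <- sim_config(n_trios = 1, n_sites = 2e5, chrom_length = 1e7,
                    dnm_rate_snv = 1e-4)
  lambda <- cfg$n_sites * cfg$dnm_rate_snv  # 20
  counts <- integer(30)
  for (k in seq_along(counts)) {
    set.seed(200 + k)
    acc <- simulate_rate_trial(cfg)
    counts[k] <- acc[["n_planted"]]
  }
  # each draw within the central 99.9% Poisson band, mean within 4 SE
  expect_true(all(counts >= qpois(5e-4, lambda) &
                  counts <= qpois(1 - 5e-4, lambda)))
  expect_lt(abs(mean(counts) - lambda) / (sqrt(lambda / 30)), 4)
})

test_that("truth tables locate every planted event in the emitted calls", {
  cfg <- sim_config(n_trios = 2, n_sites = 2e4, n_sites_indel = 5e3,
                    chrom_length = 1e7, dnm_rate_snv = 5e-4,
                    dnm_rate_indel = 5e-4)
  set.seed(102)
  coh <- simulate_trio_cohort(cfg)
  expect_gt(nrow(coh$truth), 0)
  for (r in seq_len(nrow(coh$truth))) {
    i <- which(coh$calls$sites$pos == coh$truth$pos[r])
    expect_length(i, 1)
    child <- coh$ped$offspring_id[coh$ped$trio_id == coh$truth$trio_id[r]]
    expect_gte(coh$calls$gt[i, child], 1L)
  }
})

test_that("VCF round-trip preserves genotypes and call-level fields", {
  cfg <- sim_config(n_trios = 2, n_sites = 500, n_sites_indel = 100,
                    chrom_length = 1e6, dnm_rate_snv = 1e-3)
  set.seed(103)
  d <- tempfile()
  coh <- simulate_trio_cohort(cfg, dir = d)
  back <- read_trio_vcf(file.path(d, "trios.vcf"))
  expect_identical(back$gt, coh$calls$gt)
  expect_identical(back$ad_alt, coh$calls$ad_alt)
  expect_identical(back$dp, coh$calls$dp)
  expect_identical(back$gq, coh$calls$gq)
  expect_equal(back$sites$pos, coh$calls$sites$pos)
  ped <- read_ped(file.path(d, "trios.ped"))
  expect_identical(ped$offspring_id, coh$ped$offspring_id)
})

test_that("multiallelic records are split into biallelic records on read", {
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:AD:DP:GQ\t1/2:2,14,14:30:80",
    "chr1\t200\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP:GQ\t0/1:15,15:30:99"),
    tmp)
  expect_warning(calls <- read_trio_vcf(tmp), "multiallelic")
  expect_equal(nrow(calls$sites), 3)  # A>G, A>T, A>G
  split_rows <- calls$sites$pos == 100
  # 1/2 seen from the A>G record: one G allele -> het; AD re-indexed
  expect_equal(calls$gt[split_rows, "S1"], c(1L, 1L))
  expect_equal(calls$ad_alt[split_rows, "S1"], c(14L, 14L))
  expect_equal(calls$ad_ref[split_rows, "S1"], c(2L, 2L))
})

test_that("sex-chromosome records are excluded at load", {
  sites <- data.frame(chrom = c("chr1", "chrX"), pos = c(1, 2),
                      ref = "A", alt = "G")
  m <- function(v) matrix(as.integer(v), 2, 1, dimnames = list(NULL, "S1"))
  expect_message(
    calls <- trio_calls(sites, m(c(1, 1)), m(15), m(15), m(30), m(99)),
    "sex-chromosome")
  expect_equal(calls$sites$chrom, "chr1")
})

test_that("caller dropout and jitter degrade CNV concordance as expected", {
  cfg <- sim_config(n_trios = 1, n_cnv_loci = 40, n_cnv_denovo = 2)
  # caller B total dropout: merged set empty
  set.seed(104)
  sim <- simulate_cnv_callsets(cfg, jitter = 0, dropout = c(0, 1))
  expect_equal(nrow(sim$caller_b), 0)
  a <- sim$caller_a[sim$caller_a$sample == "BTQ_C", ]
  expect_gt(nrow(a), 0)
  expect_equal(nrow(merge_callsets(a, sim$caller_b[0, ])), 0)
  # 60%-of-length jitter pushes reciprocal overlap below 50% for most calls
  set.seed(105)
  sim <- simulate_cnv_callsets(cfg, jitter = c(0, 0.6), dropout = 0)
  a <- sim$caller_a[sim$caller_a$sample == "BTQ_C", ]
  b <- sim$caller_b[sim$caller_b$sample == "BTQ_C", ]
  merged <- merge_callsets(a, b)
  expect_lt(nrow(merged), nrow(a))
})

test_that("depth profiles encode planted copy number for re-genotyping", {
  cfg <- sim_config(n_trios = 1, n_cnv_loci = 30, n_cnv_denovo = 3)
  set.seed(106)
  sim <- simulate_cnv_callsets(cfg, jitter = 0, dropout = 0)
  dn <- sim$truth[sim$truth$origin == "denovo", ]
  expect_gt(nrow(dn), 0)
  prof_c <- sim$depth_profiles[sim$depth_profiles$sample == "BTQ_C", ]
  prof_f <- sim$depth_profiles[sim$depth_profiles$sample == "BTQ_F", ]
  for (r in seq_len(nrow(dn))) {
    inside_c <- prof_c$start >= dn$start[r] & prof_c$end <= dn$end[r]
    expect_true(all(prof_c$depth[inside_c] == cfg$depth_mean / 2))
    inside_f <- prof_f$start >= dn$start[r] & prof_f$end <= dn$end[r]
    expect_true(all(prof_f$depth[inside_f] == cfg$depth_mean))
  }
})
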