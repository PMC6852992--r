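cnv_row <- function(start, end, svtype = "DEL", sample = "S1",
                    caller = "caller_A", cn = NA_integer_, chrom = "chr1") {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             svtype = svtype, copy_number = cn, caller = caller,
             stringsAsFactors = FALSE)
}

test_that("CNV loading enforces the 100 bp size floor and copy-number consistency", {
  x <- rbind(cnv_row(0, 100), cnv_row(0, 101), cnv_row(0, 5000, "DUP"))
  expect_message(out <- cnv_calls(x), "dropping 1")  # the 100 bp call
  expect_true(all(out$end - out$start > 100))
  expect_equal(nrow(out), 2)
  expect_error(cnv_calls(cnv_row(0, 5000, "DEL", cn = 3L)), "inconsistent")
  expect_error(cnv_calls(cnv_row(0, 5000, "DUP", cn = 1L)), "inconsistent")
  onX <- cnv_row(0, 5000, chrom = "chrX")
  expect_message(out <- cnv_calls(rbind(x[3, ], onX)), "dropping 1")
  expect_equal(out$chrom, "chr1")
})

test_that("ensemble merge keeps two-caller concordant calls and applies masks", {
  a <- cnv_row(0, 1000)
  b <- cnv_row(0, 1000, caller = "caller_B")
  expect_equal(nrow(merge_callsets(a, b)), 1)
  # single-caller call removed (criterion i)
  expect_equal(nrow(merge_callsets(a, cnv_row(5000, 6000, caller = "caller_B"))), 0)
  # type mismatch is discordant
  expect_equal(nrow(merge_callsets(a, cnv_row(0, 1000, "DUP", caller = "caller_B"))), 0)
  # reciprocal 0.6/0.6 concordant, but segdup mask covers 60% >= 50%
  a2 <- cnv_row(0, 1000); b2 <- cnv_row(400, 1400, caller = "caller_B")
  segdup <- genome_mask("chr1", 0, 600, name = "gapseg")
  expect_equal(nrow(merge_callsets(a2, b2)), 1)
  expect_equal(nrow(merge_callsets(a2, b2, gapseg_mask = segdup)), 0)
  # one-base repeat overlap removes the call (criterion ii)
  rep1 <- genome_mask("chr1", 999, 1200, name = "repeats")
  expect_equal(nrow(merge_callsets(a2, b2, repeat_mask = rep1)), 0)
  # representative interval comes from the preferred caller
  m <- merge_callsets(a2, b2)
  expect_equal(m$start, 0)
  m <- merge_callsets(a2, b2, prefer_caller = "B")
  expect_equal(m$start, 400)
  # mixed samples rejected
  expect_error(merge_callsets(rbind(a, cnv_row(0, 1000, sample = "S2")), b),
               "single sample")
})

test_that("ensemble merge matches a brute-force reference and is idempotent", {
  set.seed(33)
  for (i in 1:50) {
    a <- random_cnv_set(sample(3:12, 1))
    b <- random_cnv_set(sample(3:12, 1))
    b$caller <- "caller_B"
    got <- merge_callsets(a, b)
    want <- merge_brute(a, b)
    expect_equal(got$start, want$start, info = paste("case", i))
    expect_equal(got$end, want$end, info = paste("case", i))
    # idempotence: merging the result with itself changes nothing
    again <- merge_callsets(got, got)
    expect_equal(again, got, ignore_attr = TRUE)
  }
})

test_that("CNV novelty requires < 50% reciprocal overlap with every database record", {
  reg <- cnv_row(0, 1000)
  expect_false(is_novel_cnv(reg, data.frame(chrom = "chr1", start = 0,
                                            end = 1000, svtype = "DEL")))
  expect_true(is_novel_cnv(reg, data.frame(chrom = "chr9", start = 0,
                                           end = 1000, svtype = "DEL")))
  # reciprocal (0.4, 0.4)
  expect_true(is_novel_cnv(reg, data.frame(chrom = "chr1", start = 600,
                                           end = 1600, svtype = "DEL")))
  # any-type matching by default; svtype matching on request
  db_dup <- data.frame(chrom = "chr1", start = 0, end = 1000, svtype = "DUP")
  expect_false(is_novel_cnv(reg, db_dup))
  expect_true(is_novel_cnv(reg, db_dup, match_svtype = TRUE))
})

test_that("de novo CNV detection drops parent-matched and depth-supported calls", {
  child <- cnv_row(1000, 3000, sample = "C")
  dad_match <- cnv_row(1000, 3000, sample = "F")
  none <- cnv_row(900000, 901000, sample = "X")[0, ]
  prof <- function(f_depth, m_depth) rbind(
    data.frame(sample = "F", chrom = "chr1", start = 0, end = 10000,
               depth = f_depth),
    data.frame(sample = "M", chrom = "chr1", start = 0, end = 10000,
               depth = m_depth))
  md <- c(F = 30, M = 30)

  # step (i): matched in father
  dd <- detect_denovo_cnv(child, dad_match, none,
                          depth_profiles = prof(30, 30), mean_depths = md,
                          father_id = "F", mother_id = "M")
  expect_equal(nrow(dd$calls), 0)

  # step (ii): clean parental depth ratios 1.0/1.0 -> de novo
  dd <- detect_denovo_cnv(child, none, none,
                          depth_profiles = prof(30, 30), mean_depths = md,
                          father_id = "F", mother_id = "M")
  expect_equal(nrow(dd$calls), 1)
  expect_true(dd$calls$verified)
  expect_equal(dd$calls$father_cn, 2)

  # step (ii): mother depth ratio 0.5 (CN 1) supports an inherited deletion
  dd <- detect_denovo_cnv(child, none, none,
                          depth_profiles = prof(30, 15), mean_depths = md,
                          father_id = "F", mother_id = "M")
  expect_equal(nrow(dd$calls), 0)
  expect_true(dd$report$removed_step_ii)
  expect_equal(dd$report$mother_cn, 1)

  # no profiles: unverified with a warning
  expect_warning(dd <- detect_denovo_cnv(child, none, none), "unverified")
  expect_equal(nrow(dd$calls), 1)
  expect_false(dd$calls$verified)
})

test_that("emitted de novo CNVs never have a reciprocally matching parental call", {
  set.seed(44)
  for (i in 1:20) {
    child <- random_cnv_set(8, sample = "C")
    dad <- random_cnv_set(8, sample = "F")
    mom <- random_cnv_set(8, sample = "M")
    dd <- suppressWarnings(detect_denovo_cnv(child, dad, mom))
    for (k in seq_len(nrow(dd$calls))) {
      for (par in list(dad, mom)) {
        same <- par[par$svtype == dd$calls$svtype[k], , drop = FALSE]
        if (nrow(same) == 0) next
        ro <- reciprocal_overlap(dd$calls[k, ], same)
        expect_true(all(pmin(ro$frac_a, ro$frac_b) < 0.5))
      }
    }
  }
})

test_that("the CNV rate is de novo over total, reported to one significant digit", {
  expect_equal(estimate_cnv_rate(2, 1754)$rate_reported, 0.001)
  expect_equal(estimate_cnv_rate(1, 2172)$rate_reported, 0.0005)
  expect_equal(estimate_cnv_rate(0, 1000)$rate, 0)
  expect_error(estimate_cnv_rate(1, 0), "positive")
  expect_error(estimate_cnv_rate(5, 4), "exceeds")
})

test_that("sharing classes follow the population precedence rules", {
  pops <- c("BTQ", "MDQ", "SMI", "DSN", "MRT")
  ped <- trio_pedigree(pops, paste0(pops, "_F"), paste0(pops, "_M"),
                       paste0(pops, "_C"), pops)
  pres <- function(...) setNames(pops %in% c(...), pops)
  expect_equal(as.character(classify_sharing(pres("BTQ", "MDQ", "SMI"), ped)), "OA")
  expect_equal(as.character(classify_sharing(pres("BTQ", "DSN"), ped)), "MLS")
  expect_equal(as.character(classify_sharing(pres("MDQ"), ped)), "private")
  expect_equal(as.character(classify_sharing(pres("BTQ", "MDQ"), ped)), "NGO")
  expect_equal(as.character(classify_sharing(pres("DSN", "MRT"), ped)), "NB")
  expect_equal(as.character(classify_sharing(pres("BTQ", "SMI"), ped)), "other")
  # all five populations span both groups
  expect_equal(as.character(classify_sharing(pres("BTQ", "MDQ", "SMI", "DSN", "MRT"), ped)), "MLS")
})

test_that("sharing classification partitions every presence pattern", {
  pops <- c("BTQ", "MDQ", "SMI", "DSN", "MRT")
  ped <- trio_pedigree(pops, paste0(pops, "_F"), paste0(pops, "_M"),
                       paste0(pops, "_C"), pops)
  # all 31 non-empty presence patterns
  pats <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 5)))[-1, ]
  colnames(pats) <- pops
  cls <- classify_sharing(pats, ped)
  expect_equal(length(cls), 31)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 31)
})

test_that("noise-free synthetic CNV callsets are recovered exactly end to end", {
  cfg <- sim_config(n_trios = 2, n_cnv_loci = 60, n_cnv_denovo = 3)
  set.seed(55)
  sim <- simulate_cnv_callsets(cfg, jitter = 0, dropout = 0)
  for (tid in c("BTQ", "MDQ")) {
    ids <- c(F = paste0(tid, "_F"), M = paste0(tid, "_M"), C = paste0(tid, "_C"))
    merged <- lapply(ids, function(s)
      merge_callsets(sim$caller_a[sim$caller_a$sample == s, ],
                     sim$caller_b[sim$caller_b$sample == s, ]))
    # merge recovers exactly the planted per-sample sets
    for (s in ids) {
      planted <- sim$truth[sim$truth$sample == s, ]
      expect_equal(sort(merged[[which(ids == s)]]$start), sort(planted$start))
    }
    dd <- detect_denovo_cnv(merged$C, merged$F, merged$M,
                            depth_profiles = sim$depth_profiles,
                            mean_depths = sim$mean_depths)
    planted_dn <- sim$truth[sim$truth$sample == ids["C"] &
                            sim$truth$origin == "denovo", ]
    # precision = recall = 1 at zero noise
    expect_setequal(dd$calls$start, planted_dn$start)
  }
})

test_that("region clustering assigns trio presence used for sharing", {
  pops <- c("BTQ", "MDQ")
  ped <- trio_pedigree(pops, paste0(pops, "_F"), paste0(pops, "_M"),
                       paste0(pops, "_C"), pops)
  calls <- rbind(cnv_row(0, 1000, sample = "BTQ_C"),
                 cnv_row(10, 1010, sample = "MDQ_F"),
                 cnv_row(50000, 51000, sample = "MDQ_M"))
  rp <- cnv_region_presence(calls, ped)
  expect_equal(nrow(rp$regions), 2)
  shared <- which(rp$regions$start == 0)
  expect_true(all(rp$presence[shared, ]))
  cls <- classify_sharing(rp$presence, ped)
  expect_equal(sum(cls == "private"), 1)
})
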