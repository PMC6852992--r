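test_that("the de novo cascade accepts a textbook candidate and rejects near-misses", {
  trio <- test_trio()
  # clean candidate: child het 15/15 at 30x GQ99, parents hom-ref 30/0
  calls <- make_trio_calls(f_gt = 0, m_gt = 0, c_gt = 1)
  aud <- classify_denovo(calls, trio)
  expect_true(aud$pass)
  expect_equal(as.character(aud$reason), "pass")

  # one stray paternal alt read: criterion iv
  calls <- make_trio_calls(0, 0, 1, f_ad_alt = 2)
  aud <- classify_denovo(calls, trio)
  expect_false(aud$pass)
  expect_equal(as.character(aud$reason), "criterion_iv")

  # child hom-ref (with alt reads in balance, so only v fails)
  aud <- classify_denovo(make_trio_calls(0, 0, 0, c_ad_alt = 12), trio)
  expect_equal(as.character(aud$reason), "criterion_v")

  # allele balance 8/30 = 0.267: criterion ii
  aud <- classify_denovo(make_trio_calls(0, 0, 1, c_ad_alt = 8), trio)
  expect_equal(as.character(aud$reason), "criterion_ii")

  # parental GQ below 50: criterion iii
  aud <- classify_denovo(make_trio_calls(0, 0, 1, f_gq = 49), trio)
  expect_equal(as.character(aud$reason), "criterion_iii")

  # missing member genotype is not evaluable
  aud <- classify_denovo(make_trio_calls(NA, 0, 1), trio)
  expect_equal(as.character(aud$reason), "missing")
})

test_that("masked sites fail criterion i and audit reports the first failure in order", {
  trio <- test_trio()
  mask <- genome_mask("chr1", 0, 5000, name = "excl")
  # site at pos 1000 is masked AND has bad allele balance: reason must be i
  calls <- make_trio_calls(0, 0, 1, c_ad_alt = 8)
  aud <- classify_denovo(calls, trio, masks = list(mask))
  expect_equal(as.character(aud$reason), "criterion_i")
  expect_false(aud$crit_ii)
  # father het fails both iv and v: audit reports iv
  aud <- classify_denovo(make_trio_calls(1, 0, 1), trio)
  expect_equal(as.character(aud$reason), "criterion_iv")
  expect_false(aud$crit_v)
})

test_that("allele-balance bounds are inclusive at 0.3 and 0.7", {
  trio <- test_trio()
  # 9/30 = 0.3 and 21/30 = 0.7 both pass; 8/30 and 22/30 fail
  for (ad in c(9L, 21L))
    expect_true(classify_denovo(make_trio_calls(0, 0, 1, c_ad_alt = ad),
                                trio)$pass)
  for (ad in c(8L, 22L))
    expect_false(classify_denovo(make_trio_calls(0, 0, 1, c_ad_alt = ad),
                                 trio)$pass)
})

test_that("depth bounds 10-120 are inclusive for the offspring", {
  trio <- test_trio()
  ok <- function(dp, ad) classify_denovo(
    make_trio_calls(0, 0, 1, c_dp = dp, c_ad_alt = ad), trio)$pass
  expect_true(ok(10L, 5L))
  expect_true(ok(120L, 60L))
  expect_false(ok(9L, 4L))    # 4/9 = 0.44 in balance, depth too low
  expect_false(ok(121L, 60L))
})

test_that("site callability matches binomial enumeration and gates deterministically", {
  # masked site is never callable
  expect_equal(site_callability(30, 99, 0, 30, 99, 0, 30, masked = TRUE), 0)
  # exact value at child depth 10
  expect_equal(site_callability(30, 99, 0, 30, 99, 0, 10), 0.890625)
  # child depth 30 equals the enumerated binomial sum
  expect_equal(site_callability(30, 99, 0, 30, 99, 0, 30),
               sum(choose(30, 9:21)) / 2^30)
  # full enumeration oracle across the low end of the depth window;
  # below the window the depth gate zeroes the site
  for (d in 10:20)
    expect_equal(site_callability(30, 99, 0, 30, 99, 0, d),
                 ab_prob_brute(d), info = paste("depth", d))
  for (d in 1:9)
    expect_equal(site_callability(30, 99, 0, 30, 99, 0, d), 0)
  # deterministic gates: parental depth, GQ, stray alt reads
  expect_equal(site_callability(9, 99, 0, 30, 99, 0, 30), 0)
  expect_equal(site_callability(30, 49, 0, 30, 99, 0, 30), 0)
  expect_equal(site_callability(30, 99, 1, 30, 99, 0, 30), 0)
  expect_equal(site_callability(30, 99, 0, 30, 99, 0, 130), 0)
  # offspring quality gate applies when supplied
  expect_equal(site_callability(30, 99, 0, 30, 99, 0, 30, child_gq = 20), 0)
  # always a probability
  set.seed(5)
  p <- site_callability(sample(5:150, 200, TRUE), sample(0:99, 200, TRUE),
                        sample(0:2, 200, TRUE), sample(5:150, 200, TRUE),
                        sample(0:99, 200, TRUE), sample(0:2, 200, TRUE),
                        sample(0:150, 200, TRUE))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the rate estimator is count over twice the callability sum", {
  expect_equal(estimate_dnm_rate(0, 2.0e9)$mu, 0)
  expect_equal(estimate_dnm_rate(49, 2.268519e9)$mu, 1.08e-8, tolerance = 1e-3)
  expect_equal(estimate_dnm_rate(10, 1.724e9)$mu, 2.9e-9, tolerance = 1e-3)
  expect_error(estimate_dnm_rate(3, 0), "positive")
  expect_error(estimate_dnm_rate(3, -1), "positive")
})

test_that("no de novo calls arise from error-free Mendelian-consistent data", {
  cfg <- sim_config(n_trios = 1, n_sites = 5e4, chrom_length = 1e7,
                    dnm_rate_snv = 0, dnm_rate_indel = 0, error_rate = 0)
  trio <- test_trio()
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    tab <- simulate_trio_sites(cfg, "snv", positions = FALSE)
    calls <- sim_as_trio_calls(tab)
    aud <- classify_denovo(calls, trio)
    expect_equal(sum(aud$pass), 0, info = paste("seed", seed))
  }
})

test_that("planted de novo events passing the deterministic criteria are all recovered", {
  cfg <- sim_config(n_trios = 1, n_sites = 5e4, chrom_length = 1e7,
                    dnm_rate_snv = 2e-3, error_rate = 0)
  trio <- test_trio()
  set.seed(77)
  tab <- simulate_trio_sites(cfg, "snv", positions = FALSE)
  calls <- sim_as_trio_calls(tab)
  aud <- classify_denovo(calls, trio)
  planted <- which(tab$dnm_paternal | tab$dnm_maternal)
  expect_gt(length(planted), 50)
  # calls must be a subset of planted events (zero sequencing error)
  expect_true(all(which(aud$pass) %in% planted))
  # every planted event satisfying criteria i-iii with hom-ref parents and
  # no parental alt reads must be called
  must_call <- planted[
    aud$crit_i[planted] & aud$crit_ii[planted] & aud$crit_iii[planted] &
    aud$crit_iv[planted] & aud$crit_v[planted]]
  expect_true(all(aud$pass[must_call]))
  expect_gt(length(must_call), 10)
  # and none violating iv or v is called
  bad <- planted[!aud$crit_iv[planted] | !aud$crit_v[planted]]
  expect_true(all(!aud$pass[bad]))
})

test_that("streaming rate trial equals the materialised simulate-classify path", {
  cfg <- sim_config(n_trios = 1, n_sites = 1e5, chrom_length = 1e7,
                    dnm_rate_snv = 1e-4)
  trio <- test_trio()
  for (seed in c(1, 2)) {
    set.seed(seed)
    acc <- simulate_rate_trial(cfg)
    set.seed(seed)
    tab <- simulate_trio_sites(cfg, "snv", positions = FALSE)
    calls <- sim_as_trio_calls(tab)
    aud <- classify_denovo(calls, trio)
    expect_equal(acc[["n_planted"]],
                 sum(tab$dnm_paternal) + sum(tab$dnm_maternal))
    expect_equal(acc[["n_pass"]], sum(aud$pass))
    expect_equal(acc[["callability_sum"]], callability_sum(calls, trio))
  }
})

test_that("per-trio analysis assembles calls and rates by variant type", {
  cfg <- sim_config(n_trios = 2, n_sites = 2e4, n_sites_indel = 5e3,
                    chrom_length = 1e7, dnm_rate_snv = 1e-3,
                    dnm_rate_indel = 1e-3, error_rate = 0)
  set.seed(9)
  coh <- simulate_trio_cohort(cfg)
  res <- denovo_small_analysis(coh$calls, coh$ped)
  expect_equal(nrow(res$rates), 4)  # 2 trios x 2 vtypes
  expect_setequal(unique(res$rates$vtype), c("snv", "indel"))
  expect_true(all(res$rates$mu >= 0))
  expect_true(all(res$calls$pass))
  # every reported call corresponds to a planted truth event
  key <- function(d) paste(d$trio_id, d$pos)
  expect_true(all(key(res$calls) %in% key(coh$truth)))
})
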