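test_that("mapping_bias_filter applies both predicates and catches duplicates", {
  stats <- data.frame(tsnp_id = c("a", "b", "c", "d"),
                      sim_total = c(150, 198, 198, 205),
                      sim_allele_ratio = c(0.50, 0.50, 0.55, 0.50))
  expect_identical(mapping_bias_filter(stats), "b")
  # boundary: deviation exactly 5% is removed (strict <), coverage bounds inclusive
  stats2 <- data.frame(tsnp_id = c("e", "f", "g"),
                       sim_total = c(193, 202, 198),
                       sim_allele_ratio = c(0.5, 0.5, 0.55))
  expect_identical(mapping_bias_filter(stats2), c("e", "f"))
  expect_error(
    mapping_bias_filter(data.frame(tsnp_id = c("a", "a"),
                                   sim_total = c(198, 198),
                                   sim_allele_ratio = c(0.5, 0.5))),
    "duplicate.*a")
})

test_that("mapping_bias_filter matches a brute-force predicate oracle", {
  set.seed(41)
  stats <- data.frame(tsnp_id = sprintf("t%03d", 1:100),
                      sim_total = sample(180:215, 100, replace = TRUE),
                      sim_allele_ratio = runif(100, 0.4, 0.6))
  got <- mapping_bias_filter(stats)
  oracle <- character(0)
  for (i in 1:100) {  # independent re-application, record by record
    if (stats$sim_total[i] >= 193 && stats$sim_total[i] <= 202 &&
        abs(stats$sim_allele_ratio[i] - 0.5) < 0.05)
      oracle <- c(oracle, stats$tsnp_id[i])
  }
  expect_identical(got, oracle)
})

make_counts <- function(tab) {
  # tab: list of per-tSNP data.frames(sample_id, ref, alt)
  do.call(rbind, lapply(names(tab), function(ts) {
    d <- tab[[ts]]
    data.frame(sample_id = d$sample_id, tsnp_id = ts,
               ref_count = d$ref, alt_count = d$alt)
  }))
}

full_het_map <- function(records)
  data.frame(sample_id = records$sample_id, tsnp_id = records$tsnp_id,
             het = TRUE)

test_that("count_filters drops low coverage, sparse tSNPs, mono-allelic tSNPs in order", {
  samples <- sprintf("s%02d", 1:25)
  tab <- list(
    # survives everything
    good = data.frame(sample_id = samples, ref = 20, alt = 18),
    # one observation at 29 reads (dropped) leaves 24 het samples: retained
    low1 = data.frame(sample_id = samples, ref = c(20, rep(20, 24)),
                      alt = c(9, rep(18, 24))),
    # only 19 samples with >= 30 reads: whole tSNP dropped
    sparse = data.frame(sample_id = samples, ref = c(rep(20, 19), rep(5, 6)),
                        alt = c(rep(15, 19), rep(4, 6))),
    # one sample at alt/total = 0.95 -> deviation 0.45 > 0.4: tSNP dropped
    mono = data.frame(sample_id = samples, ref = c(2, rep(20, 24)),
                      alt = c(38, rep(18, 24))))
  rec <- make_counts(tab)
  out <- count_filters(rec, full_het_map(rec))
  expect_setequal(out$tsnps, c("good", "low1"))
  expect_equal(sum(out$records$tsnp_id == "low1"), 24)
  expect_equal(unname(out$log["low_coverage_removed"]), 1 + 6 + 0)
  # a record with total = 0 is dropped at step 1, not an error
  rec0 <- rbind(rec, data.frame(sample_id = "s99", tsnp_id = "good",
                                ref_count = 0, alt_count = 0))
  out0 <- count_filters(rec0, full_het_map(rec0))
  expect_false("s99" %in% out0$records$sample_id)
})

test_that("count_filters equals a brute-force three-step oracle on a random panel", {
  set.seed(42)
  n_ts <- 50
  recs <- do.call(rbind, lapply(seq_len(n_ts), function(j) {
    ns <- sample(15:30, 1)
    tot <- sample(10:80, ns, replace = TRUE)
    frac <- runif(ns, 0.05, 0.95)
    alt <- rbinom(ns, tot, frac)
    data.frame(sample_id = sprintf("s%02d", seq_len(ns)),
               tsnp_id = sprintf("t%02d", j),
               ref_count = tot - alt, alt_count = alt)
  }))
  hm <- full_het_map(recs)
  got <- count_filters(recs, hm)

  # oracle: literal sequential reimplementation
  r <- recs
  r <- r[r$ref_count + r$alt_count >= 30, ]
  cnt <- table(r$tsnp_id)
  r <- r[r$tsnp_id %in% names(cnt)[cnt >= 20], ]
  dev <- abs(0.5 - r$alt_count / (r$ref_count + r$alt_count))
  bad <- unique(r$tsnp_id[dev > 0.4])
  r <- r[!r$tsnp_id %in% bad, ]
  expect_setequal(got$tsnps, unique(r$tsnp_id))
  expect_equal(nrow(got$records), nrow(r))

  # idempotence: reapplying the filter changes nothing
  again <- count_filters(got$records, hm)
  expect_equal(again$records, got$records, ignore_attr = TRUE)

  # monotonicity: a stricter read filter never enlarges the retained set
  strict <- count_filters(recs, hm, qc_config(min_reads_per_obs = 40))
  key <- function(d) paste(d$sample_id, d$tsnp_id)
  expect_true(all(key(strict$records) %in% key(got$records)))

  # provenance: counts balance
  lg <- got$log
  expect_equal(unname(lg["input"] - lg["non_het_removed"] -
                        lg["low_coverage_removed"]) -
                 unname(lg["retained_records"]) >= 0, TRUE)
})

test_that("test_eligibility enforces 15/15 and dichotomous cell minimums", {
  g <- function(nhet, nhom) c(rep("het", nhet), rep("hom-ref", nhom))
  e_cont <- function(n) rnorm(n)
  set.seed(1)
  r <- test_eligibility(g(14, 200), e_cont(214), "continuous")
  expect_false(r$eligible); expect_equal(r$reason, "het<15")
  r <- test_eligibility(g(15, 15), e_cont(30), "continuous")
  expect_true(r$eligible)
  # dichotomous with one cell of 4
  geno <- c(rep("het", 100), rep("hom-alt", 100))
  env <- c(rep(1, 96), rep(0, 4), rep(0, 50), rep(1, 50))
  r <- test_eligibility(geno, env, "dichotomous")
  expect_false(r$eligible); expect_equal(r$reason, "group<5")
  # missing env removed before counting; both homozygote classes pooled
  geno2 <- c(rep("het", 16), rep("hom-ref", 8), rep("hom-alt", 8))
  env2 <- c(NA, NA, rnorm(30))
  r <- test_eligibility(geno2, env2, "continuous")
  expect_false(r$eligible)  # 14 het after NA removal
  expect_error(test_eligibility(g(20, 20), rep(NA_real_, 40), "continuous"),
               "non-missing")
  # dosage input accepted
  r <- test_eligibility(c(rep(1, 15), rep(0, 10), rep(2, 5)), e_cont(30),
                        "continuous")
  expect_true(r$eligible)
})
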