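test_that("hard-filter boundaries are inclusive on the passing side", {
  # all metrics exactly at their thresholds, mean depth = cohort mean
  boundary <- make_candidate(overrides = list(
    qd = 2, fs = 60, mq_rank_sum = -12.5, read_pos_rank_sum = -8,
    mq = 40, sor = 3))
  res <- apply_hard_filters(boundary)
  expect_equal(nrow(res$survivors$info), 1)
  expect_true(all(res$removals == 0))

  # each single violation is removed and attributed to its own rule
  viols <- list(qd = 1.5, fs = 60.01, mq_rank_sum = -12.6,
                read_pos_rank_sum = -8.5, mq = 39.9, sor = 3.5)
  for (rule in names(viols)) {
    cand <- make_candidate(overrides = viols[rule])
    res <- apply_hard_filters(cand)
    expect_equal(nrow(res$survivors$info), 0, label = rule)
    expect_equal(unname(res$removals[rule]), 1L, label = rule)
    expect_equal(sum(res$removals), 1L, label = rule)
  }

  # non-finite metric => removed with missing_qc, never a silent pass
  cand <- make_candidate(overrides = list(qd = NA_real_))
  res <- apply_hard_filters(cand)
  expect_equal(unname(res$removals["missing_qc"]), 1L)

  # empty input => empty output, zero counts
  empty <- apply_hard_filters(
    candidate_set(make_candidate()$info[0, ], matrix(0L, 0, 2),
                  matrix(0L, 0, 2), c("S1", "S2")))
  expect_equal(nrow(empty$survivors$info), 0)
  expect_true(all(empty$removals == 0))
})

test_that("hard-filter survivors equal the per-rule brute-force oracle", {
  rc <- random_candidates(1000, rate = 0.05, seed = 2)
  res <- apply_hard_filters(rc$cand)
  info <- rc$cand$info
  cm <- mean(rowMeans(rc$cand$dp))
  md <- rowMeans(rc$cand$dp)
  oracle_keep <- info$qd >= 2 & info$fs <= 60 & info$mq_rank_sum >= -12.5 &
    info$read_pos_rank_sum >= -8 & info$mq >= 40 & info$sor <= 3 &
    md >= cm / 3 & md <= 3 * cm
  expect_setequal(res$survivors$info$pos, info$pos[oracle_keep])
  # attribution counts partition the removals
  expect_equal(sum(res$removals), sum(!oracle_keep))
})

test_that("hard filtering is idempotent", {
  rc <- random_candidates(500, rate = 0.1, seed = 4)
  once <- apply_hard_filters(rc$cand)
  twice <- apply_hard_filters(once$survivors)
  expect_equal(twice$survivors$info, once$survivors$info)
  expect_true(all(twice$removals == 0))
})

test_that("editing frequency matches the rational oracle exhaustively", {
  for (d in 1:20) {
    a <- 0:d
    expect_equal(editing_frequency(a, rep(d, d + 1)), a / d)
  }
  expect_equal(editing_frequency(10, 10), 1.0)
  expect_true(is.na(editing_frequency(0, 0)))
  expect_error(editing_frequency(5, 3), "exceed")
  expect_error(editing_frequency(-1, 3), "non-negative")
})

test_that("editing filters implement the per-sample validity window", {
  # depth 10, alt 3 -> freq 0.30, valid
  c1 <- make_candidate(dp = 10L, ad = 3L)
  r1 <- apply_editing_filters(c1)
  expect_equal(nrow(r1$sites$sites), 1)
  expect_equal(unname(r1$sites$freq[1, 1]), 0.30)
  expect_true(all(r1$sites$valid))

  # alt 0 -> frequency 0 < 0.10 -> invalid everywhere -> site dropped
  c2 <- make_candidate(dp = 10L, ad = 0L)
  r2 <- apply_editing_filters(c2)
  expect_equal(nrow(r2$sites$sites), 0)
  expect_equal(unname(r2$removals["no_valid_sample"]), 1L)

  # frequency 1.0 is inside the window (upper bound inclusive)
  c3 <- make_candidate(dp = 12L, ad = 12L)
  expect_equal(nrow(apply_editing_filters(c3)$sites$sites), 1)

  # tri-allelic candidates are rejected regardless of depths
  c4 <- make_candidate(dp = 50L, ad = 20L,
                       overrides = list(alt = "G,T", n_alt = 2L))
  r4 <- apply_editing_filters(c4)
  expect_equal(nrow(r4$sites$sites), 0)
  expect_equal(unname(r4$removals["multiallelic"]), 1L)

  # base quality below 25 is rejected
  c5 <- make_candidate(overrides = list(base_quality = 24.9))
  expect_equal(unname(apply_editing_filters(c5)$removals["base_quality"]), 1L)

  # known-SNP exclusion
  c6 <- make_candidate()
  r6 <- apply_editing_filters(
    c6, known_snps = data.frame(contig = "chrS", pos = 100L))
  expect_equal(unname(r6$removals["known_snp"]), 1L)

  # mixed per-sample validity: only valid measurements carry a frequency
  c7 <- candidate_set(make_candidate()$info,
                      dp = matrix(c(20L, 4L, 20L, 20L), 1),
                      ad = matrix(c(6L, 2L, 2L, 1L), 1),
                      paste0("S", 1:4))
  r7 <- apply_editing_filters(c7)
  expect_equal(unname(r7$sites$valid[1, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(r7$sites$freq[1, ]), c(0.3, NA, NA, NA))
})

test_that("editing filtering is idempotent on the surviving set", {
  rc <- random_candidates(300, rate = 0.05, seed = 6)
  s1 <- apply_editing_filters(apply_hard_filters(rc$cand)$survivors)
  # rebuild a candidate_set from survivors and re-filter
  surv_info <- cbind(s1$sites$sites, n_alt = 1L,
                     qd = 10, fs = 1, mq_rank_sum = 0, read_pos_rank_sum = 0,
                     mq = 55, sor = 1)
  cand2 <- candidate_set(surv_info, s1$sites$dp, s1$sites$ad,
                         s1$sites$samples)
  s2 <- apply_editing_filters(cand2)
  expect_equal(s2$sites$sites$pos, s1$sites$sites$pos)
  expect_equal(s2$sites$freq, s1$sites$freq)
})

test_that("true editing sites survive discovery with corruption off", {
  big <- clean_big_study()
  sim <- big$sim
  snps <- sim$truth$sites[sim$truth$sites$status == "SNP", c("contig", "pos")]
  disc <- discover_editing_sites(sim$candidates, known_snps = snps)
  found <- paste(disc$sites$sites$contig, disc$sites$sites$pos)
  tr <- sim$truth$sites
  true_edit <- tr[tr$status == "editing", ]
  recall <- mean(paste(true_edit$contig, true_edit$pos) %in% found)
  expect_gte(recall, 0.95)
  # and no germline SNP slipped through
  expect_false(any(paste(snps$contig, snps$pos) %in% found))
})

test_that("VCF round trip preserves the candidate set", {
  st <- default_study()
  cand <- st$sim$candidates
  f <- tempfile(fileext = ".vcf")
  write_candidate_vcf(cand, f)
  back <- read_candidate_vcf(f)
  expect_equal(back$info$pos, cand$info$pos)
  expect_equal(back$info$alt, cand$info$alt)
  expect_equal(back$info$qd, cand$info$qd, tolerance = 1e-4)
  expect_equal(back$info$sor, cand$info$sor, tolerance = 1e-4)
  expect_equal(unname(back$dp), unname(cand$dp))
  expect_equal(unname(back$ad), unname(cand$ad))
  expect_equal(back$samples, cand$samples)
  unlink(f)
})

test_that("editing-sites TSV round trips", {
  st <- default_study()
  disc <- discover_editing_sites(st$sim$candidates)
  f <- tempfile(fileext = ".tsv")
  write_editing_sites(disc$sites, f)
  back <- read_editing_sites(f)
  expect_equal(back$sites$pos, disc$sites$sites$pos)
  expect_equal(back$freq, disc$sites$freq, tolerance = 1e-6)
  expect_equal(back$valid, disc$sites$valid)
  unlink(f)
})
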