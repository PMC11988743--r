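two_group_design <- function(n_per = 3) {
  design_table(c(paste0("CON_", 1:n_per), paste0("LPS_", 1:n_per)),
               rep(c("CON", "LPS"), each = n_per))
}

test_that("size factors follow median-of-ratios with geometric-mean-1 scaling", {
  m <- matrix(c(10, 20, 5, 10, 20, 5), 3, 2,
              dimnames = list(NULL, c("A", "B")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # sample B = 2x sample A everywhere -> factor ratio exactly 2
  m2 <- cbind(A = c(10, 20, 5), B = c(20, 40, 10))
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # scale invariance on random matrices: scaling one sample by c scales its
  # factor by c (after the common geometric-mean renormalization)
  set.seed(8)
  for (k in 1:10) {
    m3 <- matrix(rpois(60, 50) + 1, 10, 6)
    c0 <- runif(1, 0.5, 4)
    m4 <- m3; m4[, 3] <- m4[, 3] * c0
    r1 <- size_factors(m3); r2 <- size_factors(m4)
    expect_equal(r2[3] / r1[3] / (r2[1] / r1[1]), c0, tolerance = 1e-10)
  }
  expect_warning(size_factors(matrix(c(0, 5, 3, 0), 2, 2)), "library-size")
})

test_that("dispersion estimation recovers known limits", {
  d <- two_group_design(25)
  # Poisson limit: alpha -> 0
  set.seed(31)
  cp <- matrix(rpois(200 * 50, 500), 200, 50,
               dimnames = list(NULL, d$sample_id))
  ap <- estimate_dispersion(cp, d, moderation = 0)
  expect_lt(mean(ap), 0.05)
  # NB alpha = 0.2 recovery at depth 1000, n = 50
  cn <- matrix(rnbinom(200 * 50, mu = 1000, size = 5), 200, 50,
               dimnames = list(NULL, d$sample_id))
  an <- estimate_dispersion(cn, d, moderation = 0)
  expect_gt(mean(an), 0.1); expect_lt(mean(an), 0.3)
  # constant counts: variance 0 -> floored
  cc <- matrix(100, 5, 50, dimnames = list(NULL, d$sample_id))
  expect_equal(unname(estimate_dispersion(cc, d)), rep(1e-8, 5))
  # all-zero feature untestable -> NA
  cz <- rbind(cc, 0)
  expect_true(is.na(estimate_dispersion(cz, d)[6]))
})

test_that("all-zero features are excluded from testing", {
  d <- two_group_design(3)
  m <- rbind(a = c(5, 6, 7, 5, 6, 7), b = 0)
  colnames(m) <- d$sample_id
  res <- nb_wald_test(m, d)
  expect_equal(res$note[res$feature == "b"], "all_zero")
  expect_true(is.na(res$p_value[res$feature == "b"]))
  expect_false(is.na(res$p_value[res$feature == "a"]))
})

test_that("symmetric null gives log2fc 0 and p ~ 1", {
  d <- two_group_design(3)
  m <- matrix(rep(c(8, 12, 10), 2), 1, dimnames = list("g", d$sample_id))
  res <- nb_wald_test(m, d)
  expect_equal(res$log2fc, 0, tolerance = 1e-6)
  expect_gt(res$p_value, 0.99)
})

test_that("Wald engine is calibrated and recovers known effects", {
  d <- two_group_design(3)
  set.seed(17)
  # reduced-size null calibration (the full 2000-gene version runs in the
  # acceptance suite)
  null_counts <- matrix(rnbinom(600 * 6, mu = 200, size = 10), 600, 6,
                        dimnames = list(NULL, d$sample_id))
  res <- nb_wald_test(null_counts, d)
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02); expect_lt(frac, 0.08)
  # effect recovery at true log2fc = 2 for 10% of genes (median-of-ratios
  # needs a majority-null background to be identifiable)
  mu <- matrix(200, 300, 6)
  mu[1:30, 4:6] <- 800
  eff <- matrix(rnbinom(300 * 6, mu = as.vector(mu), size = 10), 300, 6,
                dimnames = list(NULL, d$sample_id))
  res2 <- nb_wald_test(eff, d)
  expect_lt(abs(mean(res2$log2fc[1:30]) - 2), 0.3)
  expect_lt(abs(mean(res2$log2fc[31:300])), 0.1)
})

test_that("group-label swap negates log2fc and preserves p-values", {
  set.seed(23)
  d <- two_group_design(3)
  counts <- matrix(rnbinom(120 * 6, mu = 150, size = 8), 120, 6,
                   dimnames = list(NULL, d$sample_id))
  a <- nb_wald_test(counts, d, treatment = "LPS")
  b <- nb_wald_test(counts, d, treatment = "CON")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
})

test_that("uniform count scaling is absorbed by normalization", {
  # first-order property: in a true NB model an exact p-invariance under
  # counts*c is impossible (deeper counts genuinely carry more information),
  # so log2fc is compared tightly and p loosely
  set.seed(29)
  d <- two_group_design(3)
  counts <- matrix(rnbinom(80 * 6, mu = 150, size = 8), 80, 6,
                   dimnames = list(NULL, d$sample_id))
  a <- nb_wald_test(counts, d, alpha = rep(0.1, 80))
  b <- nb_wald_test(counts * 3L, d, alpha = rep(0.1, 80))
  expect_equal(a$log2fc, b$log2fc, tolerance = 1e-3)
  expect_lt(max(abs(a$p_value - b$p_value)), 0.02)
  expect_equal(unname(size_factors(counts)), unname(size_factors(counts * 3L)),
               tolerance = 1e-12)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # reference step-up oracle, written out
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(1, adj); out
  }
  set.seed(41)
  for (k in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  # NA passthrough
  p <- c(0.01, NA, 0.5)
  out <- bh_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(c(0.01, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene aggregation equals a brute-force triple loop", {
  st <- default_study()
  snps <- st$sim$truth$sites[st$sim$truth$sites$status == "SNP",
                             c("contig", "pos")]
  disc <- discover_editing_sites(st$sim$candidates, known_snps = snps)
  es <- disc$sites
  ann <- annotate_sites(es, st$models)
  agg <- aggregate_gene_editing(es, annotation = ann)
  # brute force: for every gene, sample, site
  genes <- sort(unique(ann$gene_id[!is.na(ann$gene_id)]))
  expect_equal(rownames(agg), genes)
  for (g in genes[seq(1, length(genes), by = 7)]) {
    for (s in es$samples) {
      total <- 0
      for (i in seq_len(nrow(es$sites))) {
        if (!is.na(ann$gene_id[i]) && ann$gene_id[i] == g &&
            es$valid[i, s]) total <- total + es$ad[i, s]
      }
      expect_equal(unname(agg[g, s]), as.integer(total),
                   label = paste(g, s))
    }
  }
  # genes with no surviving sites are absent
  expect_true(all(rownames(agg) %in% ann$gene_id))
  # gene with two sites, alt depths 3 and 5 -> 8
  df <- data.frame(contig = "chrS", pos = c(1300L, 1490L), ref = "A",
                   alt = "G", base_quality = 35)
  es2 <- make_sites(df, matrix(20L, 2, 1), matrix(c(3L, 5L), 2, 1), "S1")
  agg2 <- aggregate_gene_editing(es2, toy_models())
  expect_equal(unname(agg2["gplus", "S1"]), 8L)
})

test_that("differential wrappers apply the documented significance rules", {
  set.seed(53)
  d <- two_group_design(3)
  counts <- rbind(
    flat = rnbinom(6, mu = 200, size = 20),
    up = c(rnbinom(3, mu = 50, size = 20), rnbinom(3, mu = 800, size = 20)))
  colnames(counts) <- d$sample_id
  res <- differential_expression(counts, d)
  expect_true("significant" %in% names(res))
  # |log2fc| >= 1 is required for expression significance
  weak <- rbind(a = c(100, 110, 90, 130, 125, 135) * 10L)
  colnames(weak) <- d$sample_id
  res2 <- differential_expression(weak, d)
  expect_true(all(abs(res2$log2fc[res2$significant]) >= 1))
})
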