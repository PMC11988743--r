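# Shared fixture builders. Everything is generated in code; larger simulated
# studies are cached per test run so multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A hand-built candidate_set with fully controlled metrics. `overrides` is a
# named list applied to the single-row info defaults.
make_candidate <- function(n_samples = 4, dp = 20L, ad = 6L,
                           overrides = list()) {
  info <- data.frame(contig = "chrS", pos = 100L, ref = "A", alt = "G",
                     qd = 10, fs = 5, mq_rank_sum = 0, read_pos_rank_sum = 0,
                     mq = 55, sor = 1, base_quality = 35, n_alt = 1L,
                     stringsAsFactors = FALSE)
  for (k in names(overrides)) info[[k]] <- overrides[[k]]
  samples <- paste0("S", seq_len(n_samples))
  candidate_set(info,
                matrix(dp, 1, n_samples),
                matrix(ad, 1, n_samples), samples)
}

# Bind single-row candidates into one set
bind_candidates <- function(...) {
  xs <- list(...)
  candidate_set(do.call(rbind, lapply(xs, `[[`, "info")),
                do.call(rbind, lapply(xs, `[[`, "dp")),
                do.call(rbind, lapply(xs, `[[`, "ad")),
                xs[[1]]$samples)
}

# Random candidate set with independently corrupted QC metrics, plus the
# per-rule violation truth, for filter-cascade oracles.
random_candidates <- function(n, n_samples = 6, rate = 0.05, seed = 1,
                              mean_depth = 100) {
  set.seed(seed)
  draw <- function(lo_ok, hi_ok, lo_bad, hi_bad, bad) {
    ifelse(bad, runif(n, lo_bad, hi_bad), runif(n, lo_ok, hi_ok))
  }
  bad <- replicate(7, runif(n) < rate)
  colnames(bad) <- c("qd", "fs", "mq_rank_sum", "read_pos_rank_sum",
                     "mq", "sor", "depth_window")
  dp <- matrix(rnbinom(n * n_samples, mu = mean_depth, size = 10),
               n, n_samples)
  dp[bad[, "depth_window"], ] <-
    dp[bad[, "depth_window"], , drop = FALSE] * 10L
  ad <- matrix(rbinom(n * n_samples, as.vector(dp), 0.3), n, n_samples)
  info <- data.frame(
    contig = "chrS", pos = seq_len(n), ref = "A", alt = "G",
    qd = draw(5, 30, 0, 1.99, bad[, "qd"]),
    fs = draw(0, 20, 60.01, 100, bad[, "fs"]),
    mq_rank_sum = draw(-2, 2, -20, -12.51, bad[, "mq_rank_sum"]),
    read_pos_rank_sum = draw(-2, 2, -15, -8.01, bad[, "read_pos_rank_sum"]),
    mq = draw(50, 60, 10, 39.99, bad[, "mq"]),
    sor = draw(0.5, 2, 3.01, 9, bad[, "sor"]),
    base_quality = 35, n_alt = 1L, stringsAsFactors = FALSE)
  list(cand = candidate_set(info, dp, ad, paste0("S", seq_len(n_samples))),
       violations = bad)
}

# A tiny hand-constructed gene-model set on a known sequence, for region and
# consequence tests. Layout on a 3000 bp contig (all 1-based inclusive):
#   plus-strand coding gene "gplus": 1201..1660
#     exon1 1201..1380, intron 1381..1480, exon2 1481..1660
#     CDS (240 nt) = 1261..1380 + 1481..1600
#     UTR5 1201..1260, UTR3 1601..1660
#   ncRNA gene "gnc": 3001..3200, exons 3001..3050 and 3151..3200
toy_models <- function(cds_seq = NULL) {
  set.seed(99)
  if (is.null(cds_seq)) {
    body <- c("AAA", "CCA", "GGA", "TTA", "GCT", "CGT")
    cds_seq <- paste0("ATG", paste(rep(body, length.out = 78),
                                   collapse = ""), "TAA")
  }
  stopifnot(nchar(cds_seq) == 240)
  part1 <- substr(cds_seq, 1, 120)
  part2 <- substr(cds_seq, 121, 240)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  contig <- paste0(rand(1200),          # intergenic / upstream space
                   rand(60),            # UTR5 1201..1260
                   part1,               # CDS part 1  1261..1380
                   rand(100),           # intron 1381..1480
                   part2,               # CDS part 2  1481..1600
                   rand(60),            # UTR3 1601..1660
                   rand(1340),          # 1661..3000
                   rand(200),           # gnc 3001..3200
                   rand(400))           # tail to 3600
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "chrS"
  gr <- function(s, e, strand, gid) {
    GenomicRanges::GRanges("chrS", IRanges::IRanges(s, e), strand = strand,
                           gene_id = gid)
  }
  genes <- c(gr(1201, 1660, "+", "gplus"), gr(3001, 3200, "+", "gnc"))
  S4Vectors::mcols(genes)$gene_type <- c("protein_coding", "ncRNA")
  exons <- c(gr(1201, 1380, "+", "gplus"), gr(1481, 1660, "+", "gplus"),
             gr(3001, 3050, "+", "gnc"), gr(3151, 3200, "+", "gnc"))
  cds <- c(gr(1261, 1380, "+", "gplus"), gr(1481, 1600, "+", "gplus"))
  gt <- data.frame(gene_id = c("gplus", "gnc"),
                   start = c(1201, 3001), end = c(1660, 3200),
                   strand = "+", tx_length = c(360L, 100L),
                   cds_length = c(240L, NA_integer_),
                   stringsAsFactors = FALSE)
  structure(list(genome = genome, genes = genes, exons = exons, cds = cds,
                 gene_table = gt), class = "gene_models")
}

# an editing_sites object straight from matrices (all measurements valid
# unless freq is NA)
make_sites <- function(df, dp, ad, samples) {
  freq <- ifelse(dp > 0, ad / dp, NA_real_)
  editing_sites(df, dp, ad, freq, !is.na(freq), samples)
}

# default synthetic study used by several files (medium size)
default_study <- function() {
  cached("default_study", function() {
    cfg <- simulation_config(n_genes = 150, seed = 11)
    models <- simulate_reference(cfg)
    sim <- simulate_candidates(cfg, models)
    expr <- simulate_expression(cfg, models, sim$truth)
    list(cfg = cfg, models = models, sim = sim, expr = expr)
  })
}

# large clean study: no QC corruption, used for recall / calibration tests
clean_big_study <- function() {
  cached("clean_big_study", function() {
    cfg <- simulation_config(n_genes = 400, editing_sites_per_gene = 25,
                             qc_violation_rate = 0, bq_violation_rate = 0,
                             multiallelic_rate = 0, frac_diff_edited_genes = 0,
                             frac_de_genes = 0, seed = 5)
    models <- simulate_reference(cfg)
    sim <- simulate_candidates(cfg, models)
    list(cfg = cfg, models = models, sim = sim)
  })
}
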