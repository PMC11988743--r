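#' Candidate-set container
#'
#' A light S3 container for variant candidates: an `info` data.frame
#' (contig, pos, ref, alt [comma-separated if multiallelic], QC metrics,
#' mean alt base quality) plus per-sample depth (`dp`) and first-alt depth
#' (`ad`) integer matrices, rows parallel to `info`.
#'
#' @param info data.frame of site-level fields
#' @param dp,ad integer matrices, sites x samples
#' @param samples character vector of sample ids (column order of dp/ad)
#' @return object of class `candidate_set`
#' @export
candidate_set <- function(info, dp, ad, samples) {
  stopifnot(nrow(info) == nrow(dp), nrow(info) == nrow(ad),
            ncol(dp) == length(samples), ncol(ad) == length(samples))
  if (any(ad > dp)) stop("alt depth exceeds total depth")
  colnames(dp) <- colnames(ad) <- samples
  structure(list(info = info, dp = dp, ad = ad, samples = samples),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", nrow(x$info), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# passing / violating QC-metric draws per hard-filter rule
qc_draw <- function(n, rule, violate) {
  ok <- list(
    qd = function(n) runif(n, 5, 30),
    fs = function(n) runif(n, 0, 20),
    mq_rank_sum = function(n) rnorm(n, 0, 1),
    read_pos_rank_sum = function(n) rnorm(n, 0, 1),
    mq = function(n) runif(n, 50, 60),
    sor = function(n) runif(n, 0.5, 2.0))
  bad <- list(
    qd = function(n) runif(n, 0, 1.9),
    fs = function(n) runif(n, 61, 120),
    mq_rank_sum = function(n) runif(n, -20, -12.6),
    read_pos_rank_sum = function(n) runif(n, -15, -8.1),
    mq = function(n) runif(n, 10, 39.5),
    sor = function(n) runif(n, 3.1, 9))
  out <- ok[[rule]](n)
  if (any(violate)) out[violate] <- bad[[rule]](sum(violate))
  out
}

#' Simulate variant candidates and the ground-truth table
#'
#' Draws true editing sites inside gene exons (A>G and C>T sense-strand
#' mismatches dominating per the configured type probabilities), germline-SNP
#' confounders at allele frequency ~0.5 or 1.0 in every sample, NB-distributed
#' per-sample coverage, binomial alt counts at the group-specific true
#' frequency, and QC metrics corrupted independently per hard-filter rule at
#' the configured rate. Differentially edited genes receive a
#' `editing_effect_log2fc` frequency shift in the LPS group; enzyme-linked
#' target genes instead take per-sample frequencies from the linear
#' enzyme-expression link.
#'
#' @param config a [simulation_config()]
#' @param models `gene_models` from [simulate_reference()]
#' @return list with `candidates` (a [candidate_set()]), `truth` (list of
#'   data.frames `sites`, `genes`, `enzyme`; see Details) and `design`
#'   (sample/group table)
#' @details `truth$sites` has one row per emitted candidate: status
#'   (editing/SNP), true CON/LPS frequencies and per-rule QC violation flags.
#'   `truth$genes` has per-gene differential-editing and DE flags with
#'   direction. `truth$enzyme` records the enzyme gene id, its per-sample
#'   true scaled expression and each target gene's true per-sample MAF.
#' @export
simulate_candidates <- function(config, models) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(models, "gene_models"))
  set.seed(stage_seed(config, "candidates"))
  cfg <- config
  n_per <- cfg$n_samples_per_group
  samples <- c(paste0("CON_", seq_len(n_per)), paste0("LPS_", seq_len(n_per)))
  group <- rep(c("CON", "LPS"), each = n_per)
  design <- design_table(samples, group)
  gt <- models$gene_table
  ng <- nrow(gt)

  ## per-gene truth flags -----------------------------------------------
  genes_truth <- data.frame(gene_id = gt$gene_id,
                            diff_edited = rep(FALSE, ng),
                            edit_direction = rep(NA_character_, ng),
                            de = rep(FALSE, ng),
                            de_direction = rep(NA_character_, ng),
                            enzyme = rep(FALSE, ng),
                            enzyme_target = rep(FALSE, ng),
                            stringsAsFactors = FALSE)
  enzyme_truth <- NULL
  if (ng > 0) {
    n_enz_tgt <- min(cfg$n_enzyme_targets, max(ng - 1, 0))
    enzyme_idx <- integer(0); target_idx <- integer(0)
    if (n_enz_tgt > 0 && ng >= 2) {
      picks <- sample(ng, 1 + n_enz_tgt)
      enzyme_idx <- picks[1]; target_idx <- picks[-1]
      genes_truth$enzyme[enzyme_idx] <- TRUE
      genes_truth$enzyme_target[target_idx] <- TRUE
    }
    free <- setdiff(seq_len(ng), c(enzyme_idx, target_idx))
    n_dre <- round(cfg$frac_diff_edited_genes * ng)
    n_dre <- max(0, n_dre - length(target_idx))  # targets are already DRE
    dre_idx <- if (n_dre > 0) sample(free, min(n_dre, length(free))) else integer(0)
    genes_truth$diff_edited[dre_idx] <- TRUE
    genes_truth$edit_direction[dre_idx] <-
      sample(c("up", "down"), length(dre_idx), replace = TRUE)
    genes_truth$diff_edited[target_idx] <- TRUE
    genes_truth$edit_direction[target_idx] <- "up"
    n_de <- round(cfg$frac_de_genes * ng)
    n_de <- max(0, n_de - length(enzyme_idx))
    de_pool <- setdiff(seq_len(ng), enzyme_idx)
    de_idx <- if (n_de > 0) sample(de_pool, min(n_de, length(de_pool))) else integer(0)
    genes_truth$de[de_idx] <- TRUE
    genes_truth$de_direction[de_idx] <-
      sample(c("up", "down"), length(de_idx), replace = TRUE)
    genes_truth$de[enzyme_idx] <- TRUE
    genes_truth$de_direction[enzyme_idx] <- "up"

    ## enzyme per-sample true expression and target MAF link -------------
    enz_expr <- rlnorm(2 * n_per, meanlog = 0, sdlog = 0.25) *
      ifelse(group == "LPS", 2^cfg$expression_effect_log2fc, 1)
    enz_scaled <- enz_expr / mean(enz_expr)
    enzyme_truth <- list(
      enzyme_gene = if (length(enzyme_idx)) gt$gene_id[enzyme_idx] else NA_character_,
      target_genes = gt$gene_id[target_idx],
      samples = samples,
      enzyme_scaled_expression = enz_scaled,
      target_maf = NULL)
    if (length(target_idx)) {
      maf <- sapply(gt$gene_id[target_idx], function(g) {
        pmin(pmax(cfg$enzyme_link_intercept +
                    cfg$enzyme_link_slope * enz_scaled +
                    rnorm(length(enz_scaled), 0, cfg$enzyme_link_noise_sd),
                  0.02), cfg$freq_clamp)
      })
      enzyme_truth$target_maf <- matrix(maf, nrow = length(enz_scaled),
                                        dimnames = list(samples,
                                                        gt$gene_id[target_idx]))
    }
  }

  ## site placement ------------------------------------------------------
  genome_chars <- strsplit(as.character(models$genome[[1]]), "")[[1]]
  site_rows <- list()
  used_pos <- integer(0)
  for (i in seq_len(ng)) {
    n_sites <- rpois(1, cfg$editing_sites_per_gene)
    if (n_sites == 0) next
    ex <- models$exons[S4Vectors::mcols(models$exons)$gene_id == gt$gene_id[i]]
    pos_pool <- unlist(lapply(seq_along(ex), function(k)
      seq(GenomicRanges::start(ex)[k], GenomicRanges::end(ex)[k])))
    strand <- gt$strand[i]
    u <- runif(n_sites)
    cls <- ifelse(u < cfg$type_prob_a2i, "a2i",
                  ifelse(u < cfg$type_prob_a2i + cfg$type_prob_c2u, "c2u",
                         "other"))
    for (s in seq_len(n_sites)) {
      if (cls[s] == "a2i") { sense_ref <- "A"; sense_alt <- "G" }
      else if (cls[s] == "c2u") { sense_ref <- "C"; sense_alt <- "T" }
      else {
        repeat {
          sense_ref <- sample(c("A", "C", "G", "T"), 1)
          sense_alt <- sample(setdiff(c("A", "C", "G", "T"), sense_ref), 1)
          if (!(sense_ref == "A" && sense_alt == "G") &&
              !(sense_ref == "C" && sense_alt == "T")) break
        }
      }
      gref <- if (strand == "+") sense_ref else COMPLEMENT[[sense_ref]]
      galt <- if (strand == "+") sense_alt else COMPLEMENT[[sense_alt]]
      cand_pos <- pos_pool[genome_chars[pos_pool] == gref]
      cand_pos <- cand_pos[!cand_pos %in% used_pos]
      if (length(cand_pos) == 0) next
      pos <- if (length(cand_pos) == 1) cand_pos else sample(cand_pos, 1)
      used_pos <- c(used_pos, pos)
      site_rows[[length(site_rows) + 1]] <- data.frame(
        gene_id = gt$gene_id[i], pos = pos, ref = gref, alt = galt,
        status = "editing", stringsAsFactors = FALSE)
    }
  }
  n_edit <- length(site_rows)

  ## germline-SNP confounders -------------------------------------------
  n_snp <- if (cfg$frac_germline_snps > 0 && cfg$frac_germline_snps < 1)
    round(cfg$frac_germline_snps / (1 - cfg$frac_germline_snps) * n_edit)
  else 0
  if (n_snp > 0 && ng > 0) {
    used <- used_pos
    gidx <- sample(ng, n_snp, replace = TRUE)
    for (k in seq_len(n_snp)) {
      i <- gidx[k]
      pos_pool <- seq(gt$start[i], gt$end[i])
      pos_pool <- setdiff(pos_pool, used)
      if (!length(pos_pool)) next
      pos <- if (length(pos_pool) == 1) pos_pool else sample(pos_pool, 1)
      used <- c(used, pos)
      gref <- genome_chars[pos]
      galt <- sample(setdiff(c("A", "C", "G", "T"), gref), 1)
      site_rows[[length(site_rows) + 1]] <- data.frame(
        gene_id = gt$gene_id[i], pos = pos, ref = gref, alt = galt,
        status = "SNP", stringsAsFactors = FALSE)
    }
  }

  if (!length(site_rows)) {
    empty <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character())
    cand <- candidate_set(
      cbind(empty, qd = numeric(0), fs = numeric(0),
            mq_rank_sum = numeric(0), read_pos_rank_sum = numeric(0),
            mq = numeric(0), sor = numeric(0), base_quality = numeric(0),
            n_alt = integer(0)),
      matrix(0L, 0, length(samples)), matrix(0L, 0, length(samples)), samples)
    return(list(candidates = cand,
                truth = list(sites = data.frame(), genes = genes_truth,
                             enzyme = enzyme_truth),
                design = design))
  }

  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$pos), , drop = FALSE]
  ns <- nrow(sites)
  nsam <- length(samples)

  ## true per-sample frequencies ----------------------------------------
  freq <- matrix(NA_real_, ns, nsam, dimnames = list(NULL, samples))
  base_f <- runif(ns, cfg$baseline_editing_freq_range[1],
                  cfg$baseline_editing_freq_range[2])
  for (r in seq_len(ns)) {
    if (sites$status[r] == "SNP") {
      f <- if (runif(1) < 0.5) 0.5 else 1.0
      freq[r, ] <- f
      next
    }
    g <- sites$gene_id[r]
    gi <- match(g, genes_truth$gene_id)
    if (isTRUE(genes_truth$enzyme_target[gi]) && !is.null(enzyme_truth$target_maf)) {
      freq[r, ] <- enzyme_truth$target_maf[, g]
    } else if (isTRUE(genes_truth$diff_edited[gi])) {
      mult <- if (genes_truth$edit_direction[gi] == "up")
        2^cfg$editing_effect_log2fc else 2^(-cfg$editing_effect_log2fc)
      f_con <- base_f[r]
      # realize the stated effect exactly: for up-shifted genes the control
      # frequency is drawn from the feasible sub-range so that
      # f_con * 2^lfc stays below the clamp (a 4x shift from f = 0.5 is
      # physically impossible; censoring would silently shrink the effect)
      if (mult > 1) {
        hi <- cfg$freq_clamp / mult
        lo <- cfg$baseline_editing_freq_range[1]
        f_con <- if (hi > lo) runif(1, lo, hi) else hi
      }
      f_lps <- pmin(pmax(f_con * mult, 0.01), cfg$freq_clamp)
      freq[r, ] <- ifelse(group == "LPS", f_lps, f_con)
    } else {
      freq[r, ] <- base_f[r]
    }
  }

  ## depths and alt counts ----------------------------------------------
  size <- 1 / cfg$depth_dispersion
  dp <- matrix(rnbinom(ns * nsam, mu = cfg$mean_depth, size = size),
               ns, nsam)
  depth_violate <- runif(ns) < cfg$qc_violation_rate
  if (any(depth_violate)) {
    dir_up <- runif(sum(depth_violate)) < 0.5
    mult <- ifelse(dir_up, 8, 1 / 8)
    dp[depth_violate, ] <- round(dp[depth_violate, , drop = FALSE] * mult)
  }
  ad <- matrix(rbinom(ns * nsam, as.vector(dp), as.vector(freq)), ns, nsam)
  # homozygous SNPs: every read supports alt
  hom <- sites$status == "SNP" & freq[, 1] == 1
  ad[hom, ] <- dp[hom, ]

  ## QC metrics with independent per-rule corruption ---------------------
  rules <- c("qd", "fs", "mq_rank_sum", "read_pos_rank_sum", "mq", "sor")
  viol <- sapply(rules, function(r) runif(ns) < cfg$qc_violation_rate)
  if (ns == 1) viol <- matrix(viol, nrow = 1, dimnames = list(NULL, rules))
  qc <- sapply(rules, function(r) qc_draw(ns, r, viol[, r]))
  if (ns == 1) qc <- matrix(qc, nrow = 1, dimnames = list(NULL, rules))
  bq_violate <- runif(ns) < cfg$bq_violation_rate
  bq <- ifelse(bq_violate, runif(ns, 10, 24.5), runif(ns, 30, 40))
  multi <- runif(ns) < cfg$multiallelic_rate
  alt2 <- rep(NA_character_, ns)
  if (any(multi)) {
    alt2[multi] <- vapply(which(multi), function(r)
      sample(setdiff(c("A", "C", "G", "T"), c(sites$ref[r], sites$alt[r])), 1),
      character(1))
  }

  info <- data.frame(
    contig = "chrS", pos = sites$pos, ref = sites$ref,
    alt = ifelse(multi, paste(sites$alt, alt2, sep = ","), sites$alt),
    qd = qc[, "qd"], fs = qc[, "fs"],
    mq_rank_sum = qc[, "mq_rank_sum"],
    read_pos_rank_sum = qc[, "read_pos_rank_sum"],
    mq = qc[, "mq"], sor = qc[, "sor"],
    base_quality = bq, n_alt = ifelse(multi, 2L, 1L),
    stringsAsFactors = FALSE)

  truth_sites <- data.frame(
    contig = "chrS", pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene_id = sites$gene_id, status = sites$status,
    true_freq_con = rowMeans(freq[, group == "CON", drop = FALSE]),
    true_freq_lps = rowMeans(freq[, group == "LPS", drop = FALSE]),
    viol_qd = viol[, "qd"], viol_fs = viol[, "fs"],
    viol_mq_rank_sum = viol[, "mq_rank_sum"],
    viol_read_pos_rank_sum = viol[, "read_pos_rank_sum"],
    viol_mq = viol[, "mq"], viol_sor = viol[, "sor"],
    viol_depth_window = depth_violate,
    viol_base_quality = bq_violate, multiallelic = multi,
    stringsAsFactors = FALSE)

  list(candidates = candidate_set(info, dp, ad, samples),
       truth = list(sites = truth_sites, genes = genes_truth,
                    enzyme = enzyme_truth),
       design = design)
}

#' Write a candidate set as VCF v4.2
#'
#' Emits INFO keys QD, FS, MQRankSum, ReadPosRankSum, MQ, SOR and BQ (mean
#' alt base quality) and per-sample FORMAT AD (ref,alt depths) and DP.
#'
#' @param cand a [candidate_set()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_candidate_vcf <- function(cand, path) {
  info <- cand$info
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=editlens-simulate",
    "##contig=<ID=chrS>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean alt base quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cand$samples), collapse = "\t"))
  if (nrow(info) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  fmt_num <- function(x) formatC(x, digits = 4, format = "f")
  info_str <- paste0(
    "QD=", fmt_num(info$qd), ";FS=", fmt_num(info$fs),
    ";MQRankSum=", fmt_num(info$mq_rank_sum),
    ";ReadPosRankSum=", fmt_num(info$read_pos_rank_sum),
    ";MQ=", fmt_num(info$mq), ";SOR=", fmt_num(info$sor),
    ";BQ=", fmt_num(info$base_quality))
  n_alt <- info$n_alt
  geno <- sapply(seq_along(cand$samples), function(j) {
    ref_d <- cand$dp[, j] - cand$ad[, j]
    ad <- paste(ref_d, cand$ad[, j], sep = ",")
    ad[n_alt == 2] <- paste0(ad[n_alt == 2], ",0")
    paste0(ad, ":", cand$dp[, j])
  })
  if (nrow(info) == 1) geno <- matrix(geno, nrow = 1)
  body <- cbind("chrS", info$pos, ".", info$ref, info$alt, ".", ".",
                info_str, "AD:DP", geno)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a candidate VCF into a candidate_set
#'
#' Expects INFO keys QD, FS, MQRankSum, ReadPosRankSum, MQ, SOR (BQ optional;
#' missing BQ yields NA base quality) and FORMAT AD/DP.
#'
#' @param path VCF path
#' @return a [candidate_set()]
#' @export
read_candidate_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  get_info <- function(key) {
    if (key %in% colnames(inf)) as.numeric(inf[[key]]) else
      rep(NA_real_, nrow(inf))
  }
  alt_l <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(as.list(alt_l), function(a)
    paste(as.character(a), collapse = ","), character(1))
  n_alt <- lengths(alt_l)
  samples <- colnames(vcf)
  ad_l <- VariantAnnotation::geno(vcf)$AD
  dp <- VariantAnnotation::geno(vcf)$DP
  ad <- matrix(vapply(seq_along(ad_l), function(k) {
    v <- ad_l[[k]]
    if (length(v) >= 2) as.integer(v[2]) else NA_integer_
  }, integer(1)), nrow = nrow(vcf))
  dp <- matrix(as.integer(dp), nrow = nrow(vcf))
  info <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt_chr,
    qd = get_info("QD"), fs = get_info("FS"),
    mq_rank_sum = get_info("MQRankSum"),
    read_pos_rank_sum = get_info("ReadPosRankSum"),
    mq = get_info("MQ"), sor = get_info("SOR"),
    base_quality = get_info("BQ"), n_alt = as.integer(n_alt),
    stringsAsFactors = FALSE)
  rownames(info) <- NULL
  candidate_set(info, dp, ad, samples)
}
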