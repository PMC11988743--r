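#' Filter thresholds for the two-stage editing-site cascade
#'
#' Stage one ("hard filters") reproduces the GATK-style site-level
#' exclusions: QD < 2, FS > 60, MQRankSum < -12.5, ReadPosRankSum < -8,
#' MQ < 40, SOR > 3, and a cohort-relative mean-depth window
#' \[cohort_mean/3, 3*cohort_mean\]. Stage two ("editing filters") applies
#' the editing-specific criteria: mean alt base quality >= 25, at most two
#' alleles, optional known-SNP exclusion, and per-sample measurement
#' validity: depth >= 5, alt depth >= 3 and editing frequency within
#' \[0.10, 1.00\].
#'
#' @param qd_min,fs_max,mq_rank_sum_min,read_pos_rank_sum_min,mq_min,sor_max
#'   hard-filter bounds (all inclusive on the passing side)
#' @param depth_ratio_low,depth_ratio_high bounds on a site's mean depth
#'   relative to the cohort-wide mean site depth
#' @param base_quality_min minimum mean alt-supporting base quality
#' @param depth_min,alt_depth_min per-sample depth requirements
#' @param freq_min,freq_max editing-frequency retention window (inclusive)
#' @param max_alleles maximum number of alleles (ref + alts)
#' @return object of class `filter_thresholds`
#' @export
filter_thresholds <- function(qd_min = 2, fs_max = 60,
                              mq_rank_sum_min = -12.5,
                              read_pos_rank_sum_min = -8,
                              mq_min = 40, sor_max = 3,
                              depth_ratio_low = 1 / 3, depth_ratio_high = 3,
                              base_quality_min = 25,
                              depth_min = 5, alt_depth_min = 3,
                              freq_min = 0.10, freq_max = 1.00,
                              max_alleles = 2) {
  thr <- as.list(environment())
  if (freq_min >= freq_max) stop("freq_min must be < freq_max")
  if (!all(vapply(thr, is.finite, logical(1))))
    stop("all thresholds must be finite")
  structure(thr, class = "filter_thresholds")
}

HARD_FILTER_RULES <- c("qd", "fs", "mq_rank_sum", "read_pos_rank_sum",
                       "mq", "sor", "depth_window")

#' Apply site-level hard filters to variant candidates
#'
#' A candidate survives iff qd >= qd_min AND fs <= fs_max AND
#' mq_rank_sum >= mq_rank_sum_min AND read_pos_rank_sum >=
#' read_pos_rank_sum_min AND mq >= mq_min AND sor <= sor_max AND its mean
#' across-sample depth lies within
#' \[cohort_mean * depth_ratio_low, cohort_mean * depth_ratio_high\].
#' All boundaries are inclusive on the passing side. Removals are attributed
#' to the first failing rule in the fixed order QD, FS, MQRankSum,
#' ReadPosRankSum, MQ, SOR, depth window; a non-finite metric removes the
#' candidate under reason `missing_qc`.
#'
#' The cohort mean depth used by the window is stored as attribute
#' `cohort_mean_depth` on the result and reused when the filter is
#' re-applied to its own output, which makes the operation idempotent.
#'
#' @param cand a [candidate_set()]
#' @param thr a [filter_thresholds()]
#' @param cohort_mean_depth optionally, a fixed cohort mean depth; default
#'   computed from `cand` (or taken from its attribute if present)
#' @return list with `survivors` (a [candidate_set()] carrying the
#'   `cohort_mean_depth` attribute) and `removals` (named integer vector of
#'   first-failing-rule counts, including `missing_qc`)
#' @export
apply_hard_filters <- function(cand, thr = filter_thresholds(),
                               cohort_mean_depth = NULL) {
  stopifnot(inherits(cand, "candidate_set"))
  info <- cand$info
  n <- nrow(info)
  rules <- c(HARD_FILTER_RULES, "missing_qc")
  removals <- setNames(integer(length(rules)), rules)
  if (n == 0) {
    out <- cand
    attr(out, "cohort_mean_depth") <- cohort_mean_depth %||% NA_real_
    return(list(survivors = out, removals = removals))
  }
  site_mean_depth <- rowMeans(cand$dp)
  cm <- cohort_mean_depth %||% attr(cand, "cohort_mean_depth") %||%
    mean(site_mean_depth)

  metrics <- info[, c("qd", "fs", "mq_rank_sum", "read_pos_rank_sum",
                      "mq", "sor")]
  nonfinite <- !apply(metrics, 1, function(r) all(is.finite(r)))

  fails <- cbind(
    qd = info$qd < thr$qd_min,
    fs = info$fs > thr$fs_max,
    mq_rank_sum = info$mq_rank_sum < thr$mq_rank_sum_min,
    read_pos_rank_sum = info$read_pos_rank_sum < thr$read_pos_rank_sum_min,
    mq = info$mq < thr$mq_min,
    sor = info$sor > thr$sor_max,
    depth_window = site_mean_depth < cm * thr$depth_ratio_low |
      site_mean_depth > cm * thr$depth_ratio_high)
  fails[is.na(fails)] <- FALSE

  first_fail <- apply(fails, 1, function(r) {
    w <- which(r)
    if (length(w)) HARD_FILTER_RULES[w[1]] else NA_character_
  })
  first_fail[nonfinite] <- "missing_qc"
  removed <- !is.na(first_fail)
  if (any(removed)) {
    tab <- table(first_fail[removed])
    removals[names(tab)] <- as.integer(tab)
  }
  keep <- !removed
  surv <- candidate_set(info[keep, , drop = FALSE],
                        cand$dp[keep, , drop = FALSE],
                        cand$ad[keep, , drop = FALSE],
                        cand$samples)
  attr(surv, "cohort_mean_depth") <- cm
  list(survivors = surv, removals = removals)
}

#' Per-site editing frequency
#'
#' The proportion of reads supporting the edited base:
#' `alt_depth / total_depth`. A zero total depth yields `NA` (an undefined
#' measurement), never 0.
#'
#' @param alt_depth,total_depth non-negative read counts (vectorized)
#' @return numeric vector of frequencies in \[0, 1\], `NA` where
#'   `total_depth == 0`
#' @export
editing_frequency <- function(alt_depth, total_depth) {
  if (any(alt_depth < 0 | total_depth < 0, na.rm = TRUE))
    stop("depths must be non-negative")
  if (any(alt_depth > total_depth, na.rm = TRUE))
    stop("alt_depth must not exceed total_depth")
  ifelse(total_depth == 0, NA_real_, alt_depth / total_depth)
}

#' Editing-site container
#'
#' Filtered sites with per-sample depth, alt depth, editing frequency
#' (`NA` where the measurement is invalid) and the validity mask.
#'
#' @param sites data.frame with contig, pos, ref, alt, base_quality
#' @param dp,ad integer matrices sites x samples
#' @param freq numeric frequency matrix (NA = invalid measurement)
#' @param valid logical matrix of per-sample measurement validity
#' @param samples sample ids
#' @return object of class `editing_sites`
#' @export
editing_sites <- function(sites, dp, ad, freq, valid, samples) {
  stopifnot(nrow(sites) == nrow(dp), all(dim(dp) == dim(freq)),
            all(dim(dp) == dim(valid)))
  colnames(dp) <- colnames(ad) <- colnames(freq) <- colnames(valid) <- samples
  structure(list(sites = sites, dp = dp, ad = ad, freq = freq,
                 valid = valid, samples = samples),
            class = "editing_sites")
}

#' @export
print.editing_sites <- function(x, ...) {
  cat("editing_sites:", nrow(x$sites), "sites x", length(x$samples),
      "samples;", sum(x$valid), "valid measurements\n")
  invisible(x)
}

#' Apply editing-specific filters to hard-filtered candidates
#'
#' Retains a candidate iff its mean alt base quality >= `base_quality_min`,
#' it carries exactly one alt allele (at most `max_alleles` alleles total),
#' and it is not listed in `known_snps`. A per-sample measurement is valid
#' iff total depth >= `depth_min`, alt depth >= `alt_depth_min` and
#' frequency lies in \[`freq_min`, `freq_max`\] (inclusive). A site is kept
#' iff at least one sample measurement is valid; invalid measurements have
#' `NA` frequency.
#'
#' @param cand hard-filtered [candidate_set()]
#' @param thr a [filter_thresholds()]
#' @param known_snps optional data.frame with columns contig, pos listing
#'   germline SNP positions to exclude
#' @return list with `sites` (an [editing_sites()]) and `removals`
#'   (named counts: base_quality, multiallelic, known_snp, no_valid_sample)
#' @export
apply_editing_filters <- function(cand, thr = filter_thresholds(),
                                  known_snps = NULL) {
  stopifnot(inherits(cand, "candidate_set"))
  info <- cand$info
  n <- nrow(info)
  removals <- c(base_quality = 0L, multiallelic = 0L, known_snp = 0L,
                no_valid_sample = 0L)
  if (n == 0) {
    es <- editing_sites(
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), base_quality = numeric()),
      matrix(0L, 0, length(cand$samples)), matrix(0L, 0, length(cand$samples)),
      matrix(0, 0, length(cand$samples)),
      matrix(FALSE, 0, length(cand$samples)), cand$samples)
    return(list(sites = es, removals = removals))
  }
  n_alt <- info$n_alt %||% lengths(strsplit(info$alt, ","))
  if (any(n_alt == 0)) stop("candidate with zero alt alleles")
  bq_fail <- !is.finite(info$base_quality) |
    info$base_quality < thr$base_quality_min
  multi_fail <- (n_alt + 1L) > thr$max_alleles
  snp_fail <- rep(FALSE, n)
  if (!is.null(known_snps) && nrow(known_snps) > 0) {
    key <- paste(info$contig, info$pos)
    snp_fail <- key %in% paste(known_snps$contig, known_snps$pos)
  }
  # per-sample validity on sites passing the site-level rules
  freq <- editing_frequency(cand$ad, cand$dp)
  valid <- cand$dp >= thr$depth_min & cand$ad >= thr$alt_depth_min &
    !is.na(freq) & freq >= thr$freq_min & freq <= thr$freq_max
  valid[is.na(valid)] <- FALSE
  any_valid <- rowSums(valid) > 0

  reason <- rep(NA_character_, n)
  reason[!any_valid] <- "no_valid_sample"
  reason[snp_fail] <- "known_snp"
  reason[multi_fail] <- "multiallelic"
  reason[bq_fail] <- "base_quality"
  keep <- is.na(reason)
  tab <- table(reason[!keep])
  removals[names(tab)] <- as.integer(tab)

  freq_out <- freq
  freq_out[!valid] <- NA_real_
  sites <- data.frame(contig = info$contig, pos = info$pos, ref = info$ref,
                      alt = sub(",.*$", "", info$alt),
                      base_quality = info$base_quality,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(sites) <- NULL
  es <- editing_sites(sites,
                      cand$dp[keep, , drop = FALSE],
                      cand$ad[keep, , drop = FALSE],
                      freq_out[keep, , drop = FALSE],
                      valid[keep, , drop = FALSE],
                      cand$samples)
  list(sites = es, removals = removals)
}

#' Run the full two-stage discovery cascade
#'
#' @param cand a [candidate_set()] (e.g. from [read_candidate_vcf()])
#' @param thr a [filter_thresholds()]
#' @param known_snps optional known-SNP table (contig, pos)
#' @return list with `sites` (an [editing_sites()]) and `report` (data.frame
#'   of per-rule removal counts across both stages)
#' @export
discover_editing_sites <- function(cand, thr = filter_thresholds(),
                                   known_snps = NULL) {
  hard <- apply_hard_filters(cand, thr)
  edit <- apply_editing_filters(hard$survivors, thr, known_snps)
  report <- data.frame(
    stage = c(rep("hard", length(hard$removals)),
              rep("editing", length(edit$removals))),
    rule = c(names(hard$removals), names(edit$removals)),
    removed = c(as.integer(hard$removals), as.integer(edit$removals)),
    stringsAsFactors = FALSE)
  list(sites = edit$sites, report = report)
}

#' Write an editing-sites table as TSV
#'
#' One row per site: contig, pos (1-based), ref, alt, base_quality, then per
#' sample `<s>.dp`, `<s>.alt`, `<s>.freq` (empty where invalid).
#'
#' @param es an [editing_sites()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_editing_sites <- function(es, path) {
  df <- es$sites
  for (s in es$samples) {
    df[[paste0(s, ".dp")]] <- es$dp[, s]
    df[[paste0(s, ".alt")]] <- es$ad[, s]
    df[[paste0(s, ".freq")]] <- round(es$freq[, s], 6)
  }
  write_tsv(df, path)
}

#' Read an editing-sites TSV written by [write_editing_sites()]
#' @param path TSV path
#' @return an [editing_sites()]
#' @export
read_editing_sites <- function(path) {
  df <- read_tsv(path)
  samples <- unique(sub("\\.dp$", "", grep("\\.dp$", names(df), value = TRUE)))
  get <- function(suffix) as.matrix(df[, paste0(samples, suffix),
                                       drop = FALSE])
  dp <- get(".dp"); ad <- get(".alt"); freq <- get(".freq")
  editing_sites(df[, c("contig", "pos", "ref", "alt", "base_quality")],
                dp, ad, freq, !is.na(freq), samples)
}
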