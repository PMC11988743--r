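#' Transcripts per million
#'
#' rate_gs = count_gs / length_g; tpm_gs = rate_gs / sum_g(rate_gs) * 1e6.
#' Each sample column sums to 1e6 (up to floating point), and scaling all
#' counts of a sample leaves its TPM column unchanged.
#'
#' @param counts gene x sample count matrix
#' @param lengths named vector of gene effective lengths (bp), covering all
#'   rows of `counts`
#' @return TPM matrix with the same dimnames as `counts`
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || anyNA(lengths))
    stop("lengths must cover every gene in counts")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / as.numeric(lengths)
  denom <- colSums(rate)
  if (any(denom == 0)) stop("sample with zero total rate")
  sweep(rate, 2, denom, "/") * 1e6
}

#' Sample-sample Pearson correlation of expression
#'
#' Computed on log2(TPM + 1) by default (`log_transform = FALSE` uses the
#' matrix as given). Symmetric with unit diagonal; a zero-variance sample
#' yields `NA` correlations.
#'
#' @param expr gene x sample matrix (TPM unless `log_transform = FALSE`)
#' @param log_transform apply log2(x + 1) first
#' @return sample x sample correlation matrix
#' @export
sample_correlation <- function(expr, log_transform = TRUE) {
  m <- as.matrix(expr)
  if (nrow(m) < 2) stop("need >= 2 genes")
  if (log_transform) m <- log2(m + 1)
  sds <- apply(m, 2, sd)
  cc <- suppressWarnings(cor(m))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  cc
}

#' PCA of editing frequencies
#'
#' Sites observed (valid) in fewer than `min_samples_observed` samples are
#' dropped; remaining missing frequencies are imputed with the per-site mean
#' over observed samples; site columns are centered and samples decomposed
#' by SVD. Component signs follow the convention that the
#' largest-magnitude site loading is positive.
#'
#' @param freq site x sample frequency matrix (NA = unobserved)
#' @param min_samples_observed minimum observed samples per retained site
#' @return list with `scores` (samples x components), `variance_pct`
#'   (non-increasing percentages) and `n_sites_used`
#' @export
editing_pca <- function(freq, min_samples_observed = 2) {
  freq <- as.matrix(freq)
  if (ncol(freq) < 2) stop("need >= 2 samples")
  obs <- rowSums(!is.na(freq))
  keep <- obs >= min_samples_observed
  X <- t(freq[keep, , drop = FALSE])       # samples x sites
  if (ncol(X) < 2) stop("fewer than 2 sites retained")
  for (j in seq_len(ncol(X))) {
    m <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- m
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  k <- min(dim(X)) - 0L
  scores <- X %*% sv$v
  # sign convention: largest-|loading| positive per component
  for (c in seq_len(ncol(sv$v))) {
    l <- sv$v[, c]
    s <- sign(l[which.max(abs(l))])
    if (s < 0) { sv$v[, c] <- -l; scores[, c] <- -scores[, c] }
  }
  total <- sum(sv$d^2)
  var_pct <- if (total > 0) sv$d^2 / total * 100 else rep(0, length(sv$d))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- colnames(freq)
  list(scores = scores, variance_pct = var_pct,
       n_sites_used = ncol(X))
}

#' Shared and group-unique editing events
#'
#' Sites are keyed by (contig, pos, ref, alt); an event belongs to a group
#' if at least one of the group's samples has a valid measurement.
#'
#' @param es an [editing_sites()]
#' @param design sample/group table
#' @return data.frame of 2-set Venn counts: label
#'   (`common`, `<group>_only`), count; plus an attribute `keys` holding the
#'   per-group key sets
#' @export
shared_events <- function(es, design) {
  key <- paste(es$sites$contig, es$sites$pos, es$sites$ref, es$sites$alt,
               sep = ":")
  groups <- sort(unique(design$group))
  if (length(groups) != 2) stop("exactly two groups required")
  sets <- lapply(groups, function(g) {
    sm <- design$sample_id[design$group == g]
    key[rowSums(es$valid[, sm, drop = FALSE]) > 0]
  })
  names(sets) <- groups
  common <- intersect(sets[[1]], sets[[2]])
  out <- data.frame(
    label = c("common", paste0(groups, "_only")),
    count = c(length(common),
              length(setdiff(sets[[1]], sets[[2]])),
              length(setdiff(sets[[2]], sets[[1]]))),
    stringsAsFactors = FALSE)
  attr(out, "keys") <- sets
  out
}

#' Per-group histogram of editing frequencies
#'
#' Bins all valid per-sample frequency measurements of each group. Bins are
#' given by breakpoints partitioning \[0, 1\]; intervals are (lo, hi] with
#' the first bin closed on the left.
#'
#' @param es an [editing_sites()]
#' @param design sample/group table
#' @param breaks increasing breakpoints spanning \[0, 1\]
#' @return data.frame: group, bin_lo, bin_hi, count; counts per group sum
#'   to that group's number of valid measurements
#' @export
frequency_histogram <- function(es, design,
                                breaks = seq(0, 1, by = 0.1)) {
  if (is.unsorted(breaks, strictly = TRUE) ||
      breaks[1] > 0 || breaks[length(breaks)] < 1)
    stop("breaks must strictly increase and span [0, 1]")
  groups <- unique(design$group)
  rows <- lapply(groups, function(g) {
    sm <- design$sample_id[design$group == g]
    f <- es$freq[, sm, drop = FALSE]
    f <- f[!is.na(f)]
    idx <- cut(f, breaks = breaks, include.lowest = TRUE, right = TRUE)
    data.frame(group = g, bin_lo = head(breaks, -1), bin_hi = breaks[-1],
               count = tabulate(idx, nbins = length(breaks) - 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
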