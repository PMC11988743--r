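QUADRANT_STATES <- c("down", "ns", "up")

#' Nine-quadrant editing-by-expression classification
#'
#' Each gene present in both result sets gets one of nine quadrants from
#' its editing state (rows: down/ns/up, bottom to top) and expression state
#' (columns: down/ns/up, left to right), indexed 1--9 row-major from the
#' bottom-left. A state is "up" iff log2FC > threshold (and BH-significant
#' when `require_significance`), "down" iff log2FC < -threshold (and
#' significant), else "ns". Candidates are the up/up quadrant (index 9):
#' coordinated upregulation of both editing and expression.
#'
#' By default the expression axis reuses the DEG rule (|log2FC| >= 1) while
#' the editing axis uses significance only (threshold 0).
#'
#' @param editing_results,expression_results `differential_result`
#'   data.frames (from [differential_editing()] / [differential_expression()])
#' @param lfc_threshold_edit,lfc_threshold_expr per-axis |log2FC| thresholds
#' @param padj_threshold adjusted-p threshold defining significance
#' @param require_significance require BH significance for up/down states
#' @return data.frame: gene, editing_log2fc, expression_log2fc,
#'   editing_state, expression_state, quadrant (1-9), candidate; attribute
#'   `n_excluded` counts genes present in only one result set
#' @export
nine_quadrant <- function(editing_results, expression_results,
                          lfc_threshold_edit = 0, lfc_threshold_expr = 1,
                          padj_threshold = 0.05,
                          require_significance = TRUE) {
  if (lfc_threshold_edit < 0 || lfc_threshold_expr < 0)
    stop("thresholds must be >= 0")
  common <- intersect(editing_results$feature, expression_results$feature)
  n_excluded <- length(union(editing_results$feature,
                             expression_results$feature)) - length(common)
  ed <- editing_results[match(common, editing_results$feature), ]
  ex <- expression_results[match(common, expression_results$feature), ]
  state <- function(lfc, padj, thr) {
    sig <- if (require_significance)
      !is.na(padj) & padj < padj_threshold else rep(TRUE, length(lfc))
    ifelse(!is.na(lfc) & lfc > thr & sig, "up",
           ifelse(!is.na(lfc) & lfc < -thr & sig, "down", "ns"))
  }
  es <- state(ed$log2fc, ed$p_adjusted, lfc_threshold_edit)
  xs <- state(ex$log2fc, ex$p_adjusted, lfc_threshold_expr)
  quadrant <- (match(es, QUADRANT_STATES) - 1L) * 3L +
    match(xs, QUADRANT_STATES)
  out <- data.frame(gene = common,
                    editing_log2fc = ed$log2fc,
                    expression_log2fc = ex$log2fc,
                    editing_state = es, expression_state = xs,
                    quadrant = quadrant,
                    candidate = es == "up" & xs == "up",
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-sample mean allele frequency (MAF) of a gene's editing sites
#'
#' The study's "MAF" is the mean of a gene's valid per-site editing
#' frequencies in a sample (not population minor-allele frequency);
#' missing where the gene has no valid measurement in that sample.
#'
#' @param es an [editing_sites()]
#' @param gene_id gene to summarize
#' @param annotation [annotate_sites()] output aligned to `es` (or models
#'   via `models=` to compute it)
#' @param models optional `gene_models`
#' @return named numeric vector over samples (NA where unobserved)
#' @export
gene_maf <- function(es, gene_id, annotation = NULL, models = NULL) {
  if (is.null(annotation)) {
    if (is.null(models)) stop("provide annotation or models")
    annotation <- annotate_sites(es, models)
  }
  idx <- which(annotation$gene_id == gene_id)
  if (!length(idx)) stop("gene has no editing sites: ", gene_id)
  f <- es$freq[idx, , drop = FALSE]
  out <- colMeans(f, na.rm = TRUE)
  out[colSums(!is.na(f)) == 0] <- NA_real_
  out
}

#' Pearson correlation between enzyme expression and target editing level
#'
#' Pearson r over paired non-missing samples; two-sided p from
#' t = r * sqrt((n - 2) / (1 - r^2)). Requires >= 3 complete pairs;
#' zero variance in either vector yields NA r.
#'
#' @param enzyme_expr per-sample enzyme expression (e.g. TPM)
#' @param target_maf per-sample target-gene MAF ([gene_maf()])
#' @return list: r, p_value, n (complete pairs used)
#' @export
enzyme_correlation <- function(enzyme_expr, target_maf) {
  ok <- is.finite(enzyme_expr) & is.finite(target_maf)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 paired non-missing samples")
  x <- enzyme_expr[ok]; y <- target_maf[ok]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}
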