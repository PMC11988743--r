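#' Build the enrichment universe
#'
#' `annotated_only` (default): the universe is the union of all pathway
#' gene sets — the genes carrying a pathway annotation. `all_genes`
#' requires an explicit gene list.
#'
#' @param pathways data.frame with columns pathway_id, gene_id
#'   (pathway_name optional)
#' @param mode "annotated_only" or "all_genes"
#' @param all_genes gene ids for `mode = "all_genes"`
#' @return character vector, the universe gene set (N = its length)
#' @export
build_universe <- function(pathways, mode = c("annotated_only", "all_genes"),
                           all_genes = NULL) {
  mode <- match.arg(mode)
  if (nrow(pathways) == 0) stop("empty pathway table")
  if (mode == "annotated_only")
    sort(unique(pathways$gene_id))
  else {
    if (is.null(all_genes)) stop("all_genes required for mode='all_genes'")
    sort(unique(as.character(all_genes)))
  }
}

# upper-tail hypergeometric P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n)
# evaluated in log space: Pr(X >= m).
hyper_upper_tail <- function(m, M, N, n) {
  if (m <= 0) return(1)
  i <- m:min(M, n)
  if (length(i) == 0 || i[1] > min(M, n)) return(0)
  lw <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  lw <- lw[is.finite(lw)]
  if (!length(lw)) return(0)
  mx <- max(lw)
  min(1, exp(mx + log(sum(exp(lw - mx)))))
}

#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway, with N the universe size, n the number of candidate
#' genes in the universe, M the pathway's genes in the universe and m the
#' candidate genes in the pathway, computes the upper-tail probability
#' P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n) (log-space
#' evaluation), BH-adjusts across tested pathways, and flags enrichment at
#' `fdr_threshold`. Candidates outside the universe are dropped (and
#' counted); pathways with no universe genes are skipped.
#'
#' @param candidates candidate gene ids
#' @param pathways data.frame pathway_id, gene_id (pathway_name optional)
#' @param universe universe gene set (default [build_universe()] on
#'   `pathways`)
#' @param fdr_threshold enrichment FDR threshold
#' @return data.frame sorted by fdr then p: pathway_id, pathway_name, N, n,
#'   M, m, p_value, fdr, enriched; attribute `n_dropped_candidates`
#' @export
hypergeometric_enrichment <- function(candidates, pathways,
                                      universe = NULL,
                                      fdr_threshold = 0.05) {
  if (is.null(universe)) universe <- build_universe(pathways)
  candidates <- unique(as.character(candidates))
  dropped <- sum(!candidates %in% universe)
  cand <- intersect(candidates, universe)
  N <- length(universe); n <- length(cand)
  ids <- unique(pathways$pathway_id)
  rows <- lapply(ids, function(pid) {
    genes <- intersect(unique(pathways$gene_id[pathways$pathway_id == pid]),
                       universe)
    M <- length(genes)
    if (M == 0) return(NULL)
    m <- length(intersect(cand, genes))
    nm <- if ("pathway_name" %in% names(pathways))
      pathways$pathway_name[match(pid, pathways$pathway_id)] else pid
    data.frame(pathway_id = pid, pathway_name = nm, N = N, n = n,
               M = M, m = m,
               p_value = if (n == 0) 1 else hyper_upper_tail(m, M, N, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(), pathway_name = character(),
                      N = integer(), n = integer(), M = integer(),
                      m = integer(), p_value = numeric())
  out$fdr <- bh_adjust(out$p_value)
  out$enriched <- !is.na(out$fdr) & out$fdr <= fdr_threshold
  out <- out[order(out$fdr, out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_candidates") <- dropped
  out
}
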