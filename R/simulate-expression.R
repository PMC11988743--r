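#' Simulate a gene-by-sample expression count matrix
#'
#' Counts are NB with gene-specific log-normal baseline means and the
#' configured dispersion. DE genes are shifted by
#' `expression_effect_log2fc` in the LPS group. The enzyme gene's expected
#' counts are proportional to the true per-sample scaled expression recorded
#' in the truth table, so the linear enzyme-to-editing link of the target
#' genes (already baked into the candidate frequencies) is recoverable from
#' the realized expression matrix.
#'
#' @param config a [simulation_config()]
#' @param models `gene_models`
#' @param truth truth list from [simulate_candidates()]
#' @return list with `counts` (integer matrix genes x samples) and
#'   `lengths` (named vector of transcript lengths, bp)
#' @export
simulate_expression <- function(config, models, truth) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config, "expression"))
  gt <- models$gene_table
  gtr <- truth$genes
  if (!identical(sort(gt$gene_id), sort(gtr$gene_id)))
    stop("truth table does not match gene models")
  gtr <- gtr[match(gt$gene_id, gtr$gene_id), ]
  n_per <- config$n_samples_per_group
  samples <- c(paste0("CON_", seq_len(n_per)), paste0("LPS_", seq_len(n_per)))
  group <- rep(c("CON", "LPS"), each = n_per)
  ng <- nrow(gt)
  base_mu <- rlnorm(ng, config$expr_mean_log, config$expr_sd_log)
  # the editing enzyme is robustly expressed (liver deaminases are abundant);
  # a fixed high baseline also keeps its TPM measurement error small
  if (!is.null(truth$enzyme) && !is.na(truth$enzyme$enzyme_gene %||% NA)) {
    ei0 <- match(truth$enzyme$enzyme_gene, gt$gene_id)
    if (!is.na(ei0))
      base_mu[ei0] <- exp(config$expr_mean_log + config$expr_sd_log)
  }
  mu <- matrix(base_mu, ng, length(samples))
  shift <- ifelse(gtr$de & !gtr$enzyme,
                  ifelse(gtr$de_direction == "up",
                         2^config$expression_effect_log2fc,
                         2^(-config$expression_effect_log2fc)), 1)
  mu[, group == "LPS"] <- mu[, group == "LPS"] * shift
  if (!is.null(truth$enzyme) && !is.na(truth$enzyme$enzyme_gene %||% NA)) {
    ei <- match(truth$enzyme$enzyme_gene, gt$gene_id)
    if (!is.na(ei))
      mu[ei, ] <- base_mu[ei] * truth$enzyme$enzyme_scaled_expression
  }
  alpha <- config$expr_disp_asymp + config$expr_disp_shape / pmax(mu, 1)
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / as.vector(alpha)),
                   ng, length(samples),
                   dimnames = list(gt$gene_id, samples))
  lengths <- setNames(gt$tx_length, gt$gene_id)
  list(counts = counts, lengths = lengths)
}

#' Simulate a pathway membership table
#'
#' Assigns genes to `n_pathways` overlapping pathways. To give enrichment
#' something real to find, differentially edited genes are concentrated into
#' the first pathway ("PW0001") with elevated probability.
#'
#' @param config a [simulation_config()]
#' @param models `gene_models`
#' @param truth truth list from [simulate_candidates()]
#' @param n_pathways number of pathways
#' @param mean_size mean genes per pathway
#' @return data.frame with columns pathway_id, pathway_name, gene_id
#' @export
simulate_pathways <- function(config, models, truth, n_pathways = 20,
                              mean_size = 25) {
  set.seed(stage_seed(config, "pathways"))
  gids <- models$gene_table$gene_id
  gtr <- truth$genes
  dre <- gtr$gene_id[gtr$diff_edited]
  rows <- list()
  for (p in seq_len(n_pathways)) {
    pid <- sprintf("PW%04d", p)
    size <- max(3, rpois(1, mean_size))
    if (p == 1 && length(dre)) {
      take_dre <- dre[runif(length(dre)) < 0.6]
      pool <- setdiff(gids, take_dre)
      rest <- sample(pool, min(length(pool), max(0, size - length(take_dre))))
      members <- c(take_dre, rest)
    } else {
      members <- sample(gids, min(size, length(gids)))
    }
    rows[[p]] <- data.frame(pathway_id = pid,
                            pathway_name = paste0("pathway_", p),
                            gene_id = sort(members),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate and write a complete synthetic study
#'
#' Runs [simulate_reference()], [simulate_candidates()],
#' [simulate_expression()] and [simulate_pathways()] and writes the full
#' input bundle to `out_dir`: `reference.fa`, `genes.gff3`,
#' `candidates.vcf`, `expression_counts.tsv`, `gene_lengths.tsv`,
#' `pathways.tsv`, `design.tsv`, plus ground-truth tables
#' `truth_sites.tsv`, `truth_genes.tsv` and `truth_enzyme.tsv` and a
#' `known_snps.tsv` (contig, pos) derived from the truth, usable as the
#' known-SNP exclusion list.
#'
#' @param config a [simulation_config()]
#' @param out_dir output directory (created if absent)
#' @return invisibly, a list with all in-memory objects and file paths
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- simulate_reference(config)
  sim <- simulate_candidates(config, models)
  expr <- simulate_expression(config, models, sim$truth)
  pathways <- simulate_pathways(config, models, sim$truth)

  p <- function(f) file.path(out_dir, f)
  write_gene_models(models, p("reference.fa"), p("genes.gff3"))
  write_candidate_vcf(sim$candidates, p("candidates.vcf"))
  write_tsv(data.frame(gene_id = rownames(expr$counts), expr$counts,
                       check.names = FALSE),
            p("expression_counts.tsv"))
  write_tsv(data.frame(gene_id = names(expr$lengths),
                       length = as.integer(expr$lengths)),
            p("gene_lengths.tsv"))
  write_tsv(pathways, p("pathways.tsv"))
  write_tsv(sim$design, p("design.tsv"))
  if (nrow(sim$truth$sites) > 0) {
    write_tsv(sim$truth$sites, p("truth_sites.tsv"))
    snps <- sim$truth$sites[sim$truth$sites$status == "SNP",
                            c("contig", "pos")]
    write_tsv(snps, p("known_snps.tsv"))
  } else {
    write_tsv(data.frame(contig = character(), pos = integer()),
              p("known_snps.tsv"))
  }
  write_tsv(sim$truth$genes, p("truth_genes.tsv"))
  if (!is.null(sim$truth$enzyme) && !is.null(sim$truth$enzyme$target_maf)) {
    enz <- data.frame(sample_id = sim$truth$enzyme$samples,
                      enzyme_gene = sim$truth$enzyme$enzyme_gene,
                      enzyme_scaled_expression =
                        sim$truth$enzyme$enzyme_scaled_expression,
                      sim$truth$enzyme$target_maf, check.names = FALSE)
    write_tsv(enz, p("truth_enzyme.tsv"))
  }
  invisible(list(config = config, models = models, candidates = sim$candidates,
                 truth = sim$truth, design = sim$design,
                 counts = expr$counts, lengths = expr$lengths,
                 pathways = pathways, dir = out_dir))
}

# plain deterministic TSV writers/readers shared across the package
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Read a gene-by-sample count matrix TSV (first column = gene_id)
#' @param path TSV path
#' @return integer matrix with gene rownames
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
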