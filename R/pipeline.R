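#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds for [run_pipeline()].
#' Precedence of settings is caller arguments > config file > defaults;
#' [read_pipeline_config()] loads a JSON file into this constructor.
#'
#' @param vcf variant-candidate VCF path
#' @param fasta reference FASTA path
#' @param gff3 gene-model GFF3 path
#' @param counts expression count matrix TSV (gene_id + sample columns)
#' @param lengths gene length TSV (gene_id, length)
#' @param pathways pathway membership TSV (pathway_id, pathway_name, gene_id)
#' @param design design TSV (sample_id, group)
#' @param out_dir run directory for stage outputs and the manifest
#' @param known_snps optional known-SNP TSV (contig, pos); `NULL` disables
#'   the exclusion
#' @param enzyme_gene optional editing-enzyme gene id for the
#'   enzyme-correlation stage
#' @param thresholds a [filter_thresholds()]
#' @param padj_threshold adjusted-p cutoff for both differential analyses
#' @param lfc_threshold_expr |log2FC| cutoff for differential expression and
#'   the expression axis of the quadrant plot
#' @param lfc_threshold_edit |log2FC| cutoff for the editing axis
#' @param enrichment_fdr FDR cutoff for pathway enrichment
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(vcf, fasta, gff3, counts, lengths, pathways,
                            design, out_dir,
                            known_snps = NULL, enzyme_gene = NULL,
                            thresholds = filter_thresholds(),
                            padj_threshold = 0.05,
                            lfc_threshold_expr = 1,
                            lfc_threshold_edit = 0,
                            enrichment_fdr = 0.05,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' File keys mirror the [pipeline_config()] arguments; `overrides` (a named
#' list, e.g. from CLI flags) take precedence over file values.
#'
#' @param path JSON config path
#' @param overrides named list of overriding arguments
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- vals$thresholds
  vals$thresholds <- if (is.null(thr)) filter_thresholds()
  else do.call(filter_thresholds, as.list(thr))
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Validate pipeline inputs
#'
#' Checks that all referenced files exist, the VCF carries the required
#' INFO/FORMAT keys, the design covers every VCF sample, every GFF3 CDS has
#' total length divisible by 3, and the count-matrix samples match the
#' design.
#'
#' @param config a `pipeline_config`
#' @return character vector of problems (empty when valid)
#' @export
validate_inputs <- function(config) {
  problems <- character()
  need <- c("vcf", "fasta", "gff3", "counts", "lengths", "pathways",
            "design")
  for (k in need) {
    if (is.null(config[[k]]) || !file.exists(config[[k]]))
      problems <- c(problems, paste0("missing input file: ", k))
  }
  if (length(problems)) return(problems)

  hdr <- readLines(config$vcf, n = 200)
  hdr <- hdr[startsWith(hdr, "#")]
  for (key in c("QD", "FS", "MQRankSum", "ReadPosRankSum", "MQ", "SOR")) {
    if (!any(grepl(paste0("##INFO=<ID=", key, ","), hdr, fixed = TRUE)))
      problems <- c(problems, paste0("VCF missing INFO key: ", key))
  }
  for (key in c("AD", "DP")) {
    if (!any(grepl(paste0("##FORMAT=<ID=", key, ","), hdr, fixed = TRUE)))
      problems <- c(problems, paste0("VCF missing FORMAT key: ", key))
  }
  chrom <- hdr[startsWith(hdr, "#CHROM")]
  design <- read_tsv(config$design)
  if (length(chrom) == 1) {
    vcf_samples <- strsplit(chrom, "\t")[[1]][-(1:9)]
    miss <- setdiff(vcf_samples, design$sample_id)
    if (length(miss))
      problems <- c(problems,
                    paste0("design missing VCF sample(s): ",
                           paste(miss, collapse = ", ")))
  } else problems <- c(problems, "VCF has no #CHROM header line")

  models <- tryCatch(read_gene_models(config$fasta, config$gff3),
                     error = function(e) NULL)
  if (is.null(models)) {
    problems <- c(problems, "failed to parse FASTA/GFF3")
  } else {
    bad <- models$gene_table$gene_id[
      !is.na(models$gene_table$cds_length) &
        models$gene_table$cds_length %% 3 != 0]
    if (length(bad))
      problems <- c(problems,
                    paste0("CDS length not divisible by 3: ",
                           paste(bad, collapse = ", ")))
  }
  counts <- tryCatch(read_count_matrix(config$counts),
                     error = function(e) NULL)
  if (is.null(counts)) problems <- c(problems, "failed to parse counts TSV")
  else {
    miss <- setdiff(colnames(counts), design$sample_id)
    if (length(miss))
      problems <- c(problems,
                    paste0("design missing count sample(s): ",
                           paste(miss, collapse = ", ")))
  }
  problems
}

#' Run the full editing-analysis pipeline
#'
#' Executes discover -> annotate -> diff-edit -> diff-expr -> summarize ->
#' integrate -> enrich, writing one TSV per stage plus a JSON run manifest
#' (`manifest.json`: stage row counts, input MD5 checksums, settings).
#' Outputs are deterministic: re-running with the same config reproduces
#' byte-identical files. A stage failure aborts with the stage name and
#' leaves a `<stage>.failed` marker in the run directory.
#'
#' @param config a `pipeline_config`
#' @return invisibly, a list of in-memory stage results
#' @export
run_pipeline <- function(config) {
  problems <- validate_inputs(config)
  if (length(problems))
    stop("invalid inputs:\n", paste("-", problems, collapse = "\n"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out, f)
  stages <- character()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      file.create(p(paste0(name, ".failed")))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  design <- read_tsv(config$design)
  models <- read_gene_models(config$fasta, config$gff3)
  counts <- read_count_matrix(config$counts)
  lengths_df <- read_tsv(config$lengths)
  lengths <- setNames(lengths_df$length, lengths_df$gene_id)
  pathways <- read_tsv(config$pathways)
  known_snps <- if (!is.null(config$known_snps) &&
                    file.exists(config$known_snps))
    read_tsv(config$known_snps) else NULL

  disc <- run_stage("discover", function() {
    cand <- read_candidate_vcf(config$vcf)
    d <- discover_editing_sites(cand, config$thresholds, known_snps)
    write_editing_sites(d$sites, p("sites.tsv"))
    write_tsv(d$report, p("filter_report.tsv"))
    d
  })
  es <- disc$sites

  ann <- run_stage("annotate", function() {
    a <- annotate_sites(es, models)
    write_tsv(a, p("annotated_sites.tsv"))
    s <- summarize_landscape(a)
    write_tsv(cbind(axis = rep(c("type", "region", "consequence"),
                               vapply(s, nrow, 1L)),
                    do.call(rbind, s)),
              p("landscape_summary.tsv"))
    a
  })

  diff_edit <- run_stage("diff-edit", function() {
    r <- differential_editing(es, models, design,
                              padj_threshold = config$padj_threshold,
                              annotation = ann)
    write_tsv(r, p("differential_editing.tsv"))
    r
  })

  diff_expr <- run_stage("diff-expr", function() {
    r <- differential_expression(counts, design,
                                 padj_threshold = config$padj_threshold,
                                 lfc_threshold = config$lfc_threshold_expr)
    write_tsv(r, p("differential_expression.tsv"))
    r
  })

  summ <- run_stage("summarize", function() {
    tp <- tpm(counts, lengths)
    write_tsv(data.frame(gene_id = rownames(tp), round(tp, 4),
                         check.names = FALSE), p("tpm.tsv"))
    sc <- sample_correlation(tp)
    write_tsv(data.frame(sample_id = rownames(sc), round(sc, 6),
                         check.names = FALSE), p("sample_correlation.tsv"))
    pca <- tryCatch(editing_pca(es$freq), error = function(e) NULL)
    if (!is.null(pca)) {
      write_tsv(data.frame(sample_id = rownames(pca$scores),
                           round(pca$scores, 6), check.names = FALSE),
                p("pca_scores.tsv"))
      write_tsv(data.frame(component = seq_along(pca$variance_pct),
                           variance_pct = round(pca$variance_pct, 4)),
                p("pca_scree.tsv"))
    }
    venn <- shared_events(es, design)
    write_tsv(venn, p("shared_events.tsv"))
    write_tsv(frequency_histogram(es, design), p("frequency_histogram.tsv"))
    list(tpm = tp, correlation = sc, pca = pca, venn = venn)
  })

  integ <- run_stage("integrate", function() {
    q <- nine_quadrant(diff_edit, diff_expr,
                       lfc_threshold_edit = config$lfc_threshold_edit,
                       lfc_threshold_expr = config$lfc_threshold_expr,
                       padj_threshold = config$padj_threshold)
    write_tsv(q, p("quadrants.tsv"))
    cands <- q$gene[q$candidate]
    write_tsv(data.frame(gene = cands), p("candidate_genes.tsv"))
    corr <- NULL
    if (!is.null(config$enzyme_gene) &&
        config$enzyme_gene %in% rownames(summ$tpm)) {
      targets <- setdiff(cands, config$enzyme_gene)
      targets <- intersect(targets, unique(ann$gene_id))
      if (length(targets)) {
        corr <- do.call(rbind, lapply(targets, function(g) {
          maf <- gene_maf(es, g, annotation = ann)
          r <- tryCatch(enzyme_correlation(
            summ$tpm[config$enzyme_gene, es$samples], maf[es$samples]),
            error = function(e) NULL)
          if (is.null(r)) return(NULL)
          data.frame(enzyme = config$enzyme_gene, target = g,
                     r = round(r$r, 6), p_value = r$p_value, n = r$n)
        }))
        if (!is.null(corr)) write_tsv(corr, p("enzyme_correlation.tsv"))
      }
    }
    list(quadrants = q, candidates = cands, correlation = corr)
  })

  enr <- run_stage("enrich", function() {
    e <- hypergeometric_enrichment(integ$candidates, pathways,
                                   fdr_threshold = config$enrichment_fdr)
    write_tsv(e, p("enrichment.tsv"))
    e
  })

  inputs <- c(config$vcf, config$fasta, config$gff3, config$counts,
              config$lengths, config$pathways, config$design)
  manifest <- list(
    package = "editlens",
    version = as.character(utils::packageVersion("editlens")),
    seed = config$seed,
    stages = stages,
    input_md5 = as.list(tools::md5sum(inputs)),
    rows = list(sites = nrow(es$sites),
                annotated = nrow(ann),
                differential_editing = nrow(diff_edit),
                differential_expression = nrow(diff_expr),
                quadrants = nrow(integ$quadrants),
                candidates = length(integ$candidates),
                enrichment = nrow(enr)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             p("manifest.json"))
  invisible(list(sites = es, annotation = ann, diff_edit = diff_edit,
                 diff_expr = diff_expr, summaries = summ,
                 integration = integ, enrichment = enr,
                 manifest = manifest))
}
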