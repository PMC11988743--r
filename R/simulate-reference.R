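#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-study generator. Defaults encode
#' the study design the pipeline targets: two groups (control "CON" and
#' endotoxin-treated "LPS") of three biological replicates, overdispersed
#' (negative-binomial) site coverage and expression counts, per-site editing
#' frequencies drawn from a broad 10--90% window, a subset of genes with
#' group-dependent editing and/or expression shifts, germline-SNP
#' confounders at allele frequency 0.5 or 1.0 in every sample, and one
#' designated "editing enzyme" gene whose per-sample expression linearly
#' drives the editing level of its target genes.
#'
#' @param n_genes number of genes to place on the synthetic contig
#' @param n_samples_per_group biological replicates per group (study used 3)
#' @param mean_depth mean per-site sequencing depth (reads)
#' @param depth_dispersion NB dispersion of per-site coverage
#'   (variance = m + dispersion * m^2)
#' @param editing_sites_per_gene Poisson mean of true editing sites per gene
#' @param baseline_editing_freq_range range of baseline per-site editing
#'   frequencies (uniform draw)
#' @param frac_diff_edited_genes proportion of genes with a group-dependent
#'   editing shift
#' @param editing_effect_log2fc log2 effect size applied to the editing
#'   frequency (hence alt-read counts) of differentially edited genes in the
#'   treatment group; frequencies are clamped to at most `freq_clamp`
#' @param frac_de_genes proportion of differentially expressed genes
#' @param expression_effect_log2fc log2 effect size on expression counts
#' @param frac_germline_snps proportion of candidate sites that are germline
#'   SNPs (frequency 0.5 or 1.0 in all samples)
#' @param type_prob_a2i,type_prob_c2u probability that a true editing site is
#'   A-to-I (A>G on the sense strand) / C-to-U (C>T); remainder is spread
#'   over the other ten mismatch classes
#' @param qc_violation_rate per-rule Bernoulli rate at which a candidate's QC
#'   metric is drawn from the failing side of the corresponding hard filter
#' @param bq_violation_rate rate of sites with mean alt base quality below 25
#' @param multiallelic_rate rate of sites corrupted to carry two alt alleles
#' @param expr_mean_log,expr_sd_log log-normal parameters of baseline gene
#'   expression means
#' @param expr_disp_asymp,expr_disp_shape parameters of the canonical
#'   mean-dispersion trend of expression counts,
#'   `alpha(mu) = expr_disp_asymp + expr_disp_shape / mu` (asymptotic
#'   gene-wise dispersion for highly expressed genes, and the shot-noise-like
#'   extra-Poisson component at low means)
#' @param enzyme_link_slope,enzyme_link_intercept parameters of the linear
#'   map from the enzyme's scaled expression to target-gene editing frequency
#' @param enzyme_link_noise_sd Gaussian noise sd on the enzyme->MAF link
#' @param n_enzyme_targets number of genes whose editing level is driven by
#'   the enzyme
#' @param freq_clamp upper clamp on simulated editing frequencies
#' @param seed integer seed; identical configs give byte-identical outputs
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_genes = 200,
                              n_samples_per_group = 3,
                              mean_depth = 150,
                              depth_dispersion = 0.15,
                              editing_sites_per_gene = 3,
                              baseline_editing_freq_range = c(0.10, 0.90),
                              frac_diff_edited_genes = 0.10,
                              editing_effect_log2fc = 2,
                              frac_de_genes = 0.10,
                              expression_effect_log2fc = 2,
                              frac_germline_snps = 0.10,
                              type_prob_a2i = 0.60,
                              type_prob_c2u = 0.20,
                              qc_violation_rate = 0.02,
                              bq_violation_rate = 0.02,
                              multiallelic_rate = 0.01,
                              expr_mean_log = log(300),
                              expr_sd_log = 1,
                              expr_disp_asymp = 0.01,
                              expr_disp_shape = 3,
                              enzyme_link_slope = 0.30,
                              enzyme_link_intercept = 0.10,
                              enzyme_link_noise_sd = 0.02,
                              n_enzyme_targets = 3,
                              freq_clamp = 0.95,
                              seed = 42L) {
  props <- c(frac_diff_edited_genes, frac_de_genes, frac_germline_snps,
             type_prob_a2i, type_prob_c2u, qc_violation_rate,
             bq_violation_rate, multiallelic_rate)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (type_prob_a2i + type_prob_c2u > 1)
    stop("type_prob_a2i + type_prob_c2u must not exceed 1")
  if (any(baseline_editing_freq_range < 0 | baseline_editing_freq_range > 1) ||
      diff(baseline_editing_freq_range) <= 0)
    stop("baseline_editing_freq_range must be an increasing range in [0, 1]")
  if (n_genes < 0 || n_samples_per_group < 2)
    stop("need n_genes >= 0 and n_samples_per_group >= 2")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# Split seed into per-stage substreams so candidate and expression draws are
# reproducible independently of each other.
stage_seed <- function(cfg, stage) {
  offset <- c(reference = 11L, candidates = 23L, expression = 37L,
              pathways = 53L)[[stage]]
  (cfg$seed * 101L + offset) %% 2147483647L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random CDS: start codon + non-stop codons + stop codon.
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste, collapse = "")
  body <- setdiff(all_codons, stops)
  if (n_codons > 2)
    codons[2:(n_codons - 1)] <- sample(body, n_codons - 2, replace = TRUE)
  codons[n_codons] <- sample(stops, 1)
  paste(codons, collapse = "")
}

#' Generate a synthetic reference genome with gene models
#'
#' Places `n_genes` non-overlapping protein-coding genes on one contig.
#' Each gene has 1--3 exons; its spliced mRNA is 5'UTR + CDS + 3'UTR, with
#' the CDS a multiple of 3, beginning with ATG and ending in a stop codon.
#' Strand is assigned at random; minus-strand genes are reverse-complemented
#' into the genome.
#'
#' @param config a [simulation_config()]
#' @return object of class `gene_models`: list with `genome`
#'   (a [Biostrings::DNAStringSet]), `genes`, `exons`, `cds`
#'   ([GenomicRanges::GRanges] carrying `gene_id`), and `gene_table`
#'   (data.frame of gene_id, strand, tx_length, cds_length)
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config, "reference"))
  n <- config$n_genes
  gap <- 1500L   # intergenic gap > default upstream/downstream windows
  utr <- 60L
  intron_len <- 200L

  gene_rows <- vector("list", n)
  seq_parts <- character(0)
  cursor <- 0L
  exon_list <- list(); cds_list <- list()
  seq_parts <- c(seq_parts, random_dna(gap)); cursor <- gap

  for (i in seq_len(n)) {
    gid <- sprintf("gene%04d", i)
    strand <- sample(c("+", "-"), 1)
    n_codons <- sample(100:300, 1)
    cds_seq <- random_cds(n_codons)
    mrna <- paste0(random_dna(utr), cds_seq, random_dna(utr))
    mrna_len <- nchar(mrna)
    n_exons <- sample(1:3, 1)
    # exon cut points on the spliced mRNA (sense orientation)
    if (n_exons > 1) {
      cuts <- sort(sample(seq(50L, mrna_len - 50L), n_exons - 1))
    } else cuts <- integer(0)
    ex_start <- c(1L, cuts + 1L)
    ex_end <- c(cuts, mrna_len)
    ex_seqs <- substring(mrna, ex_start, ex_end)
    introns <- replicate(max(0, n_exons - 1), random_dna(intron_len))
    genomic_sense <- paste0(paste0(ex_seqs[-n_exons], introns, collapse = ""),
                            ex_seqs[n_exons])
    if (n_exons == 1) genomic_sense <- ex_seqs[1]
    glen <- nchar(genomic_sense)
    gstart <- cursor + 1L
    gend <- cursor + glen

    # genomic exon coordinates in sense orientation, offsets within the gene
    off <- cumsum(c(0L, head(ex_end - ex_start + 1L, -1) + intron_len))
    sense_ex_start <- off + 1L
    sense_ex_end <- off + (ex_end - ex_start + 1L)
    # mRNA coordinates of CDS
    cds_m_start <- utr + 1L
    cds_m_end <- utr + nchar(cds_seq)
    # map an mRNA coordinate to a sense-gene genomic offset
    m2g <- function(m) {
      k <- findInterval(m, ex_start)
      sense_ex_start[k] + (m - ex_start[k])
    }
    # CDS segments per exon (sense coords within gene)
    cds_segs <- lapply(seq_len(n_exons), function(k) {
      s <- max(ex_start[k], cds_m_start); e <- min(ex_end[k], cds_m_end)
      if (s > e) return(NULL)
      c(m2g(s), m2g(e))
    })
    cds_segs <- do.call(rbind, cds_segs)

    if (strand == "+") {
      gseq <- genomic_sense
      ex_g_start <- gstart - 1L + sense_ex_start
      ex_g_end <- gstart - 1L + sense_ex_end
      cds_g <- cbind(gstart - 1L + cds_segs[, 1], gstart - 1L + cds_segs[, 2])
    } else {
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(genomic_sense)))
      ex_g_start <- gend + 1L - sense_ex_end
      ex_g_end <- gend + 1L - sense_ex_start
      cds_g <- cbind(gend + 1L - cds_segs[, 2], gend + 1L - cds_segs[, 1])
    }

    seq_parts <- c(seq_parts, gseq, random_dna(gap))
    cursor <- gend + gap

    gene_rows[[i]] <- data.frame(
      gene_id = gid, start = gstart, end = gend, strand = strand,
      tx_length = mrna_len, cds_length = nchar(cds_seq),
      stringsAsFactors = FALSE)
    exon_list[[i]] <- data.frame(gene_id = gid, start = ex_g_start,
                                 end = ex_g_end, strand = strand)
    cds_list[[i]] <- data.frame(gene_id = gid, start = cds_g[, 1],
                                end = cds_g[, 2], strand = strand)
  }

  contig <- paste(seq_parts, collapse = "")
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "chrS"
  gene_table <- if (n > 0) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(), start = integer(), end = integer(),
               strand = character(), tx_length = integer(),
               cds_length = integer())

  mk_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0)
      return(GenomicRanges::GRanges(seqnames = character(0),
                                    ranges = IRanges::IRanges(),
                                    gene_id = character(0)))
    GenomicRanges::GRanges("chrS",
                           IRanges::IRanges(df$start, df$end),
                           strand = df$strand, gene_id = df$gene_id)
  }
  genes <- mk_gr(gene_table)
  exons <- mk_gr(if (n > 0) do.call(rbind, exon_list) else NULL)
  cds <- mk_gr(if (n > 0) do.call(rbind, cds_list) else NULL)
  S4Vectors::mcols(genes)$gene_type <- rep("protein_coding", length(genes))

  structure(list(genome = genome, genes = genes, exons = exons, cds = cds,
                 gene_table = gene_table),
            class = "gene_models")
}

#' Extract the spliced CDS sequence of one gene (sense orientation)
#' @param models a `gene_models` object
#' @param gene_id gene identifier
#' @return character CDS sequence (starts ATG, ends in a stop codon)
#' @export
gene_cds_seq <- function(models, gene_id) {
  cds <- models$cds[S4Vectors::mcols(models$cds)$gene_id == gene_id]
  if (length(cds) == 0) stop("gene has no CDS: ", gene_id)
  cds <- sort(cds)
  segs <- as.character(Biostrings::extractAt(
    models$genome[[1]],
    IRanges::IRanges(GenomicRanges::start(cds), GenomicRanges::end(cds))))
  s <- paste(segs, collapse = "")
  if (as.character(GenomicRanges::strand(cds))[1] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Write reference FASTA and GFF3 gene models
#' @param models a `gene_models` object
#' @param fasta,gff3 output paths
#' @return invisibly, the two paths
#' @export
write_gene_models <- function(models, fasta, gff3) {
  Biostrings::writeXStringSet(models$genome, fasta)
  cds <- models$cds
  gid <- S4Vectors::mcols(cds)$gene_id
  phase <- rep(0L, length(cds))
  for (g in unique(gid)) {
    k <- which(gid == g)
    st <- as.character(GenomicRanges::strand(cds))[k[1]]
    o <- order(GenomicRanges::start(cds)[k], decreasing = (st == "-"))
    w <- GenomicRanges::width(cds)[k][o]
    phase[k[o]] <- (3L - cumsum(c(0L, head(w, -1))) %% 3L) %% 3L
  }
  feats <- c(
    local({ g <- models$genes; S4Vectors::mcols(g)$type <- "gene"; g }),
    local({ g <- models$exons; S4Vectors::mcols(g)$type <- "exon"; g }),
    local({ g <- cds; S4Vectors::mcols(g)$type <- "CDS"
            S4Vectors::mcols(g)$phase <- phase; g }))
  S4Vectors::mcols(feats)$ID <- paste0(
    S4Vectors::mcols(feats)$gene_id, "_",
    S4Vectors::mcols(feats)$type, "_", seq_along(feats))
  S4Vectors::mcols(feats)$type <- factor(S4Vectors::mcols(feats)$type)
  rtracklayer::export(sort(feats), gff3, format = "gff3")
  invisible(c(fasta, gff3))
}

#' Read gene models back from FASTA + GFF3
#' @param fasta,gff3 input paths
#' @return a `gene_models` object
#' @export
read_gene_models <- function(fasta, gff3) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3, format = "gff3")
  typ <- as.character(S4Vectors::mcols(gr)$type)
  genes <- gr[typ == "gene"]
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  keep <- function(g) {
    m <- S4Vectors::mcols(g)
    S4Vectors::mcols(g) <- NULL
    S4Vectors::mcols(g)$gene_id <- as.character(m$gene_id)
    g
  }
  genes <- keep(genes); exons <- keep(exons); cds <- keep(cds)
  S4Vectors::mcols(genes)$gene_type <- "protein_coding"
  cdsw <- tapply(GenomicRanges::width(cds),
                 S4Vectors::mcols(cds)$gene_id, sum)
  txw <- tapply(GenomicRanges::width(exons),
                S4Vectors::mcols(exons)$gene_id, sum)
  gt <- data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id,
    start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    stringsAsFactors = FALSE)
  gt$tx_length <- as.integer(txw[gt$gene_id])
  gt$cds_length <- as.integer(cdsw[gt$gene_id])
  structure(list(genome = genome, genes = genes, exons = exons, cds = cds,
                 gene_table = gt),
            class = "gene_models")
}
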