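#' Classify the editing (mismatch) type of a site, collapsed by strand
#'
#' On minus-strand genes the genomic ref/alt pair is complemented before
#' naming, so the reported pair is in transcript orientation. A>G (after
#' strand adjustment) is A-to-I (adenosine deamination read as guanosine);
#' C>T is C-to-U (cytidine deamination). All other pairs keep their
#' "X-to-Y" mismatch name. For `strand = "*"` (unknown) the genomic pair is
#' reported and collapsed under the convention A>G / T>C => A-to-I and
#' C>T / G>A => C-to-U.
#'
#' @param ref_base,alt_base genomic bases (A/C/G/T), vectorized
#' @param gene_strand "+", "-" or "*" per site
#' @return data.frame with `mismatch_type` (strand-adjusted "X>Y") and
#'   `collapsed_type` ("A-to-I", "C-to-U" or "X-to-Y")
#' @export
classify_editing_type <- function(ref_base, alt_base, gene_strand = "+") {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (!all(ref_base %in% names(COMPLEMENT)) ||
      !all(alt_base %in% names(COMPLEMENT)))
    stop("bases must be A, C, G or T")
  if (any(ref_base == alt_base)) stop("ref and alt must differ")
  n <- max(length(ref_base), length(alt_base), length(gene_strand))
  ref_base <- rep_len(ref_base, n); alt_base <- rep_len(alt_base, n)
  gene_strand <- rep_len(gene_strand, n)
  minus <- gene_strand == "-"
  r <- ifelse(minus, COMPLEMENT[ref_base], ref_base)
  a <- ifelse(minus, COMPLEMENT[alt_base], alt_base)
  pair <- paste0(r, ">", a)
  collapsed <- paste0(r, "-to-", a)
  collapsed[pair == "A>G"] <- "A-to-I"
  collapsed[pair == "C>T"] <- "C-to-U"
  # unknown strand: collapse either orientation of the deamination pairs
  unk <- gene_strand == "*"
  collapsed[unk & pair %in% c("A>G", "T>C")] <- "A-to-I"
  collapsed[unk & pair %in% c("C>T", "G>A")] <- "C-to-U"
  data.frame(mismatch_type = pair, collapsed_type = collapsed,
             stringsAsFactors = FALSE)
}

REGION_LEVELS <- c("splicing", "exonic", "UTR5", "UTR3", "intronic",
                   "ncRNA_exonic", "ncRNA_intronic", "upstream",
                   "downstream", "intergenic")

#' Annotate the genomic region of each site
#'
#' Assigns exactly one region label per site under the precedence
#' splicing > exonic > UTR5/UTR3 > intronic > ncRNA_exonic >
#' ncRNA_intronic > upstream > downstream > intergenic. "exonic" means
#' CDS-overlapping exon of a coding gene; exon positions outside the CDS are
#' UTR5/UTR3 by side and strand. "splicing" means within `splice_window` nt
#' of an exon-intron boundary, inside the intron. Upstream/downstream are
#' strand-aware windows beyond the gene body. Sites on contigs absent from
#' the models are intergenic (with a warning).
#'
#' @param sites data.frame with contig, pos (1-based)
#' @param models a `gene_models` object; genes carry a `gene_type` mcol
#'   ("protein_coding" or "ncRNA")
#' @param upstream_window,downstream_window window sizes in bp
#' @param splice_window splice-region width in nt
#' @return character vector of region labels, one per site
#' @export
annotate_region <- function(sites, models, upstream_window = 1000,
                            downstream_window = 1000, splice_window = 2) {
  known <- sites$contig %in%
    unique(as.character(GenomicRanges::seqnames(models$genes))) |
    sites$contig %in% names(models$genome)
  if (!all(known))
    warning(sum(!known), " site(s) on unknown contigs set to intergenic")
  gr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$pos, sites$pos))
  n <- length(gr)
  region <- rep(NA_character_, n)

  genes <- models$genes
  gtype <- S4Vectors::mcols(genes)$gene_type %||%
    rep("protein_coding", length(genes))
  coding_ids <- S4Vectors::mcols(genes)$gene_id[gtype == "protein_coding"]
  ex_gene <- S4Vectors::mcols(models$exons)$gene_id
  exons_c <- models$exons[ex_gene %in% coding_ids]
  exons_nc <- models$exons[!ex_gene %in% coding_ids]
  genes_c <- genes[gtype == "protein_coding"]
  genes_nc <- genes[gtype != "protein_coding"]

  hit <- function(subject) {
    if (length(subject) == 0) return(rep(FALSE, n))
    suppressWarnings(
      IRanges::overlapsAny(gr, subject, ignore.strand = TRUE))
  }
  assign_region <- function(mask, label) {
    region[is.na(region) & mask] <<- label
  }

  # splicing: inside an intron, within splice_window of either boundary
  introns_near <- local({
    segs <- list()
    for (gid in unique(ex_gene)) {
      ex <- sort(models$exons[ex_gene == gid])
      if (length(ex) < 2) next
      for (k in seq_len(length(ex) - 1)) {
        i_start <- GenomicRanges::end(ex)[k] + 1L
        i_end <- GenomicRanges::start(ex)[k + 1] - 1L
        if (i_start > i_end) next
        left <- IRanges::IRanges(i_start,
                                 min(i_end, i_start + splice_window - 1L))
        right <- IRanges::IRanges(max(i_start, i_end - splice_window + 1L),
                                  i_end)
        segs[[length(segs) + 1]] <- GenomicRanges::GRanges(
          as.character(GenomicRanges::seqnames(ex))[1],
          c(left, right))
      }
    }
    if (length(segs)) do.call(c, segs) else GenomicRanges::GRanges()
  })
  assign_region(hit(introns_near), "splicing")
  assign_region(hit(models$cds), "exonic")

  # UTRs: coding-gene exon positions outside the CDS, sided by strand
  if (length(exons_c)) {
    utr <- GenomicRanges::setdiff(
      GenomicRanges::reduce(exons_c, ignore.strand = FALSE),
      GenomicRanges::reduce(models$cds, ignore.strand = FALSE),
      ignore.strand = FALSE)
    if (length(utr)) {
      ov <- suppressWarnings(
        GenomicRanges::findOverlaps(gr, utr, ignore.strand = TRUE))
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        # side relative to the gene's CDS span
        lab <- vapply(seq_along(qh), function(k) {
          p <- sites$pos[qh[k]]
          og <- suppressWarnings(GenomicRanges::findOverlaps(
            gr[qh[k]], genes_c, ignore.strand = TRUE))
          if (!length(og)) return(NA_character_)
          gid <- S4Vectors::mcols(genes_c)$gene_id[
            S4Vectors::subjectHits(og)[1]]
          cg <- models$cds[S4Vectors::mcols(models$cds)$gene_id == gid]
          if (!length(cg)) return(NA_character_)
          st <- as.character(GenomicRanges::strand(cg))[1]
          before <- p < min(GenomicRanges::start(cg))
          if (st == "+") { if (before) "UTR5" else "UTR3" }
          else { if (before) "UTR3" else "UTR5" }
        }, character(1))
        for (k in seq_along(qh)) {
          if (is.na(region[qh[k]]) && !is.na(lab[k]))
            region[qh[k]] <- lab[k]
        }
      }
    }
  }
  assign_region(hit(genes_c), "intronic")  # inside coding gene, not exonic
  assign_region(hit(exons_nc), "ncRNA_exonic")
  assign_region(hit(genes_nc), "ncRNA_intronic")

  flank <- function(g, width, side) {
    if (length(g) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::trim(GenomicRanges::flank(
      g, width, start = (side == "up"), ignore.strand = FALSE))
  }
  assign_region(hit(flank(genes, upstream_window, "up")), "upstream")
  assign_region(hit(flank(genes, downstream_window, "down")), "downstream")
  region[is.na(region)] <- "intergenic"
  region[!known] <- "intergenic"
  region
}

#' Coding consequence of a single-base edit within a CDS
#'
#' Translates the affected codon before and after the edit with the
#' standard genetic code: same amino acid = synonymous, different non-stop =
#' nonsynonymous, non-stop to stop = stopgain, stop to non-stop = stoploss.
#'
#' @param cds_sequence spliced CDS in sense orientation (character or
#'   [Biostrings::DNAString]); length must be a multiple of 3
#' @param cds_position 0-based offset of the edited base within the CDS
#' @param alt_base the edited base in CDS (sense) orientation
#' @return one of "synonymous", "nonsynonymous", "stopgain", "stoploss"
#' @export
coding_consequence <- function(cds_sequence, cds_position, alt_base) {
  s <- toupper(as.character(cds_sequence))
  L <- nchar(s)
  if (L %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (cds_position < 0 || cds_position >= L)
    stop("cds_position out of range")
  codon_i <- cds_position %/% 3
  off <- cds_position %% 3
  codon <- substr(s, codon_i * 3 + 1, codon_i * 3 + 3)
  ref_b <- substr(codon, off + 1, off + 1)
  if (ref_b == toupper(alt_base))
    stop("alt base equals the CDS reference base")
  new_codon <- codon
  substr(new_codon, off + 1, off + 1) <- toupper(alt_base)
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[new_codon]]
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_ref != "*" && aa_alt == "*") "stopgain"
  else if (aa_ref == "*" && aa_alt != "*") "stoploss"
  else "nonsynonymous"
}

# map genomic positions to (gene_id, 0-based CDS offset); NA where not in CDS
cds_offset_map <- function(models) {
  cds <- models$cds
  gid <- S4Vectors::mcols(cds)$gene_id
  maps <- list()
  for (g in unique(gid)) {
    cg <- sort(cds[gid == g])
    st <- as.character(GenomicRanges::strand(cg))[1]
    w <- GenomicRanges::width(cg)
    if (st == "+") {
      cum <- cumsum(c(0L, head(w, -1)))
      maps[[g]] <- list(strand = st,
                        start = GenomicRanges::start(cg),
                        end = GenomicRanges::end(cg), cum = cum)
    } else {
      # CDS order along transcript = descending genomic order
      o <- order(GenomicRanges::start(cg), decreasing = TRUE)
      cum <- cumsum(c(0L, head(w[o], -1)))
      maps[[g]] <- list(strand = st,
                        start = GenomicRanges::start(cg)[o],
                        end = GenomicRanges::end(cg)[o], cum = cum)
    }
  }
  maps
}

cds_offset <- function(map, pos) {
  for (k in seq_along(map$start)) {
    if (pos >= map$start[k] && pos <= map$end[k]) {
      return(if (map$strand == "+") map$cum[k] + (pos - map$start[k])
             else map$cum[k] + (map$end[k] - pos))
    }
  }
  NA_integer_
}

#' Fully annotate editing sites
#'
#' Adds gene assignment (site inside a gene body; overlaps resolved to the
#' gene with the longest CDS, ties by gene id), strand-collapsed editing
#' type, region label and coding consequence ("noncoding" outside
#' CDS-overlapping exons) to an [editing_sites()] object.
#'
#' @param es an [editing_sites()]
#' @param models a `gene_models` object
#' @param upstream_window,downstream_window,splice_window see
#'   [annotate_region()]
#' @return data.frame: one row per site with gene_id, strand,
#'   mismatch_type, collapsed_type, region, consequence
#' @export
annotate_sites <- function(es, models, upstream_window = 1000,
                           downstream_window = 1000, splice_window = 2) {
  sites <- es$sites
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  strand <- rep("*", n)
  if (n > 0 && length(models$genes) > 0) {
    gr <- GenomicRanges::GRanges(sites$contig,
                                 IRanges::IRanges(sites$pos, sites$pos))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, models$genes, ignore.strand = TRUE))
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      cand_gid <- S4Vectors::mcols(models$genes)$gene_id[sh]
      cdsl <- models$gene_table$cds_length[
        match(cand_gid, models$gene_table$gene_id)]
      cdsl[is.na(cdsl)] <- 0L
      ord <- order(qh, -cdsl, cand_gid)   # longest CDS, tie by gene id
      qh <- qh[ord]; cand_gid <- cand_gid[ord]; sh <- sh[ord]
      first <- !duplicated(qh)
      gene_id[qh[first]] <- cand_gid[first]
      strand[qh[first]] <- as.character(
        GenomicRanges::strand(models$genes))[sh[first]]
    }
  }
  typ <- if (n > 0)
    classify_editing_type(sites$ref, sites$alt, strand)
  else data.frame(mismatch_type = character(), collapsed_type = character())
  region <- if (n > 0)
    annotate_region(sites, models, upstream_window, downstream_window,
                    splice_window)
  else character()

  consequence <- rep("noncoding", n)
  if (n > 0) {
    maps <- cds_offset_map(models)
    for (i in which(region == "exonic" & !is.na(gene_id))) {
      map <- maps[[gene_id[i]]]
      if (is.null(map)) next
      off <- cds_offset(map, sites$pos[i])
      if (is.na(off)) next
      cds_seq <- gene_cds_seq(models, gene_id[i])
      alt_sense <- if (map$strand == "-") COMPLEMENT[[sites$alt[i]]]
                   else sites$alt[i]
      # a site whose alt equals the model's CDS base is inconsistent with
      # the reference (e.g. stale FASTA); leave it unclassified
      if (substr(cds_seq, off + 1, off + 1) == alt_sense) next
      consequence[i] <- coding_consequence(cds_seq, off, alt_sense)
    }
  }
  cbind(sites,
        data.frame(gene_id = gene_id, strand = strand,
                   mismatch_type = typ$mismatch_type,
                   collapsed_type = typ$collapsed_type,
                   region = region, consequence = consequence,
                   stringsAsFactors = FALSE))
}

#' Summarize the editing landscape
#'
#' Proportions of sites by collapsed editing type and by region (UTR labels
#' folded into "exonic" for the summary), and counts by coding consequence.
#'
#' @param annotated data.frame from [annotate_sites()]
#' @return list of data.frames `by_type`, `by_region`, `by_consequence`;
#'   proportions sum to 1 within each axis; empty input gives empty tables
#' @export
summarize_landscape <- function(annotated) {
  if (nrow(annotated) == 0) {
    e <- data.frame(label = character(), count = integer(),
                    proportion = numeric())
    return(list(by_type = e, by_region = e, by_consequence = e))
  }
  prop_table <- function(x, levels = NULL) {
    tab <- table(x)
    df <- data.frame(label = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df$proportion <- df$count / sum(df$count)
    if (!is.null(levels))
      df <- df[order(match(df$label, levels)), , drop = FALSE]
    else df <- df[order(-df$count, df$label), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  region_folded <- annotated$region
  region_folded[region_folded %in% c("UTR5", "UTR3")] <- "exonic"
  list(by_type = prop_table(annotated$collapsed_type),
       by_region = prop_table(region_folded, REGION_LEVELS),
       by_consequence = prop_table(annotated$consequence))
}
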