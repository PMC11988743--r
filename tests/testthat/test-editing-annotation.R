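COMP <- c(A = "T", C = "G", G = "C", T = "A")

test_that("strand collapsing matches the reverse-complement oracle on all 24 cases", {
  bases <- c("A", "C", "G", "T")
  for (r in bases) for (a in setdiff(bases, r)) {
    plus <- classify_editing_type(r, a, "+")
    minus <- classify_editing_type(r, a, "-")
    # oracle: complement both bases, then name on the plus strand
    oracle_minus <- classify_editing_type(COMP[[r]], COMP[[a]], "+")
    expect_equal(minus$collapsed_type, oracle_minus$collapsed_type,
                 label = paste(r, a))
    expect_equal(minus$mismatch_type, oracle_minus$mismatch_type)
    # collapsed naming on + strand
    expected <- if (r == "A" && a == "G") "A-to-I"
    else if (r == "C" && a == "T") "C-to-U"
    else paste0(r, "-to-", a)
    expect_equal(plus$collapsed_type, expected)
  }
  # deamination events
  expect_equal(classify_editing_type("A", "G", "+")$collapsed_type, "A-to-I")
  expect_equal(classify_editing_type("C", "T", "+")$collapsed_type, "C-to-U")
  expect_equal(classify_editing_type("T", "C", "-")$collapsed_type, "A-to-I")
  expect_equal(classify_editing_type("G", "A", "-")$collapsed_type, "C-to-U")
  # unknown strand collapses either orientation
  expect_equal(classify_editing_type("T", "C", "*")$collapsed_type, "A-to-I")
  expect_equal(classify_editing_type("G", "A", "*")$collapsed_type, "C-to-U")
  expect_error(classify_editing_type("A", "A", "+"), "differ")
  expect_error(classify_editing_type("N", "A", "+"), "bases")
})

test_that("coding consequences match an exhaustive genetic-code oracle", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  # independent oracle via Biostrings::translate on the raw codons
  aa_of <- function(cdn) as.character(
    Biostrings::translate(Biostrings::DNAString(cdn),
                          no.init.codon = TRUE, if.fuzzy.codon = "error"))
  for (cdn in codons) {
    for (p in 1:3) for (b in setdiff(bases, substr(cdn, p, p))) {
      new <- cdn; substr(new, p, p) <- b
      a1 <- aa_of(cdn); a2 <- aa_of(new)
      oracle <- if (a1 == a2) "synonymous"
      else if (a1 != "*" && a2 == "*") "stopgain"
      else if (a1 == "*" && a2 != "*") "stoploss"
      else "nonsynonymous"
      got <- coding_consequence(cdn, p - 1L, b)
      expect_equal(got, oracle, label = paste(cdn, p, b))
    }
  }
  # named examples
  expect_equal(coding_consequence("AAA", 2, "G"), "synonymous")   # AAA->AAG
  expect_equal(coding_consequence("CAA", 0, "T"), "stopgain")     # CAA->TAA
  expect_equal(coding_consequence("TGA", 0, "C"), "stoploss")     # TGA->CGA
  expect_error(coding_consequence("AAA", 3, "G"), "range")
  expect_error(coding_consequence("AAAA", 0, "G"), "multiple of 3")
})

test_that("region annotation follows the documented precedence", {
  m <- toy_models()
  site <- function(pos) data.frame(contig = "chrS", pos = pos)
  reg <- function(pos, ...) annotate_region(site(pos), m, ...)
  expect_equal(reg(1300), "exonic")         # CDS exon, far from boundary
  expect_equal(reg(1230), "UTR5")
  expect_equal(reg(1630), "UTR3")
  expect_equal(reg(1440), "intronic")       # intron middle
  # splice window: 1-2 nt inside the intron next to either exon boundary
  expect_equal(reg(1381), "splicing")
  expect_equal(reg(1382), "splicing")
  expect_equal(reg(1383), "intronic")
  expect_equal(reg(1480), "splicing")
  expect_equal(reg(1479), "splicing")
  expect_equal(reg(1478), "intronic")
  expect_equal(reg(1479, splice_window = 1), "intronic")
  # upstream window (plus strand: 5' of gene start)
  expect_equal(reg(1200), "upstream")
  expect_equal(reg(1201 - 999), "upstream")
  expect_equal(reg(150), "intergenic")      # beyond 1000 bp window
  expect_equal(reg(1661), "downstream")
  # ncRNA gene regions
  expect_equal(reg(3020), "ncRNA_exonic")
  expect_equal(reg(3100), "ncRNA_intronic")
  # unknown contig -> intergenic with warning
  expect_warning(r <- annotate_region(
    data.frame(contig = "chrX", pos = 5), m), "unknown")
  expect_equal(r, "intergenic")
  # precedence is total: one label per site
  pos_grid <- seq(1, 3400, by = 7)
  labels <- annotate_region(site(pos_grid), m)
  expect_equal(length(labels), length(pos_grid))
  expect_false(any(is.na(labels)))
})

test_that("annotate_sites maps CDS offsets and consequences correctly", {
  m <- toy_models()
  cds <- gene_cds_seq(m, "gplus")
  # genomic 1261 is CDS offset 0 ("A" of ATG); editing A>G at offset 0:
  # ATG -> GTG, Met -> Val = nonsynonymous
  df <- data.frame(contig = "chrS", pos = c(1261L, 1300L, 3020L),
                   ref = c("A", substr(cds, 40, 40), "A"),
                   alt = c("G", setdiff(c("A", "C", "G", "T"),
                                        substr(cds, 40, 40))[1], "G"),
                   base_quality = 35)
  es <- make_sites(df, matrix(20L, 3, 2), matrix(6L, 3, 2), c("S1", "S2"))
  ann <- annotate_sites(es, m)
  expect_equal(ann$gene_id, c("gplus", "gplus", "gnc"))
  expect_equal(ann$region, c("exonic", "exonic", "ncRNA_exonic"))
  expect_equal(ann$consequence[1], "nonsynonymous")
  # site 2: offset 39, oracle from the CDS sequence itself
  oracle <- coding_consequence(cds, 39L, df$alt[2])
  expect_equal(ann$consequence[2], oracle)
  expect_equal(ann$consequence[3], "noncoding")
})

test_that("landscape summaries are exact, order-invariant and calibrated", {
  ann <- data.frame(
    collapsed_type = c("A-to-I", "A-to-I", "C-to-U", "G-to-T"),
    region = c("exonic", "UTR5", "intronic", "upstream"),
    consequence = c("synonymous", "nonsynonymous", "noncoding", "noncoding"))
  s <- summarize_landscape(ann)
  expect_equal(s$by_type$proportion[s$by_type$label == "A-to-I"], 0.50)
  expect_equal(sort(s$by_type$proportion), c(0.25, 0.25, 0.50))
  expect_equal(sum(s$by_region$proportion), 1)
  # UTR folded into exonic for the summary axis
  expect_equal(s$by_region$count[s$by_region$label == "exonic"], 2L)
  perm <- summarize_landscape(ann[c(3, 1, 4, 2), ])
  expect_equal(perm, s)
  expect_equal(nrow(summarize_landscape(ann[0, ])$by_type), 0)

  # configured 60/20 editing-type mix is recovered at 10k sites
  big <- clean_big_study()
  disc <- discover_editing_sites(
    big$sim$candidates,
    known_snps = big$sim$truth$sites[big$sim$truth$sites$status == "SNP",
                                     c("contig", "pos")])
  anns <- cached("big_annotation", function()
    annotate_sites(disc$sites, big$models))
  ss <- summarize_landscape(anns)
  p_a2i <- ss$by_type$proportion[ss$by_type$label == "A-to-I"]
  p_c2u <- ss$by_type$proportion[ss$by_type$label == "C-to-U"]
  expect_lt(abs(p_a2i - 0.60), 0.03)
  expect_lt(abs(p_c2u - 0.20), 0.03)
})
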