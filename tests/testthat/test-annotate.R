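# A hand-built two-exon gene on a 200 bp toy chromosome:
#   tx 51..130 (+), exon1 51..80, intron 81..100, exon2 101..130,
#   CDS 57..80 + 101..124, 5'UTR 51..56, 3'UTR 125..130.
# The CDS starts with codons ATT (Ile), CTG (Leu), TAC (Tyr).
toy_gene <- function() {
  set.seed(500)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  substr(s, 57, 65) <- "ATTCTGTAC"
  models <- gene_models(
    genes = data.frame(gene_id = "toy1", chrom = "chrT", strand = "+",
                       tx_start = 51L, tx_end = 130L,
                       stringsAsFactors = FALSE),
    features = data.frame(
      gene_id = "toy1", type = c("exon", "exon", "CDS", "CDS"),
      start = c(51L, 101L, 57L, 101L), end = c(80L, 130L, 80L, 124L),
      stringsAsFactors = FALSE))
  list(seq = c(chrT = s), models = models)
}

toy_variant <- function(pos, ref, alt) {
  small_variants(data.frame(sample_id = "s", chrom = "chrT", pos = pos,
                            ref = ref, alt = alt, depth = 60L,
                            quality = 200, stringsAsFactors = FALSE))
}

test_that("gene regions follow the precedence splice > CDS > UTR > promoter > intron", {
  tg <- toy_gene()
  at <- function(pos, ref = substr(tg$seq[["chrT"]], pos, pos), alt = NULL) {
    if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    assign_region(toy_variant(pos, ref, alt), tg$models)
  }
  expect_equal(at(60)$region, "exonic")
  expect_equal(at(81)$region, "splice_site")   # 1 bp into the intron
  expect_equal(at(82)$region, "splice_site")   # 2 bp window
  expect_equal(at(90)$region, "intronic")
  expect_equal(at(100)$region, "splice_site")  # intron 3' flank
  expect_equal(at(53)$region, "utr5")
  expect_equal(at(127)$region, "utr3")
  expect_equal(at(30)$region, "promoter")
  expect_equal(nrow(at(170)), 0L)              # intergenic: no gene hit
})

test_that("an interval spanning several genes reports every gene", {
  cfg <- sim_config(seed = 13, n_genes = 12, n_gene_sets = 2,
                    genes_per_set = 3, chromosome_length_bp = 400000L)
  ref <- simulate_reference(cfg)
  g <- ref$genes$genes
  g1 <- g[g$chrom == "chr1", , drop = FALSE]
  g1 <- g1[order(g1$tx_start), , drop = FALSE]
  span <- data.frame(chrom = "chr1", start = g1$tx_start[1] - 1L,
                     end = g1$tx_end[3] + 10L)
  hits <- genes_hit_by_intervals(span, ref$genes)
  expect_true(all(g1$gene_id[1:3] %in% hits$gene_id))
  expect_equal(nrow(hits), 3L)
})

test_that("codon translation identifies missense, synonymous and stop gain", {
  tg <- toy_gene()
  # ATT (Ile) -> AGT (Ser) via T>G at codon position 2
  expect_equal(translational_impact(toy_variant(58, "T", "G"), "toy1",
                                    tg$models, tg$seq), "missense")
  # CTG (Leu) -> CTA (Leu)
  expect_equal(translational_impact(toy_variant(62, "G", "A"), "toy1",
                                    tg$models, tg$seq), "synonymous")
  # TAC (Tyr) -> TAA (*)
  expect_equal(translational_impact(toy_variant(65, "C", "A"), "toy1",
                                    tg$models, tg$seq), "stop_gain")
})

test_that("frameshift is exactly net length change not divisible by 3", {
  tg <- toy_gene()
  s <- tg$seq[["chrT"]]
  for (L in 1:9) {
    del <- toy_variant(66, substr(s, 66, 66 + L), substr(s, 66, 66))
    want <- if (L %% 3 == 0) "in_frame" else "frameshift"
    expect_equal(translational_impact(del, "toy1", tg$models, tg$seq), want)
  }
  ins <- toy_variant(70, substr(s, 70, 70), paste0(substr(s, 70, 70), "A"))
  expect_equal(translational_impact(ins, "toy1", tg$models, tg$seq),
               "frameshift")
})

test_that("a variant crossing the CDS boundary is flagged complex", {
  tg <- toy_gene()
  s <- tg$seq[["chrT"]]
  cross <- toy_variant(78, substr(s, 78, 84), substr(s, 78, 78))
  expect_warning(
    impact <- translational_impact(cross, "toy1", tg$models, tg$seq),
    "CDS boundary")
  expect_equal(impact, "complex")
})

test_that("minus-strand impact equals the reverse-complement computation", {
  tg <- toy_gene()
  L <- 200L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  seq_rc <- c(chrT = rc(tg$seq[["chrT"]]))
  mirror <- function(p) L + 1L - p
  f <- tg$models$features
  models_rc <- gene_models(
    genes = data.frame(gene_id = "toy1", chrom = "chrT", strand = "-",
                       tx_start = mirror(130L), tx_end = mirror(51L),
                       stringsAsFactors = FALSE),
    features = data.frame(gene_id = "toy1", type = f$type,
                          start = mirror(f$end), end = mirror(f$start),
                          stringsAsFactors = FALSE))
  for (case in list(c(58, "T", "G"), c(62, "G", "A"), c(65, "C", "A"))) {
    p <- as.integer(case[1])
    plus_impact <- translational_impact(
      toy_variant(p, case[2], case[3]), "toy1", tg$models, tg$seq)
    minus_impact <- translational_impact(
      toy_variant(mirror(p), comp[[case[2]]], comp[[case[3]]]),
      "toy1", models_rc, seq_rc)
    expect_equal(minus_impact, plus_impact)
  }
})

test_that("population flags follow presence in any frequency table", {
  keys <- sprintf("chr1:%d:A:G", 1:82)
  tb <- data.frame(key = keys[1:51], freq = runif(51, 0.01, 0.4))
  flags <- flag_population(keys, list(thousand_genomes = tb))
  expect_equal(sum(flags$population_flag == "novel"), 31L)
  expect_equal(sum(flags$population_flag == "polymorphic"), 51L)
  # zero-frequency presence does not count as polymorphic
  z <- flag_population("k1", list(data.frame(key = "k1", freq = 0)))
  expect_equal(z$population_flag, "novel")
  none <- flag_population("k2", list(data.frame(key = "k1", freq = 0.5)))
  expect_equal(none$population_flag, "novel")
})

test_that("annotation passes classification labels through unchanged", {
  sim <- tiny_sim(seed = 51)
  cl <- classify_small_variants(sim$small$twin_affected,
                                sim$small$twin_unaffected,
                                sim$small$father, sim$small$mother)
  ann <- annotate_variants(cl$calls, sim$reference$genes,
                           sim$reference$sequences)
  expect_equal(ann$origin, cl$calls$origin)
  expect_equal(ann$sharing, cl$calls$sharing)
  expect_true(all(ann$impact[ann$region != "exonic"] %in%
                    c("none", "complex")))
})

test_that("the phenotype tag filter keeps exactly tagged-gene variants", {
  ann <- data.frame(key = sprintf("k%d", 1:5),
                    genes = c("g1", "g2;g3", NA, "g4", "g5"),
                    stringsAsFactors = FALSE)
  tags <- data.frame(gene_id = c("g1", "g3", "g9"),
                     tag = c("neurological", "neurological", "cardiac"),
                     stringsAsFactors = FALSE)
  kept <- phenotype_tag_filter(ann, "neurological", tags)
  expect_equal(kept$key, c("k1", "k2"))   # g3 rescues the multi-gene hit
  expect_warning(out <- phenotype_tag_filter(ann, character(0), tags),
                 "identity")
  expect_equal(nrow(out), 5L)
})
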