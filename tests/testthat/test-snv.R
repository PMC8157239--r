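test_that("within-family sharing requires every affected member to carry", {
  vs <- make_vs(4, samples = c("S1", "S2"))
  vs$geno[2, "S2"] <- 0L
  vs$geno[3, "S2"] <- NA
  vs$geno[4, "S1"] <- 2L  # hom alt still counts as carrier
  out <- shared_within_family(vs, c("S1", "S2"))
  expect_equal(variant_ids(out), variant_ids(vs)[c(1, 4)])
  expect_error(shared_within_family(vs, "S1"), "at least 2")
  expect_error(shared_within_family(vs, c("S1", "S9")), "absent")
})

test_that("rarity filter keeps missing AF and the 1:1000 boundary", {
  vs <- make_vs(4, pop_af = c(0.0005, 0.002, NA, 0.001))
  out <- filter_rare(vs)
  expect_equal(variant_ids(out), variant_ids(vs)[c(1, 3, 4)])
})

test_that("pool-of-normals matching is representation-proof", {
  vs <- variant_set(data.frame(
    chrom = "chr1", pos = c(100L, 300L), ref = c("AT", "C"),
    alt = c("A", "G"), stringsAsFactors = FALSE))
  # same deletion written padded: ATT>AT trims to AT>A at pos 100
  pon <- data.frame(chrom = "chr1", pos = 100L, ref = "ATT", alt = "AT",
                    stringsAsFactors = FALSE)
  out <- filter_pon(vs, pon)
  expect_equal(out$variants$pos, 300L)
  # flag-based path
  vs2 <- make_vs(3, in_pon = c(TRUE, FALSE, TRUE))
  expect_equal(n_variants(filter_pon(vs2)), 1L)
})

test_that("exonic window boundaries are inclusive at +/- pad", {
  gm <- gene_models(
    data.frame(gene = "G1", chrom = "chr1", strand = "+",
               tx_start = 1000L, tx_end = 2000L),
    data.frame(gene = "G1", chrom = "chr1", start = 1200L, end = 1400L))
  vs <- variant_set(data.frame(
    chrom = "chr1", pos = c(1190L, 1189L, 1410L, 1411L, 1300L),
    ref = "A", alt = "C", stringsAsFactors = FALSE))
  out <- exonic_window(vs, gm, pad = 10L)
  expect_equal(out$variants$pos, c(1190L, 1410L, 1300L))
  expect_true(all(out$variants$gene == "G1"))
})

test_that("a variant in two overlapping genes appears once per gene in gene hits", {
  gm <- gene_models(
    data.frame(gene = c("G1", "G2"), chrom = "chr1", strand = "+",
               tx_start = c(100L, 150L), tx_end = c(500L, 600L)),
    data.frame(gene = c("G1", "G2"), chrom = "chr1",
               start = c(180L, 160L), end = c(260L, 250L)))
  vs <- variant_set(data.frame(chrom = "chr1", pos = 200L, ref = "A",
                               alt = "C", stringsAsFactors = FALSE))
  out <- exonic_window(vs, gm)
  expect_equal(n_variants(out), 1L)          # once at variant level
  expect_equal(out$variants$gene, "G1,G2")
  hits <- attr(out, "gene_hits")
  expect_equal(nrow(hits), 2L)               # once per gene in gene outputs
})

test_that("consequence filter: LoF unconditional, nonsynonymous needs 3/5, near-miss flagged", {
  eff <- c("frameshift", "nonsynonymous", "nonsynonymous", "nonsynonymous",
           "synonymous")
  pred <- rbind(rep("benign", 5),
                c(rep("pathogenic", 3), "benign", "benign"),
                c(rep("pathogenic", 2), rep("benign", 3)),
                c(rep("pathogenic", 2), "pathogenic", "missing", "missing"),
                rep("pathogenic", 5))
  vs <- make_vs(5, effect = eff)
  vs$pred <- famvar:::pad_pred(pred, 5)
  out <- consequence_filter(vs)
  expect_equal(variant_ids(out), variant_ids(vs)[c(1, 2, 4)])
  # nonsynonymous with exactly 2/5 lands on the exception channel
  exc <- attr(out, "exceptions")
  expect_equal(variant_ids(exc), variant_ids(vs)[3])
})

test_that("cancer-gene annotation flags but never filters; case mismatch warns", {
  vs <- make_vs(3, gene = c("TP53", "brca2", "OTHER"))
  expect_warning(out <- annotate_cancer_genes(vs, c("TP53", "BRCA2")),
                 "case")
  expect_equal(out$variants$cancer_gene, c(TRUE, TRUE, FALSE))
  expect_equal(n_variants(out), 3L)
  out2 <- annotate_cancer_genes(vs, character(0))
  expect_false(any(out2$variants$cancer_gene))
})

test_that("CADD tiers use inclusive 5/20 and strict >30", {
  vs <- make_vs(6, cadd_phred = c(4.99, 5, 20, 30, 30.01, NA))
  expect_equal(cadd_tier(vs),
               c("none", "annotate", "assess", "assess", "highlight", "none"))
  expect_error(cadd_tier(vs, annotate = 25, assess = 20), "ordered|thresholds")
})

test_that("cross-family variants intersect on the normalized key", {
  sets <- list(
    A = make_vs(3, seed = 1),
    B = make_vs(2, seed = 1),
    C = make_vs(1, seed = 1))
  # make_vs with same seed yields identical coordinates; subset counts differ
  out <- cross_family_variants(sets)
  expect_equal(nrow(out), 2L)  # pos 300 is private to A
  expect_equal(out$families[out$pos == 100L], "A,B,C")
  expect_equal(out$n_families[out$pos == 200L], 2L)
  one <- cross_family_variants(list(A = make_vs(2)))
  expect_equal(nrow(one), 0L)
})

test_that("recurrent genes need two families; blacklist and quality-only support removed", {
  mk <- function(genes, qual = TRUE)
    make_vs(length(genes), gene = genes, quality_pass = qual)
  sets <- list(A = mk(c("MUC1", "KMT2C")), B = mk(c("MUC1", "KMT2C")),
               C = mk("ZZZ3"))
  out <- recurrent_genes(sets)
  expect_setequal(out$gene, c("MUC1", "KMT2C"))
  out2 <- recurrent_genes(sets, blacklist = "muc1")
  expect_equal(out2$gene, "KMT2C")
  expect_equal(attr(out2, "removed")$reason, "blacklist")
  # gene supported only by quality-failing variants drops out
  sets3 <- list(A = mk("GENEQ", qual = FALSE), B = mk("GENEQ", qual = FALSE))
  expect_equal(nrow(recurrent_genes(sets3)), 0L)
  # same gene twice in ONE family does not qualify
  sets4 <- list(A = mk(c("SOLO", "SOLO")), B = mk("OTHER"))
  expect_equal(nrow(recurrent_genes(sets4)), 0L)
})

test_that("locus scan respects the 75 kb boundary for SNVs and SVs", {
  gm <- gene_models(
    data.frame(gene = "FOXL2", chrom = "chr3", strand = "+",
               tx_start = 1000000L, tx_end = 1003000L),
    data.frame(gene = "FOXL2", chrom = "chr3", start = 1000000L,
               end = 1003000L))
  vs <- variant_set(data.frame(
    chrom = "chr3", pos = c(1000000L - 74999L, 1000000L - 75001L,
                            1003000L + 75000L),
    ref = "A", alt = "C", pop_af = c(NA, NA, 0.002),
    stringsAsFactors = FALSE))
  svs <- breakend_pairs(data.frame(
    sv_id = c("in", "out"), sv_type = "DEL", chrom1 = "chr3",
    pos1 = c(900000L, 1100000L), orient1 = "+", chrom2 = "chr3",
    pos2 = c(950000L, 1200000L), orient2 = "-", sample = "S1",
    stringsAsFactors = FALSE))
  scan <- locus_scan(vs, svs, gm, "FOXL2", flank = 75000L)
  expect_equal(scan$FOXL2$snv$pos, 1000000L - 74999L)  # boundary in, af-fail out
  expect_equal(scan$FOXL2$sv$sv_id, "in")
  # unknown symbol yields an empty, not an error
  scan2 <- locus_scan(vs, NULL, gm, "NOSUCH")
  expect_equal(nrow(scan2$NOSUCH$snv), 0L)
})

test_that("pipeline equals the naive nested-loop oracle stage by stage (<= 500 variants)", {
  samples <- c("F1a", "F1b", "F2a", "F2b")
  fc <- family_cohort(list(F1 = c("F1a", "F1b"), F2 = c("F2a", "F2b")))
  gm <- random_gm(8, seed = 21)
  for (seed in 1:3) {
    vs <- random_vs(500, samples, seed = seed)
    res <- run_snv_pipeline(vs, fc, gm, default_config())
    v <- vs$variants
    for (f in c("F1", "F2")) {
      ids <- naive_shared(v, vs$geno, fc$families[[f]])
      expect_setequal(variant_ids(res$shared[[f]]),
                      Reduce(intersect, list(
                        ids,
                        v$id[v$quality_pass],
                        naive_rare(v), naive_pon(v))))
      sub <- v[v$id %in% variant_ids(res$shared[[f]]), ]
      exonic_ids <- naive_exonic(sub, gm$exons)
      pred_sub <- vs$pred[match(sub$id, v$id), , drop = FALSE]
      cons_ids <- naive_consequence(sub[sub$id %in% exonic_ids, ],
                                    pred_sub[sub$id %in% exonic_ids, ,
                                             drop = FALSE])
      expect_setequal(variant_ids(res$qualifying[[f]]), cons_ids)
    }
  }
})

test_that("commuting filters commute and the funnel is monotone", {
  for (seed in 4:6) {
    vs <- random_vs(200, c("S1", "S2"), seed = seed)
    a <- filter_rare(filter_pon(vs))
    b <- filter_pon(filter_rare(vs))
    expect_equal(variant_ids(a), variant_ids(b))
    fc <- family_cohort(list(F1 = c("S1", "S2")))
    res <- run_snv_pipeline(vs, fc, random_gm(5, seed), default_config())
    expect_true(all(res$trace$stages$n_out <= res$trace$stages$n_in))
  }
})

test_that("the printed candidate table fixture retains 19 of 20 and flags the near-miss", {
  tab2 <- rbind(
    data.frame(family = "A", gene = c("HTRA4", "LRP2", "PCSK9"),
               effect = "nonsynonymous"),
    data.frame(family = "B",
               gene = c("BMP5", "CRLF2", "FSCN3", "HFM1", "MET", "NOX5",
                        "SPTBN5", "TEAD2"),
               effect = c("nonsynonymous", "frameshift", rep("nonsynonymous", 5),
                          "frameshift")),
    data.frame(family = "C",
               gene = c("CBX8", "HYDIN", "IGSF1", "LAMA3", "PSMD5", "PXDN",
                        "TBP"),
               effect = c("nonsynonymous", "frameshift",
                          rep("nonsynonymous", 4), "frameshift")),
    data.frame(family = "D", gene = c("USP44", "RASSF2"),
               effect = "nonsynonymous"))
  n <- nrow(tab2)
  samples <- c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2")
  geno <- matrix(0L, n, 8, dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    mem <- paste0(tab2$family[i], 1:2)
    geno[i, mem] <- 1L
  }
  # 3/5 pathogenic everywhere except RASSF2 (2/5, the footnoted exception)
  pred <- matrix(rep(c(rep("pathogenic", 3), "benign", "benign"), n),
                 n, 5, byrow = TRUE)
  pred[tab2$gene == "RASSF2", ] <- c("pathogenic", "pathogenic", "benign",
                                     "benign", "benign")
  # one exon per gene around each variant
  pos <- seq_len(n) * 10000L
  gm <- gene_models(
    data.frame(gene = tab2$gene, chrom = "chr1", strand = "+",
               tx_start = pos - 500L, tx_end = pos + 500L),
    data.frame(gene = tab2$gene, chrom = "chr1", start = pos - 100L,
               end = pos + 100L))
  vs <- variant_set(data.frame(chrom = "chr1", pos = pos, ref = "A",
                               alt = "G", gene = tab2$gene,
                               effect = tab2$effect,
                               stringsAsFactors = FALSE),
                    geno = geno, pred = pred)
  fc <- family_cohort(list(A = c("A1", "A2"), B = c("B1", "B2"),
                           C = c("C1", "C2"), D = c("D1", "D2")))
  res <- run_snv_pipeline(vs, fc, gm, default_config())
  expect_equal(nrow(res$candidates), 19L)
  expect_false("RASSF2" %in% res$candidates$gene)
  expect_equal(res$exceptions$gene, "RASSF2")
  expect_equal(res$exceptions$families, "D")
})

test_that("empty input gives an all-zero trace, not an error", {
  vs <- random_vs(50, c("S1", "S2"), seed = 9)[integer(0)]
  fc <- family_cohort(list(F1 = c("S1", "S2")))
  res <- run_snv_pipeline(vs, fc, random_gm(3, 1), default_config())
  expect_true(all(res$trace$stages$n_in == 0))
  expect_true(all(res$trace$stages$n_out == 0))
  expect_equal(nrow(res$candidates), 0L)
})
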