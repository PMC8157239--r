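mk_sv <- function(id, type = "DEL", chrom = "chr1", p1 = 10000L,
                  p2 = 50000L, o1 = "+", o2 = "-", ci = 0L,
                  sample = "S1") {
  data.frame(sv_id = id, sv_type = type, chrom1 = chrom, pos1 = p1,
             orient1 = o1, chrom2 = chrom, pos2 = p2, orient2 = o2,
             ci1_lo = -ci, ci1_hi = ci, ci2_lo = -ci, ci2_hi = ci,
             sample = sample, stringsAsFactors = FALSE)
}

test_that("breakend overlap: identical, shifted-within-gap, and type conflicts", {
  a <- breakend_pairs(mk_sv("a"))
  b <- breakend_pairs(mk_sv("b"))
  expect_true(breakends_overlap(a, b))
  shifted <- breakend_pairs(mk_sv("c", p1 = 10080L, p2 = 50080L))
  expect_true(breakends_overlap(a, shifted, max_gap = 100L))
  far <- breakend_pairs(mk_sv("d", p1 = 10201L, p2 = 50201L))
  expect_false(breakends_overlap(a, far, max_gap = 100L))
  # CI expansion rescues the same shift
  far_ci <- breakend_pairs(mk_sv("e", p1 = 10201L, p2 = 50201L, ci = 150L))
  expect_true(breakends_overlap(a, far_ci, max_gap = 100L))
  # DEL vs DUP at identical coordinates never overlap (orientation differs)
  dup <- breakend_pairs(mk_sv("f", type = "DUP", o1 = "-", o2 = "+"))
  expect_false(breakends_overlap(a, dup))
  # different chromosomes never overlap
  other <- breakend_pairs(mk_sv("g", chrom = "chr2"))
  expect_false(breakends_overlap(a, other))
})

test_that("breakend canonicalization orders slots and validates CIs", {
  bnd <- breakend_pairs(data.frame(
    sv_id = "x", sv_type = "BND", chrom1 = "chr2", pos1 = 500L,
    orient1 = "+", chrom2 = "chr1", pos2 = 900L, orient2 = "-",
    sample = "S1", stringsAsFactors = FALSE))
  expect_equal(bnd$chrom1, "chr1")
  expect_equal(bnd$pos1, 900L)
  expect_equal(bnd$orient1, "-")
  # a reversed intrachromosomal record is repaired by canonicalization
  rev <- breakend_pairs(mk_sv("y", p1 = 100L, p2 = 50L, o1 = "-", o2 = "+"))
  expect_equal(c(rev$pos1, rev$pos2), c(50L, 100L))
  expect_equal(c(rev$orient1, rev$orient2), c("+", "-"))
  df <- mk_sv("z"); df$ci1_lo <- 5L
  expect_error(breakend_pairs(df), "contain offset 0")
})

test_that("grouping is the transitive closure: chain a~b~c lands in one group", {
  chain <- breakend_pairs(rbind(
    mk_sv("a", p1 = 10000L, p2 = 50000L),
    mk_sv("b", p1 = 10150L, p2 = 50150L, sample = "S2"),
    mk_sv("c", p1 = 10300L, p2 = 50300L, sample = "S3")))
  expect_false(breakends_overlap(chain[1, ], chain[3, ], 100L))
  g <- group_svs(chain, max_gap = 100L)
  expect_equal(length(unique(g$membership$group_id)), 1L)
  expect_equal(g$groups$n_members, 3L)
})

test_that("grouping equals the O(n^3) closure oracle and is order-invariant (n <= 50)", {
  for (seed in 1:4) {
    svs <- random_svs(50, seed = seed)
    g <- group_svs(svs, max_gap = 100L)
    lab <- naive_components(famvar:::overlap_matrix(as.data.frame(svs), 100L))
    # identical partitions: same co-membership for every pair
    got <- g$membership$group_id
    for (i in 1:49) for (j in (i + 1):50)
      expect_equal(got[i] == got[j], lab[i] == lab[j])
    # partition property: every SV in exactly one group
    expect_setequal(g$membership$sv_id, svs$sv_id)
    expect_false(anyDuplicated(g$membership$sv_id) > 0)
    # permuted input gives the identical partition (stable group ids)
    set.seed(seed + 100)
    perm <- sample.int(nrow(svs))
    g2 <- group_svs(svs[perm, ], max_gap = 100L)
    m1 <- setNames(g$membership$group_id, g$membership$sv_id)
    m2 <- setNames(g2$membership$group_id, g2$membership$sv_id)
    expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
  }
})

test_that("catalogue filter drops exact and near matches, keeps disjoint", {
  svs <- breakend_pairs(rbind(mk_sv("exact"), mk_sv("near", p1 = 10050L,
                                                    p2 = 50050L),
                              mk_sv("free", p1 = 300000L, p2 = 350000L)))
  cat <- breakend_pairs(mk_sv("cat1", sample = "catalogue"))
  out <- filter_sv_catalogue(svs, cat)
  expect_equal(out$sv_id, "free")
  expect_equal(nrow(filter_sv_catalogue(svs, cat[0, ])), 3L)
})

test_that("family-shared groups require every affected member", {
  fc <- family_cohort(list(FA = c("A1", "A2"), FB = c("B1", "B2")))
  svs <- breakend_pairs(rbind(
    mk_sv("a1", sample = "A1"), mk_sv("a2", p1 = 10020L, p2 = 50020L,
                                      sample = "A2"),
    mk_sv("x1", p1 = 200000L, p2 = 260000L, sample = "A1"),
    mk_sv("x2", p1 = 200020L, p2 = 260020L, sample = "B1")))
  g <- group_svs(svs, 100L)
  fam <- family_shared_groups(g, fc)
  expect_equal(nrow(fam), 1L)
  expect_equal(fam$families, "FA")
})

test_that("genes in SV regions: span for intrachromosomal, flank for BND", {
  gm <- gene_models(
    data.frame(gene = c("IN", "NEAR", "FARAWAY"), chrom = "chr1",
               strand = "+", tx_start = c(20000L, 50500L, 90000L),
               tx_end = c(30000L, 51000L, 95000L)),
    data.frame(gene = c("IN", "NEAR", "FARAWAY"), chrom = "chr1",
               start = c(20000L, 50500L, 90000L),
               end = c(30000L, 51000L, 95000L)))
  del <- mk_sv("d", p1 = 10000L, p2 = 50000L)
  expect_equal(genes_in_sv(del, gm), "IN")
  bnd <- mk_sv("b", type = "BND", p1 = 50000L, p2 = 300000L)
  expect_equal(genes_in_sv(bnd, gm, bnd_flank = 1000L), "NEAR")
  empty_gm <- gene_models(data.frame(gene = "X", chrom = "chrZ",
                                     strand = "+", tx_start = 1L,
                                     tx_end = 10L),
                          data.frame(gene = "X", chrom = "chrZ",
                                     start = 1L, end = 10L))
  expect_equal(genes_in_sv(del, empty_gm), character(0))
})

test_that("SV gene recurrence counts distinct families, not groups", {
  fg <- data.frame(group_id = c("g1", "g2", "g3"), sv_type = "DEL",
                   chrom1 = "chr1", pos1 = c(10000L, 10000L, 10000L),
                   chrom2 = "chr1", pos2 = c(50000L, 50000L, 50000L),
                   families = c("FA", "FD", "FA"),
                   stringsAsFactors = FALSE)
  gm <- gene_models(data.frame(gene = "SHARED", chrom = "chr1",
                               strand = "+", tx_start = 20000L,
                               tx_end = 30000L),
                    data.frame(gene = "SHARED", chrom = "chr1",
                               start = 20000L, end = 30000L))
  out <- sv_recurrent_genes(fg, gm)
  expect_equal(out$gene, "SHARED")
  expect_equal(out$families, "FA,FD")
  # two groups of the same family only: excluded
  out2 <- sv_recurrent_genes(fg[c(1, 3), ], gm)
  expect_equal(nrow(out2), 0L)
})

test_that("chromosome dosage check flags chr14 DUPs / chr22 DELs by family span", {
  fg <- data.frame(group_id = c("g1", "g2", "g3"), sv_type = c("DUP", "DEL",
                                                               "DEL"),
                   chrom1 = c("chr14", "chr22", "chr1"), pos1 = 1L,
                   chrom2 = c("chr14", "chr22", "chr1"), pos2 = 100L,
                   families = c("FA", "FA,FB", "FA"),
                   stringsAsFactors = FALSE)
  out <- chrom_dosage_check(fg)
  expect_setequal(out$group_id, c("g1", "g2"))
  expect_equal(out$multiple_families[out$group_id == "g1"], FALSE)
  expect_equal(out$multiple_families[out$group_id == "g2"], TRUE)
  expect_equal(nrow(chrom_dosage_check(fg[3, ])), 0L)
})

test_that("sv pipeline on the default cohort keeps planted groups and finds the recurrent gene", {
  co <- default_cohort()
  res <- run_sv_pipeline(co$svs, co$sv_catalogue, co$cohort, co$gm,
                         default_config())
  # every planted family SV survives as a family-shared group with its gene
  for (f in c("A", "B", "C", "D")) {
    tr <- co$truth$planted_sv[co$truth$planted_sv$family == f, ]
    hit <- res$family_groups[res$family_groups$families == f, ]
    expect_equal(nrow(hit), 1L)
    expect_true(grepl(tr$gene, hit$genes))
  }
  # the planted two-family duplication is the one recurrent SV gene
  cross_gene <- co$truth$planted_sv$gene[co$truth$planted_sv$family == "B,C"]
  expect_equal(res$recurrent_genes$gene, cross_gene)
  expect_equal(res$recurrent_genes$families, "B,C")
  # decoys never join planted groups
  mem <- res$groups$membership
  planted_groups <- res$family_groups$group_id
  expect_false(any(grepl("^DECOY", mem$sv_id[mem$group_id %in%
                                               planted_groups])))
  # filters only remove
  expect_true(all(res$trace$stages$n_out <= res$trace$stages$n_in))
  # no dosage flags in the default world
  expect_equal(nrow(res$dosage_flags), 0L)
})
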