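test_that("founder AFs follow the requested spectrum with the rare fraction", {
  fd <- simulate_founders(40, 10000, af_beta = c(0.2, 0.2),
                          fraction_rare = 0.1, seed = 7)
  # empirical haplotype frequencies track model AFs
  emp <- colMeans(fd$haps)
  expect_gt(cor(emp, fd$af), 0.95)
  # the rare-fraction knob forces at least its share of markers rare (the
  # U-shaped default spectrum contributes additional natural rare sites)
  expect_gte(mean(fd$af <= 0.001), 0.1 - 0.015)
  # on a flat spectrum (essentially no natural rare sites) the knob is exact
  fdu <- simulate_founders(40, 10000, af_beta = c(1, 1),
                           fraction_rare = 0.1, seed = 8)
  expect_lt(abs(mean(fdu$af <= 0.001) - 0.1), 0.015)
  # AF-0 markers are all-reference
  fd0 <- simulate_founders(10, 100, af_beta = c(0.2, 0.2),
                           fraction_rare = 1, seed = 1)
  expect_true(all(colMeans(fd0$haps)[fd0$af == 0] == 0))
})

test_that("gene drop is Mendelian by construction and respects 0-Morgan chromosomes", {
  ped <- trio_ped()
  map0 <- data.frame(chrom = "c1", pos = 1:500, cm = rep(0, 500))
  fr <- list(F = c(1L, 2L), M = c(3L, 4L))
  org <- gene_drop(ped, fr, map0, seed = 5)
  # zero genetic length: child inherits an intact parental haplotype
  expect_equal(length(unique(org$K[1, ])), 1L)
  expect_equal(length(unique(org$K[2, ])), 1L)
  expect_true(org$K[1, 1] %in% c(1L, 2L))
  expect_true(org$K[2, 1] %in% c(3L, 4L))
  expect_error(gene_drop(ped, list(F = c(1L, 2L)), map0, seed = 1),
               "missing founder")
})

test_that("emitted genotypes carry zero Mendelian errors (trio oracle)", {
  ped <- default_families()$B
  founders <- ped$id[is.na(ped$father)]
  fr <- setNames(lapply(seq_along(founders), function(k) c(2 * k - 1, 2 * k)),
                 founders)
  set.seed(1)
  haps <- matrix(rbinom(2 * length(founders) * 2000, 1, 0.4),
                 nrow = 2 * length(founders))
  map <- data.frame(chrom = "c1", pos = 1:2000, cm = 1:2000 * 0.05)
  org <- gene_drop(ped, fr, map, seed = 3)
  geno <- sapply(ped$id, function(s) {
    h <- famvar:::haps_from_origins(org[[s]], haps)
    h[1, ] + h[2, ]
  })
  for (i in which(!is.na(ped$father))) {
    ok <- vapply(seq_len(2000), function(m)
      mendel_consistent(geno[m, ped$id[i]], geno[m, ped$father[i]],
                        geno[m, ped$mother[i]]), logical(1))
    expect_equal(sum(!ok), 0L, info = ped$id[i])
  }
})

test_that("empirical kinship of simulated pairs matches pedigree phi", {
  # parent-offspring via the cohort generator's own machinery
  p <- simulate_relative_pair(1, n_markers = 30000, seed = 21)
  est <- estimate_kinship_moment(p$gi, p$gj)
  # 3 binomial standard errors at the configured marker count
  expect_lt(abs(est$phi_hat - 0.25), 0.02)
  p2 <- simulate_relative_pair(2, n_markers = 30000, seed = 22)
  expect_lt(abs(estimate_kinship_moment(p2$gi, p2$gj)$phi_hat - 0.125), 0.02)
})

test_that("planted variants exist, are heterozygous in all affected, and recoverable", {
  co <- default_cohort()
  tr <- co$truth$planted_snv
  ids <- variant_ids(co$vs)
  expect_true(all(tr$id %in% ids))  # every planted id is in the emitted set
  for (r in seq_len(nrow(tr))) {
    fams <- strsplit(tr$families[r], ",")[[1]]
    for (f in fams) {
      for (s in co$cohort$families[[f]]) {
        expect_equal(unname(co$vs$geno[match(tr$id[r], ids), s]), 1L,
                     info = paste(tr$id[r], s))
      }
    }
  }
})

test_that("the generator is deterministic: same spec and seed, identical files", {
  spec <- sim_spec(seed = 5, n_reference = 4,
                   genome = data.frame(chrom = c("chr1", "chr2"),
                                       n_markers = c(1500L, 1500L),
                                       bp_length = c(50e6, 45e6),
                                       cm_length = c(60, 55)))
  d1 <- file.path(tempdir(), "emit1")
  d2 <- file.path(tempdir(), "emit2")
  emit_cohort(simulate_cohort(spec), d1)
  emit_cohort(simulate_cohort(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the emitted VCF
  d3 <- file.path(tempdir(), "emit3")
  emit_cohort(simulate_cohort(sim_spec(seed = 6, n_reference = 4,
                                       genome = spec$genome)), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("emitted bundle round-trips through the readers consistently", {
  spec <- sim_spec(seed = 9, n_reference = 4,
                   genome = data.frame(chrom = c("chr1", "chr2"),
                                       n_markers = c(1200L, 1200L),
                                       bp_length = c(50e6, 45e6),
                                       cm_length = c(60, 55)))
  co <- simulate_cohort(spec)
  dir <- file.path(tempdir(), "bundle")
  paths <- emit_cohort(co, dir)
  vs <- read_vcf(paths["vcf"])
  expect_equal(n_variants(vs), n_variants(co$vs))
  expect_equal(sort(variant_samples(vs)), sort(variant_samples(co$vs)))
  m <- match(variant_ids(co$vs), variant_ids(vs))
  expect_equal(vs$variants$pos[m], co$vs$variants$pos)
  expect_equal(unname(vs$geno[m, variant_samples(co$vs)]),
               unname(co$vs$geno))
  expect_equal(vs$variants$in_pon[m], co$vs$variants$in_pon)
  # phase survives: haplotypes reconstructed from the VCF equal emitted ones
  ph <- attr(vs, "phased")
  expect_false(is.null(ph))
  s1 <- co$cohort$families$B[1]
  j <- match(s1, ph$samples)
  expect_equal(ph$a1[m, j], unname(co$haps[[s1]][1, ]))
  svs <- read_sv_vcf(paths["sv"])
  expect_equal(sort(svs$sv_id), sort(co$svs$sv_id))
  ped <- read_ped(paths["ped"])
  expect_setequal(ped$id, co$ped$id)
  pon <- read_pon(paths["pon"])
  expect_equal(nrow(pon), nrow(co$pon))
  pat <- read_patients(paths["patients"])
  expect_equal(pat$age[pat$family != "reference"],
               c(35, 36, 46, 39, 35, 60, 17, 39))
})

test_that("annotation model: predictor calls track CADD through the logistic link", {
  co <- default_cohort()
  v <- co$vs$variants
  np <- pathogenic_calls(co$vs)
  lo <- np[!is.na(v$cadd_phred) & v$cadd_phred < 5]
  hi <- np[!is.na(v$cadd_phred) & v$cadd_phred > 30]
  # low-CADD variants concentrate at 0-1 pathogenic calls
  expect_gt(mean(lo <= 1), 0.95)
  expect_gt(mean(hi), mean(lo) + 2)
  # PoN fraction 0 disables membership
  spec0 <- sim_spec(seed = 3, n_reference = 4,
                    genome = data.frame(chrom = c("chr1", "chr2"),
                                        n_markers = c(800L, 800L),
                                        bp_length = c(30e6, 30e6),
                                        cm_length = c(40, 40)),
                    annotation = list(pon_frac_common = 0,
                                      pon_frac_rare = 0))
  co0 <- simulate_cohort(spec0)
  expect_false(any(co0$vs$variants$in_pon))
})

test_that("jitter never defeats grouping; planted SV copies always group", {
  co <- default_cohort()
  g <- group_svs(co$svs, max_gap = co$spec$sv$max_gap)
  for (f in c("A", "B", "C", "D")) {
    ids <- paste0("SV_", f, "_", co$cohort$families[[f]])
    gids <- unique(g$membership$group_id[g$membership$sv_id %in% ids])
    expect_length(gids, 1L)
  }
  # zero jitter yields identical breakend copies
  set.seed(1)
  expect_true(all(famvar:::sv_jitter(100, 0, 100) == 0))
})
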