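test_that("moment estimator limits: identical vectors and the degenerate case", {
  g <- c(0L, 1L, 2L, 1L, 0L, 1L)
  est <- estimate_kinship_moment(g, g)
  expect_equal(est$phi_hat, 0.5)
  expect_equal(as.character(classify_kinship(est$phi_hat)), "self/MZ")
  # adversarial: i all het, j alternating homozygotes -> no het-het pairs,
  # no opposite homozygotes (i is never homozygous), so phi_hat = 0
  gi <- rep(1L, 10); gj <- rep(c(0L, 2L), 5)
  est <- estimate_kinship_moment(gi, gj)
  expect_equal(est$phi_hat, 0)
  expect_equal(as.character(classify_kinship(est$phi_hat)), "unrelated")
  # genuine clamp path: overwhelming opposite homozygotes drive phi << -0.5
  est2 <- estimate_kinship_moment(c(1L, rep(0L, 10)), c(1L, rep(2L, 10)))
  expect_equal(est2$phi_hat, (1 - 2 * 10) / 2)
  cls <- classify_kinship(est2$phi_hat)
  expect_equal(as.character(cls), "unrelated")
  expect_true(attr(cls, "clamped"))
  # no heterozygous markers: undefined, not silently zero
  est <- estimate_kinship_moment(c(0L, 2L), c(0L, 2L))
  expect_false(est$defined)
  expect_true(is.na(est$phi_hat))
  expect_true(is.na(classify_kinship(est$phi_hat)))
  # missing markers skipped
  est <- estimate_kinship_moment(c(1L, NA, 1L), c(1L, 2L, NA))
  expect_equal(est$n_markers_used, 1L)
})

test_that("simulated parent-offspring pair estimates phi in [0.23, 0.27]", {
  p <- simulate_relative_pair(1, n_markers = 20000, seed = 11)
  est <- estimate_kinship_moment(p$gi, p$gj)
  expect_gt(est$phi_hat, 0.23)
  expect_lt(est$phi_hat, 0.27)
})

test_that("moment estimator is near zero for unrelated pairs across AF spectra", {
  set.seed(5)
  for (ab in list(c(0.2, 0.2), c(1, 1), c(2, 5))) {
    af <- rbeta(50000, ab[1], ab[2])
    gi <- rbinom(50000, 2, af)
    gj <- rbinom(50000, 2, af)
    est <- estimate_kinship_moment(gi, gj)
    expect_lt(abs(est$phi_hat), 0.02)
  }
})

test_that("IBD segments: self, disjoint, and a planted segment", {
  map <- data.frame(chrom = rep(c("c1", "c2"), each = 500),
                    pos = rep(1:500 * 1000L, 2),
                    cm = rep(seq(0, 49.9, by = 0.1), 2))
  set.seed(8)
  h <- matrix(rbinom(2000, 1, 0.5), nrow = 2)
  # i = j: one segment per chromosome spanning it, classified self via IBD2
  segs <- find_ibd_segments(h, h, map, min_cm = 3)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$cm, segs$ibd2_cm)
  est <- degree_from_ibd(segs, genome_cm(map))
  expect_equal(est$phi_hat, 0.5)
  # nothing shared
  h2 <- 1L - h
  expect_equal(nrow(find_ibd_segments(h, h2, map, min_cm = 3)), 0)
  expect_equal(as.character(
    degree_from_ibd(find_ibd_segments(h, h2, map, min_cm = 3),
                    genome_cm(map))$degree), "unrelated")
  # planted 10 cM shared stretch recovered within one marker at each edge
  hj <- matrix(rbinom(2000, 1, 0.5), nrow = 2)
  hj[hj == h] <- 1L - hj[hj == h]  # force total disagreement
  span <- 101:200  # markers 101..200 on c1: cm 10.0 .. 19.9
  hj[1, span] <- h[1, span]
  segs <- find_ibd_segments(h, hj, map, min_cm = 3)
  expect_equal(nrow(segs), 1)
  expect_true(abs(segs$start_marker - 101) <= 1)
  expect_true(abs(segs$end_marker - 200) <= 1)
  expect_equal(segs$ibd2_cm, 0)
})

test_that("unmapped markers abort IBD detection", {
  map <- data.frame(chrom = "c1", pos = 1:10, cm = c(1:9, NA))
  h <- matrix(0L, 2, 10)
  expect_error(find_ibd_segments(h, h, map), "unmapped")
})

test_that("degree classification from simulated pairs is reliable to degree 3", {
  for (d in 1:3) {
    hits <- 0L
    for (r in 1:10) {
      p <- simulate_relative_pair(d, n_markers = 50000, seed = 300 * d + r)
      est <- estimate_kinship_moment(p$gi, p$gj)
      hits <- hits + identical(as.character(classify_kinship(est$phi_hat)),
                               as.character(d))
    }
    expect_gte(hits, 9L)
  }
})

test_that("parent-offspring IBD covers the genome (half-IBD) within 2%", {
  co <- default_cohort()
  p <- simulate_relative_pair(1, n_markers = nrow(co$map), seed = 77,
                              linked = TRUE, map = co$map)
  segs <- find_ibd_segments(p$hap_i, p$hap_j, co$map, min_cm = 3)
  total <- sum(segs$cm) + sum(segs$ibd2_cm)
  expect_lt(abs(total - genome_cm(co$map)) / genome_cm(co$map), 0.02)
})

test_that("combined relatedness estimation is concordant on the default cohort", {
  co <- default_cohort()
  fam <- unlist(co$cohort$families, use.names = FALSE)
  est <- estimate_relatedness(co$haps[fam], co$map)
  pedd <- all_pairwise_degrees(co$ped, fam)
  cc <- concordance_check(pedd, est)
  # close pairs called by the moment estimator, deep pairs refined by IBD
  key <- paste(est$id1, est$id2, sep = "|")
  expect_equal(est$degree[key == "B1|B2"], "1")
  expect_equal(est$degree[key == "C1|C2"], "2")
  # every cross-family pair classifies unrelated (no >= 3 cM segments)
  cross <- substr(est$id1, 1, 1) != substr(est$id2, 1, 1)
  expect_true(all(est$degree[cross] == "unrelated"))
  # concordance: all but at most one pair within tolerance 1 (the 519 cM
  # desk genome leaves one fifth-degree pair with high realized kinship)
  expect_lte(sum(cc$status == "discordant"), 1)
  expect_equal(sum(cc$status == "untestable"), 0)
})

test_that("concordance_check flags missing estimates as untestable", {
  pedd <- data.frame(id1 = c("a", "a"), id2 = c("b", "c"),
                     degree = c("1", "2"), stringsAsFactors = FALSE)
  gen <- data.frame(id1 = "a", id2 = "b", degree = "1",
                    stringsAsFactors = FALSE)
  cc <- concordance_check(pedd, gen)
  expect_equal(sort(cc$status), c("concordant", "untestable"))
  # perfect agreement: zero flags
  cc2 <- concordance_check(pedd, pedd)
  expect_true(all(cc2$status == "concordant"))
})
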