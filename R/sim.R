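#' Simulation specification for a synthetic familial cohort
#'
#' The default spec states the emulated study design: four families whose
#' affected pairs are 1st-degree (mother-daughter), 2nd-degree (aunt-niece)
#' and twice 5th-degree (grandfathers were brothers), two affected sequenced
#' samples per family, 33 unrelated reference samples, and a desk-scale
#' genome of two chromosomes with 25,000 markers each using the genetic
#' lengths of the two largest human chromosomes. One planted rare coding
#' deleterious variant per family, one variant shared by two families (also
#' given to two reference carriers), one family-shared structural variant
#' per family and one two-family structural variant provide ground truth
#' for recovery tests.
#'
#' @param seed integer run seed (mandatory; every component seed derives
#'   from it via [derive_seed()]).
#' @param n_reference number of unrelated reference samples (default 33).
#' @param genome data.frame: `chrom`, `n_markers`, `bp_length`, `cm_length`.
#' @param af_beta Beta(a, b) parameters of the founder allele-frequency
#'   spectrum (default Beta(0.2, 0.2), a realistic U-shaped site spectrum).
#' @param fraction_rare fraction of markers forced rare (AF <= 0.001).
#' @param exonic_marker_frac fraction of extra markers placed inside exons
#'   so the coding analysis has desk-scale background (default 0.05).
#' @param n_genes_per_chrom background genes per chromosome (default 30).
#' @param missing_frac genotype no-call rate on background markers.
#' @param annotation list of annotation-model parameters (CADD mixture,
#'   predictor-CADD logistic link, pool-of-normals fractions, quality-fail
#'   fraction); see source for fields.
#' @param sv list: `jitter_sd` (breakend jitter SD in bp), `max_gap`
#'   (grouping slack the jitter must respect), `decoys_per_sample`,
#'   `catalogue_extra`.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     n_reference = 33L,
                     genome = data.frame(
                       chrom = c("chr1", "chr2"),
                       n_markers = c(25000L, 25000L),
                       bp_length = c(249e6, 243e6),
                       cm_length = c(267.77, 251.73)),
                     af_beta = c(0.2, 0.2),
                     fraction_rare = 0.1,
                     exonic_marker_frac = 0.05,
                     n_genes_per_chrom = 30L,
                     missing_frac = 0.002,
                     annotation = list(),
                     sv = list()) {
  ann <- utils::modifyList(list(
    cadd_low_frac = 0.7, cadd_low_mean = 2,
    cadd_tail_shift = 5, cadd_tail_shape = 2, cadd_tail_scale = 5,
    pred_mid = 20, pred_slope = 0.25, pred_missing = 0.05,
    pon_frac_common = 0.3, pon_frac_rare = 0.02,
    qual_fail_frac = 0.02, pop_af_hide_rare = 0.5), annotation)
  svp <- utils::modifyList(list(jitter_sd = 20, max_gap = 100L,
                                decoys_per_sample = 3L,
                                catalogue_extra = 3L), sv)
  stopifnot(fraction_rare >= 0, fraction_rare <= 1,
            exonic_marker_frac >= 0, exonic_marker_frac < 1,
            missing_frac >= 0, missing_frac < 1,
            svp$jitter_sd >= 0)
  structure(list(seed = as.integer(seed), n_reference = as.integer(n_reference),
                 genome = genome, af_beta = af_beta,
                 fraction_rare = fraction_rare,
                 exonic_marker_frac = exonic_marker_frac,
                 n_genes_per_chrom = as.integer(n_genes_per_chrom),
                 missing_frac = missing_frac,
                 annotation = ann, sv = svp),
            class = "sim_spec")
}

# ---- pedigree templates (mirror the study's four families) -----------------

fam_deg1 <- function(f) {
  # affected mother (founder) and affected daughter, padded with unaffected sibs
  kids <- paste0(f, "k", 1:7)
  pedigree(data.frame(
    id = c(paste0(f, "1"), paste0(f, "f"), paste0(f, "2"), kids),
    father = c(NA, NA, rep(paste0(f, "f"), 8)),
    mother = c(NA, NA, rep(paste0(f, "1"), 8)),
    sex = c(2, 1, 2, rep(1, 7)),
    affected = c(TRUE, FALSE, TRUE, rep(FALSE, 7)),
    family = f, stringsAsFactors = FALSE))
}

fam_deg2 <- function(f) {
  # affected aunt and affected niece (daughter of the aunt's sister)
  g1 <- paste0(f, "g1"); g2 <- paste0(f, "g2")
  aunt <- paste0(f, "1"); mom <- paste0(f, "m"); sp <- paste0(f, "s")
  niece <- paste0(f, "2")
  sibs <- paste0(f, "k", 1:3); nsibs <- paste0(f, "n", 1:2)
  pedigree(data.frame(
    id = c(g1, g2, aunt, mom, sibs, sp, niece, nsibs),
    father = c(NA, NA, g2, g2, rep(g2, 3), NA, sp, sp, sp),
    mother = c(NA, NA, g1, g1, rep(g1, 3), NA, mom, mom, mom),
    sex = c(2, 1, 2, 2, rep(1, 3), 1, 2, 2, 1),
    affected = c(FALSE, FALSE, TRUE, FALSE, rep(FALSE, 3), FALSE, TRUE,
                 FALSE, FALSE),
    family = f, stringsAsFactors = FALSE))
}

fam_deg5 <- function(f) {
  # the two patients' grandfathers are full brothers (second cousins)
  gg1 <- paste0(f, "gg1"); gg2 <- paste0(f, "gg2")
  gf1 <- paste0(f, "gf1"); gf2 <- paste0(f, "gf2")
  gw1 <- paste0(f, "gw1"); gw2 <- paste0(f, "gw2")
  p1 <- paste0(f, "p1"); p2 <- paste0(f, "p2")
  s1 <- paste0(f, "s1"); s2 <- paste0(f, "s2")
  pedigree(data.frame(
    id = c(gg1, gg2, gf1, gf2, gw1, gw2, p1, p2, s1, s2,
           paste0(f, "1"), paste0(f, "2")),
    father = c(NA, NA, gg2, gg2, NA, NA, gf1, gf2, NA, NA, s1, s2),
    mother = c(NA, NA, gg1, gg1, NA, NA, gw1, gw2, NA, NA, p1, p2),
    sex = c(2, 1, 1, 1, 2, 2, 2, 2, 1, 1, 2, 2),
    affected = c(rep(FALSE, 10), TRUE, TRUE),
    family = f, stringsAsFactors = FALSE))
}

#' Default family templates: degrees 5 (A), 1 (B), 2 (C), 5 (D)
#' @return named list of [pedigree()] objects.
#' @export
default_families <- function() {
  list(A = fam_deg5("A"), B = fam_deg1("B"), C = fam_deg2("C"),
       D = fam_deg5("D"))
}

# ---- founders and gene dropping -------------------------------------------

#' Simulate founder haplotypes and population allele frequencies
#'
#' Allele frequencies follow the spec's Beta spectrum, with a stated
#' fraction of markers forced rare (AF drawn uniformly below 0.001) to feed
#' the rarity filter; haplotype alleles are Bernoulli draws at each AF.
#'
#' @param n_haps number of founder haplotypes to draw.
#' @param n_markers number of biallelic markers.
#' @param af_beta Beta parameters.
#' @param fraction_rare fraction of markers forced rare.
#' @param seed integer seed.
#' @return list: `af` (numeric), `haps` (n_haps x n_markers 0/1 matrix).
#' @export
simulate_founders <- function(n_haps, n_markers, af_beta = c(0.2, 0.2),
                              fraction_rare = 0.1, seed = 1L) {
  set.seed(seed)
  af <- rbeta(n_markers, af_beta[1], af_beta[2])
  n_rare <- round(fraction_rare * n_markers)
  if (n_rare > 0) {
    rare_idx <- sample.int(n_markers, n_rare)
    af[rare_idx] <- runif(n_rare, 0, 0.001)
  }
  haps <- matrix(rbinom(n_haps * n_markers, 1L, rep(af, each = n_haps)),
                 nrow = n_haps)
  list(af = af, haps = haps)
}

# one meiosis: recombine the two parental origin vectors along the map.
# crossovers per chromosome ~ Poisson(length in Morgans), positions uniform
# in cM, no interference; with linked = FALSE every marker segregates
# independently (infinite-chromosome limit used for moment-estimator tests)
meiosis <- function(o1, o2, map, linked = TRUE) {
  M <- length(o1)
  child <- integer(M)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$cm[idx]
    if (!linked) {
      phase <- rbinom(length(idx), 1L, 0.5)
    } else {
      len_m <- (max(cm) - min(cm)) / 100
      k <- rpois(1, len_m)
      breaks <- sort(runif(k, min(cm), max(cm)))
      phase <- (sample(0:1, 1) + findInterval(cm, breaks)) %% 2L
    }
    child[idx] <- ifelse(phase == 0L, o1[idx], o2[idx])
  }
  child
}

#' Drop founder haplotypes through a pedigree
#'
#' Assigns each founder its own two haplotype labels and recombines labels
#' through every meiosis, so each individual's two haplotypes are mosaics of
#' founder haplotypes (the mosaic IS the ground-truth IBD structure).
#' Genotypes derived from the result are Mendelian by construction.
#'
#' @param ped a [pedigree()] (one family).
#' @param founder_rows named list: founder id -> integer pair of haplotype
#'   row indices (into the founder haplotype matrix).
#' @param map genetic map (`chrom`, `pos`, `cm`), one row per marker.
#' @param seed integer seed.
#' @param linked recombine along the map (`TRUE`) or segregate each marker
#'   independently (`FALSE`).
#' @return named list: individual id -> 2 x n_markers integer matrix of
#'   founder-haplotype origins.
#' @export
gene_drop <- function(ped, founder_rows, map, seed, linked = TRUE) {
  set.seed(seed)
  M <- nrow(map)
  origins <- list()
  for (i in attr(ped, "topo")) {
    id <- ped$id[i]
    fa <- ped$father[i]; mo <- ped$mother[i]
    if (is.na(fa) && is.na(mo)) {
      fr <- founder_rows[[id]]
      if (is.null(fr)) fv_abort(paste("missing founder haplotypes for", id))
      origins[[id]] <- rbind(rep(fr[1], M), rep(fr[2], M))
    } else {
      if (is.na(fa) || is.na(mo))
        fv_abort(paste("individual with a single known parent:", id))
      op <- origins[[fa]]; om <- origins[[mo]]
      origins[[id]] <- rbind(meiosis(op[1, ], op[2, ], map, linked),
                             meiosis(om[1, ], om[2, ], map, linked))
    }
  }
  origins
}

# alleles of one individual from its origin mosaic
haps_from_origins <- function(origin, founder_haps) {
  M <- ncol(origin)
  rbind(founder_haps[cbind(origin[1, ], seq_len(M))],
        founder_haps[cbind(origin[2, ], seq_len(M))])
}

#' Simulate a relative pair of a given degree and estimate-ready genotypes
#'
#' Builds a chain pedigree with a single common ancestor path giving
#' kinship `2^(-degree-1)` (degree 1 = parent-offspring), drops founder
#' haplotypes through it and returns the pair's allele-count vectors.
#' With `linked = FALSE` markers segregate independently, the regime in
#' which the moment estimator's sampling error is purely binomial.
#'
#' @param degree relationship degree (>= 1).
#' @param n_markers marker count.
#' @param af_beta founder AF spectrum (frequencies clamped to
#'   `[0.05, 0.95]` so markers are informative).
#' @param seed integer seed.
#' @param linked passed to [gene_drop()]; `map` only matters when linked.
#' @param map optional genetic map when `linked = TRUE`.
#' @return list: `gi`, `gj` (integer allele counts), `phi_expected`.
#' @export
simulate_relative_pair <- function(degree, n_markers = 20000L,
                                   af_beta = c(0.2, 0.2), seed = 1L,
                                   linked = FALSE, map = NULL) {
  stopifnot(degree >= 1L)
  # chain: founder F0 -> C1 -> ... -> C_degree ; pair = (F0's other child? )
  # use ancestor chain: i = A0's child via spouse chain, j = descendant
  ids <- c("A0", "S0", paste0("C", seq_len(degree)),
           if (degree > 1) paste0("S", seq_len(degree - 1)))
  father <- c(NA, NA, "A0", if (degree > 1) paste0("S", seq_len(degree - 1)),
              if (degree > 1) rep(NA, degree - 1))
  mother <- c(NA, NA, "S0", if (degree > 1) paste0("C", seq_len(degree - 1)),
              if (degree > 1) rep(NA, degree - 1))
  ped <- pedigree(data.frame(id = ids, father = father, mother = mother,
                             sex = NA, affected = FALSE, family = "SIM",
                             stringsAsFactors = FALSE))
  founders <- ped$id[is.na(ped$father)]
  if (is.null(map))
    map <- data.frame(chrom = "chrU", pos = seq_len(n_markers),
                      cm = seq_len(n_markers) * 0.01)
  set.seed(derive_seed(seed, "pair_founders", degree))
  af <- pmin(0.95, pmax(0.05, rbeta(n_markers, af_beta[1], af_beta[2])))
  haps <- matrix(rbinom(2L * length(founders) * n_markers, 1L,
                        rep(af, each = 2L * length(founders))),
                 nrow = 2L * length(founders))
  founder_rows <- setNames(lapply(seq_along(founders), function(k)
    c(2L * k - 1L, 2L * k)), founders)
  org <- gene_drop(ped, founder_rows, map,
                   seed = derive_seed(seed, "pair_drop", degree),
                   linked = linked)
  hi <- haps_from_origins(org[["A0"]], haps)
  hj <- haps_from_origins(org[[paste0("C", degree)]], haps)
  list(gi = hi[1, ] + hi[2, ], gj = hj[1, ] + hj[2, ],
       hap_i = hi, hap_j = hj, map = map,
       phi_expected = 2^(-degree - 1))
}

# ---- gene models, markers, annotation -------------------------------------

CANDIDATE_LOCI <- c("FOXL2", "STK11", "IDH1", "IDH2", "DICER1", "BRCA1",
                    "BRCA2")

build_gene_models <- function(spec, seed) {
  set.seed(seed)
  genes <- list(); exons <- list()
  add_gene <- function(sym, chrom, tx_start, n_ex, ex_len) {
    gap <- 3000L
    starts <- tx_start + (seq_len(n_ex) - 1L) * (ex_len + gap)
    ends <- starts + ex_len - 1L
    genes[[length(genes) + 1L]] <<- data.frame(
      gene = sym, chrom = chrom, strand = "+",
      tx_start = tx_start, tx_end = max(ends), stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <<- data.frame(
      gene = sym, chrom = chrom, start = starts, end = ends,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(spec$genome))) {
    ch <- spec$genome$chrom[r]
    bp <- spec$genome$bp_length[r]
    n <- spec$n_genes_per_chrom
    # spread genes over the chromosome; 2-5 kb exons keep desk-scale marker
    # grids populated with exonic sites
    tx_at <- sort(sample.int(bp - 2e6, n)) + 5e5
    for (k in seq_len(n))
      add_gene(sprintf("GENE%s_%03d", sub("chr", "", ch), k), ch, tx_at[k],
               n_ex = sample(3:8, 1), ex_len = sample(2000:5000, 1))
  }
  # candidate loci scanned with 75 kb flanks; kept variant-free by the
  # marker generator to mirror the negative locus-scan finding
  loci_chrom <- rep(spec$genome$chrom, length.out = length(CANDIDATE_LOCI))
  for (k in seq_along(CANDIDATE_LOCI)) {
    bp <- spec$genome$bp_length[match(loci_chrom[k], spec$genome$chrom)]
    add_gene(CANDIDATE_LOCI[k], loci_chrom[k],
             as.integer(bp * 0.90 + k * 400000L), n_ex = 4, ex_len = 3000)
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

build_markers <- function(spec, gm, seed) {
  set.seed(seed)
  rows <- list()
  lock <- locked_windows(gm)
  for (r in seq_len(nrow(spec$genome))) {
    ch <- spec$genome$chrom[r]
    n <- spec$genome$n_markers[r]
    n_ex <- round(n * spec$exonic_marker_frac)
    pos_bg <- sort(sample.int(spec$genome$bp_length[r], n - n_ex))
    ex <- gm$exons[gm$exons$chrom == ch, ]
    ex_pick <- ex[sample.int(nrow(ex), n_ex, replace = TRUE), ]
    pos_ex <- ex_pick$start +
      floor(runif(n_ex) * (ex_pick$end - ex_pick$start + 1L))
    pos <- sort(unique(c(pos_bg, pos_ex)))
    lk <- lock[lock$chrom == ch, ]
    for (w in seq_len(nrow(lk)))
      pos <- pos[pos < lk$lo[w] | pos > lk$hi[w]]
    rows[[r]] <- data.frame(chrom = ch, pos = as.integer(pos),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# windows (candidate locus +/- 75 kb) kept free of generated variants
locked_windows <- function(gm, flank = 75000L) {
  tx <- gm$genes[gm$genes$gene %in% CANDIDATE_LOCI, ]
  data.frame(chrom = tx$chrom, lo = tx$tx_start - flank,
             hi = tx$tx_end + flank)
}

markers_to_map <- function(markers, spec) {
  cm <- numeric(nrow(markers))
  for (r in seq_len(nrow(spec$genome))) {
    ch <- spec$genome$chrom[r]
    idx <- which(markers$chrom == ch)
    p <- markers$pos[idx]
    cm[idx] <- spec$genome$cm_length[r] * (p - min(p)) / (max(p) - min(p))
  }
  data.frame(chrom = markers$chrom, pos = markers$pos, cm = cm)
}

random_alleles <- function(n, seed, indel_frac = 0.05) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  ind <- runif(n) < indel_frac
  ins <- ind & runif(n) < 0.5
  ext <- vapply(seq_len(n), function(i)
    paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = ""), "")
  ref[ind & !ins] <- paste0(ref[ind & !ins], ext[ind & !ins])
  alt[ind & !ins] <- substr(ref[ind & !ins], 1, 1)
  alt[ins] <- paste0(ref[ins], ext[ins])
  list(ref = unname(ref), alt = unname(alt))
}

#' Synthesize the annotation bundle for simulated variants
#'
#' CADD PHRED follows a near-zero/tail mixture; effect classes come from
#' genomic context (exon, splice pad, intron, intergenic, with coding
#' classes drawn inside exons); the five predictor calls follow a logistic
#' link on CADD (`P(pathogenic) = plogis(slope * (cadd - mid))` per call,
#' with a small missing rate); pool-of-normals membership is assigned to a
#' stated fraction of common variants plus a small artefact fraction of
#' rare ones; a stated fraction of rare variants has its population
#' frequency hidden (absent from databases).
#'
#' @param markers data.frame `chrom`, `pos`.
#' @param af population allele frequencies (one per marker).
#' @param gm a [gene_models()].
#' @param ann annotation-model parameter list (see [sim_spec()]).
#' @param seed integer seed.
#' @param exon_pad splice-region pad in bp.
#' @return list: `variants` data.frame (alleles + annotations), `pred`
#'   matrix, `pon` membership logical.
#' @export
synthesize_annotations <- function(markers, af, gm, ann, seed,
                                   exon_pad = 10L) {
  n <- nrow(markers)
  al <- random_alleles(n, derive_seed(seed, "alleles"))
  set.seed(derive_seed(seed, "annot"))
  qry <- GenomicRanges::GRanges(markers$chrom,
                                IRanges::IRanges(markers$pos, markers$pos))
  in_exon <- GenomicRanges::countOverlaps(qry, exons_granges(gm, 0L)) > 0
  in_pad <- !in_exon &
    GenomicRanges::countOverlaps(qry, exons_granges(gm, exon_pad)) > 0
  in_tx <- GenomicRanges::countOverlaps(qry, tx_granges(gm, 0L)) > 0

  effect <- rep("intergenic", n)
  effect[in_tx] <- "intronic"
  effect[in_pad] <- "splice_region"
  coding <- c("nonsynonymous", "synonymous", "frameshift", "stop_gain",
              "splice_region", "other")
  effect[in_exon] <- sample(coding, sum(in_exon), replace = TRUE,
                            prob = c(0.45, 0.30, 0.08, 0.05, 0.07, 0.05))
  # indels in exons are frameshifts more often than not
  indel <- nchar(al$ref) != nchar(al$alt)
  effect[in_exon & indel] <- sample(c("frameshift", "other"),
                                    sum(in_exon & indel), replace = TRUE,
                                    prob = c(0.8, 0.2))

  low <- runif(n) < ann$cadd_low_frac
  cadd <- ifelse(low, rexp(n, 1 / ann$cadd_low_mean),
                 ann$cadd_tail_shift +
                   rgamma(n, shape = ann$cadd_tail_shape,
                          scale = ann$cadd_tail_scale))
  cadd <- round(cadd, 2)

  p_path <- plogis(ann$pred_slope * (cadd - ann$pred_mid))
  pred <- matrix("benign", n, 5)
  for (j in 1:5) {
    u <- runif(n)
    pred[u < p_path, j] <- "pathogenic"
    pred[runif(n) < ann$pred_missing, j] <- "missing"
  }

  common <- af > 0.01
  pon <- (common & runif(n) < ann$pon_frac_common) |
    (!common & runif(n) < ann$pon_frac_rare)

  pop_af <- af
  hide <- af <= 0.001 & runif(n) < ann$pop_af_hide_rare
  pop_af[hide] <- NA_real_

  qfail <- runif(n) < ann$qual_fail_frac

  gene_hit <- GenomicRanges::findOverlaps(qry, tx_granges(gm, 0L))
  gene <- rep("", n)
  gene[S4Vectors::queryHits(gene_hit)] <-
    S4Vectors::mcols(tx_granges(gm, 0L))$gene[S4Vectors::subjectHits(gene_hit)]

  list(variants = data.frame(chrom = markers$chrom, pos = markers$pos,
                             ref = al$ref, alt = al$alt, gene = gene,
                             effect = effect, pop_af = round(pop_af, 6),
                             cadd_phred = cadd, in_pon = pon,
                             quality_pass = !qfail,
                             stringsAsFactors = FALSE),
       pred = pred, pon = pon)
}
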