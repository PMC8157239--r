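#' Method-of-moments kinship from two genotype vectors
#'
#' Robust within-pair estimator based on heterozygote sharing and opposite
#' homozygotes:
#' `phi_hat = (N_het.het - 2 * N_opposite_hom) / (N_het_i + N_het_j)`.
#' It does not use population allele frequencies, which makes it robust to
#' the allele-frequency spectrum. Markers missing in either sample are
#' skipped. A zero denominator (no heterozygous markers) yields an undefined
#' estimate: `phi_hat = NA` with `defined = FALSE`, never a silent 0.
#'
#' @param gi,gj integer vectors of alternate-allele counts (0/1/2, `NA` =
#'   missing) at aligned biallelic markers.
#' @return object of class `kinship_estimate`: list with `phi_hat`,
#'   `n_markers_used`, `n_het_het`, `n_opp_hom`, `n_het_i`, `n_het_j`,
#'   `defined`, `method = "moment"`.
#' @export
estimate_kinship_moment <- function(gi, gj) {
  if (length(gi) != length(gj)) fv_abort("genotype vectors must be aligned")
  use <- !is.na(gi) & !is.na(gj)
  gi <- gi[use]; gj <- gj[use]
  n_hh <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  n_hi <- sum(gi == 1L)
  n_hj <- sum(gj == 1L)
  den <- n_hi + n_hj
  phi <- if (den == 0L) NA_real_ else (n_hh - 2 * n_opp) / den
  structure(list(phi_hat = phi, n_markers_used = length(gi),
                 n_het_het = n_hh, n_opp_hom = n_opp,
                 n_het_i = n_hi, n_het_j = n_hj,
                 defined = den > 0L, method = "moment"),
            class = "kinship_estimate")
}

#' Classify an estimated kinship into a degree label
#'
#' Estimates are clamped to `[-0.5, 0.5]` before classification; negative
#' values classify as `unrelated` (with attribute `clamped = TRUE` when
#' clamping occurred). An undefined estimate returns `NA`.
#'
#' @param phi_hat numeric estimate (may be negative or `NA`).
#' @param max_degree passed to [degree_from_kinship()].
#' @return character degree label (or `NA_character_`).
#' @export
classify_kinship <- function(phi_hat, max_degree = 9L) {
  if (is.na(phi_hat)) return(NA_character_)
  clamped <- phi_hat < -0.5 || phi_hat > 0.5
  p <- max(min(phi_hat, 0.5), -0.5)
  lab <- if (p <= 0) "unrelated" else degree_from_kinship(p, max_degree)
  attr(lab, "clamped") <- clamped
  lab
}

#' Exact-match IBD segments between two phased individuals
#'
#' Finds maximal marker intervals where some haplotype of `i` equals some
#' haplotype of `j` at every marker, keeping intervals of genetic length
#' `>= min_cm`. Matching is exact, which presumes error-free phased
#' haplotypes (the synthetic-data contract); genotyping-error-tolerant
#' matching is out of scope. Overlapping per-pairing runs are merged; the
#' `ibd2_cm` column integrates the genetic length over which two disjoint
#' haplotype pairings match simultaneously (IBD2).
#'
#' @param hap_i,hap_j integer matrices (2 x n_markers) of phased alleles.
#' @param map data.frame with one row per marker: `chrom`, `pos`, `cm`
#'   (cumulative genetic position within chromosome). Must cover all markers.
#' @param min_cm minimum genetic segment length (default 3 cM).
#' @return data.frame: `chrom`, `start_marker`, `end_marker` (indices into
#'   `map`), `start_cm`, `end_cm`, `cm`, `ibd2_cm`.
#' @export
find_ibd_segments <- function(hap_i, hap_j, map, min_cm = 3) {
  if (ncol(hap_i) != nrow(map) || ncol(hap_j) != nrow(map))
    fv_abort("haplotypes and genetic map disagree on marker count")
  if (any(is.na(map$cm))) fv_abort("unmapped markers in genetic map")
  segs <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$cm[idx]
    eq <- function(a, b) { e <- a == b; e[is.na(e)] <- FALSE; e }
    m11 <- eq(hap_i[1, idx], hap_j[1, idx])
    m12 <- eq(hap_i[1, idx], hap_j[2, idx])
    m21 <- eq(hap_i[2, idx], hap_j[1, idx])
    m22 <- eq(hap_i[2, idx], hap_j[2, idx])
    # marker mask of retained (>= min_cm) runs, one per haplotype pairing
    retained <- function(m) {
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- logical(length(m))
      for (k in which(r$values)) {
        if (cm[ends[k]] - cm[starts[k]] >= min_cm)
          keep[starts[k]:ends[k]] <- TRUE
      }
      keep
    }
    k11 <- retained(m11); k12 <- retained(m12)
    k21 <- retained(m21); k22 <- retained(m22)
    keep <- k11 | k12 | k21 | k22
    # IBD2 only where two disjoint pairings are retained simultaneously
    ibd2 <- (k11 & k22) | (k12 & k21)
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dcm <- diff(cm)  # per-interval genetic step for IBD2 integration
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      i2 <- if (e > s)
        sum(dcm[s:(e - 1L)][ibd2[s:(e - 1L)] & ibd2[(s + 1L):e]]) else 0
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start_marker = idx[s], end_marker = idx[e],
        start_cm = cm[s], end_cm = cm[e], cm = cm[e] - cm[s], ibd2_cm = i2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(0), start_marker = integer(0),
                      end_marker = integer(0), start_cm = numeric(0),
                      end_cm = numeric(0), cm = numeric(0),
                      ibd2_cm = numeric(0)))
  do.call(rbind, segs)
}

#' Kinship and degree from IBD segments
#'
#' `phi_hat = total half-IBD cM / (4 * genome_cm)`, counting IBD2 twice.
#' With zero segments the pair is `unrelated`; full-genome IBD2 gives 0.5.
#'
#' @param segments output of [find_ibd_segments()].
#' @param genome_cm total genetic length of the genome scanned (cM).
#' @param max_degree passed to [degree_from_kinship()].
#' @return list with `phi_hat`, `degree`, `total_cm`, `ibd2_cm`,
#'   `method = "ibd_segment"`.
#' @export
degree_from_ibd <- function(segments, genome_cm, max_degree = 9L) {
  total <- sum(segments$cm) + sum(segments$ibd2_cm)
  phi <- total / (4 * genome_cm)
  structure(list(phi_hat = phi,
                 degree = classify_kinship(phi, max_degree),
                 total_cm = total, ibd2_cm = sum(segments$ibd2_cm),
                 method = "ibd_segment"),
            class = "kinship_estimate")
}

#' Total genetic length spanned by a marker map
#' @param map data.frame with `chrom` and `cm` columns.
#' @return total cM summed over chromosomes (first to last marker).
#' @export
genome_cm <- function(map) {
  sum(tapply(map$cm, map$chrom, function(x) max(x) - min(x)))
}

#' Estimate pairwise kinship for a genotype matrix
#'
#' Applies [estimate_kinship_moment()] to every pair of samples.
#'
#' @param geno integer matrix (markers x samples) of allele counts.
#' @param max_degree passed to [classify_kinship()].
#' @return data.frame: `id1`, `id2`, `phi_hat`, `n_markers_used`, `degree`.
#' @export
pairwise_kinship <- function(geno, max_degree = 9L) {
  sn <- colnames(geno)
  if (length(sn) < 2L) fv_abort("need at least two samples")
  pr <- t(utils::combn(sn, 2L))
  rows <- lapply(seq_len(nrow(pr)), function(k) {
    est <- estimate_kinship_moment(geno[, pr[k, 1]], geno[, pr[k, 2]])
    data.frame(id1 = pr[k, 1], id2 = pr[k, 2], phi_hat = est$phi_hat,
               n_markers_used = est$n_markers_used,
               degree = as.character(classify_kinship(est$phi_hat, max_degree)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-tier relatedness estimation from phased haplotypes
#'
#' Combines the two estimators the way the pipeline uses them: the moment
#' estimator calls close relationships (degree 1-4), where it is accurate;
#' any pair it places beyond degree 4 (or cannot estimate) is re-evaluated
#' from exact-match IBD segments, which distinguish genuine distant
#' relatives (a few long segments) from unrelated pairs (none) at desk
#' scale, where the moment estimator's sampling noise spans several deep
#' degrees. Markers are restricted to minor allele frequency `>= min_maf`
#' for the IBD step so near-monomorphic sites cannot fake long matches.
#'
#' @param haps named list: sample id -> 2 x n_markers phased allele matrix.
#' @param map genetic map data.frame (`chrom`, `pos`, `cm`).
#' @param af optional marker allele frequencies; estimated from the
#'   supplied haplotypes when `NULL`.
#' @param min_cm,min_maf,max_degree tuning knobs (see [default_config()]).
#' @return data.frame: `id1`, `id2`, `phi_hat`, `degree`, `method`,
#'   `n_markers_used`.
#' @export
estimate_relatedness <- function(haps, map, af = NULL, min_cm = 3,
                                 min_maf = 0.05, max_degree = 9L) {
  sn <- names(haps)
  if (length(sn) < 2L) fv_abort("need at least two samples")
  if (is.null(af)) {
    hm <- do.call(rbind, haps)
    af <- colMeans(hm, na.rm = TRUE)
  }
  informative <- which(pmin(af, 1 - af) >= min_maf)
  map_inf <- map[informative, , drop = FALSE]
  gcm <- genome_cm(map)
  moment_cut <- 2^(-4L - 1.5)  # deeper than degree 4 -> IBD refinement
  pr <- t(utils::combn(sn, 2L))
  rows <- lapply(seq_len(nrow(pr)), function(k) {
    hi <- haps[[pr[k, 1]]]; hj <- haps[[pr[k, 2]]]
    gi <- hi[1, ] + hi[2, ]; gj <- hj[1, ] + hj[2, ]
    est <- estimate_kinship_moment(gi, gj)
    use_ibd <- !est$defined || is.na(est$phi_hat) ||
      est$phi_hat <= moment_cut
    if (!use_ibd) {
      data.frame(id1 = pr[k, 1], id2 = pr[k, 2], phi_hat = est$phi_hat,
                 degree = as.character(classify_kinship(est$phi_hat,
                                                        max_degree)),
                 method = "moment", n_markers_used = est$n_markers_used,
                 stringsAsFactors = FALSE)
    } else {
      segs <- find_ibd_segments(hi[, informative, drop = FALSE],
                                hj[, informative, drop = FALSE],
                                map_inf, min_cm)
      ib <- degree_from_ibd(segs, gcm, max_degree)
      data.frame(id1 = pr[k, 1], id2 = pr[k, 2], phi_hat = ib$phi_hat,
                 degree = as.character(ib$degree), method = "ibd_segment",
                 n_markers_used = length(informative),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Concordance between pedigree-declared and genomic degrees
#'
#' Joins the two pair tables and flags pairs whose numeric degrees differ by
#' more than `tolerance` (default 1). Pairs without a usable genomic
#' estimate are flagged `untestable`.
#'
#' @param ped_degrees data.frame from [all_pairwise_degrees()].
#' @param genomic data.frame with `id1`, `id2`, `degree` (genomic labels).
#' @param tolerance allowed absolute difference in numeric degree.
#' @param max_degree used to map labels to numbers.
#' @return the joined data.frame with columns `ped_degree`, `genomic_degree`,
#'   `status` in `{"concordant", "discordant", "untestable"}`.
#' @export
concordance_check <- function(ped_degrees, genomic, tolerance = 1,
                              max_degree = 9L) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pd <- data.frame(pair = key(ped_degrees$id1, ped_degrees$id2),
                   ped_degree = ped_degrees$degree, stringsAsFactors = FALSE)
  gd <- data.frame(pair = key(genomic$id1, genomic$id2),
                   genomic_degree = genomic$degree, stringsAsFactors = FALSE)
  m <- merge(pd, gd, by = "pair", all.x = TRUE)
  dp <- degree_numeric(m$ped_degree, max_degree)
  dg <- degree_numeric(m$genomic_degree, max_degree)
  m$status <- ifelse(is.na(m$genomic_degree), "untestable",
                     ifelse(abs(dp - dg) <= tolerance, "concordant",
                            "discordant"))
  m
}
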