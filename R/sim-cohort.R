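# Default clinical table for the familial arm (age at diagnosis, stage);
# the reference arm is drawn around a mean of 51 within 29-75.
FAMILIAL_PATIENTS <- data.frame(
  id = c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
  family = rep(c("A", "B", "C", "D"), each = 2),
  age = c(35, 36, 46, 39, 35, 60, 17, 39),
  stage = c("IIB", "IA", "IC", "unknown", "IA", "IA", "IC", "IC"),
  stringsAsFactors = FALSE)

# deterministic choice of background genes hosting planted variants/SVs
planted_gene_symbols <- function(spec) {
  n <- spec$n_genes_per_chrom
  if (n < 28L) fv_abort("default planting needs >= 28 genes per chromosome")
  if (!all(c("chr1", "chr2") %in% spec$genome$chrom))
    fv_abort("the default planting layout needs chromosomes chr1 and chr2")
  list(snv = c(A = sprintf("GENE1_%03d", 5L), B = sprintf("GENE1_%03d", 20L),
               C = sprintf("GENE2_%03d", 5L), D = sprintf("GENE2_%03d", 20L)),
       sv = c(A = sprintf("GENE1_%03d", 10L), B = sprintf("GENE1_%03d", 25L),
              C = sprintf("GENE2_%03d", 10L), D = sprintf("GENE2_%03d", 25L)),
       sv2 = sprintf("GENE2_%03d", 28L))
}

# gene whose transcript overlaps no other gene (so an SV spanning it hits
# exactly one symbol); searches forward from the preferred symbol
pick_isolated_gene <- function(gm, preferred) {
  g <- gm$genes
  isolated <- function(sym) {
    me <- g[g$gene == sym, ]
    sum(g$chrom == me$chrom & g$tx_start <= me$tx_end &
          g$tx_end >= me$tx_start) == 1L
  }
  pool <- g$gene[g$chrom == g$chrom[g$gene == preferred][1]]
  pool <- setdiff(pool, CANDIDATE_LOCI)
  start <- match(preferred, pool)
  for (k in c(start:length(pool), 1:max(1, start - 1L)))
    if (isolated(pool[k])) return(pool[k])
  fv_abort("no isolated gene available for SV planting")
}

#' Plant a shared variant onto a common founder haplotype
#'
#' Given gene-dropped origins for one family, finds a founder haplotype
#' carried by every affected member at the target marker. When none exists
#' the caller is expected to redrop with the next derived seed; families
#' whose affected members share no common founder cannot ever satisfy the
#' condition and abort upstream.
#'
#' @param origins output of [gene_drop()] for one family.
#' @param affected character vector of affected member ids.
#' @param marker_idx target marker index.
#' @return the shared founder-haplotype row index, or `NA` when the
#'   affected members share no founder haplotype at the marker.
#' @export
shared_founder_hap <- function(origins, affected, marker_idx) {
  sets <- lapply(affected, function(s) unique(origins[[s]][, marker_idx]))
  common <- Reduce(intersect, sets)
  if (length(common)) min(common) else NA_integer_
}

#' Simulate a complete synthetic familial cohort with ground truth
#'
#' Builds the four family pedigrees, a desk-scale marker map and synthetic
#' gene models, drops founder haplotypes through every pedigree, plants the
#' ground-truth variants (one rare coding deleterious variant per family on
#' a founder haplotype all affected members inherit, redrawing gene-drop
#' seeds until the inheritance path exists; one variant shared by two
#' families, also given to two reference carriers), synthesizes the
#' annotation bundle, generates family-shared and decoy structural variants
#' with jittered breakpoints plus a catalogue, and assembles the patients
#' table.
#'
#' @param spec a [sim_spec()].
#' @return object of class `sim_cohort`: list with `vs` (multi-sample
#'   [variant_set()]), `haps` (phased alleles per sequenced sample), `map`,
#'   `ped` (combined pedigree), `cohort` ([family_cohort()]), `gm`
#'   ([gene_models()]), `pon` (panel data.frame), `svs`
#'   ([breakend_pairs()]), `sv_catalogue`, `patients`, `truth`.
#' @export
simulate_cohort <- function(spec = sim_spec()) {
  fams <- default_families()
  gm <- build_gene_models(spec, derive_seed(spec$seed, "genes"))
  markers <- build_markers(spec, gm, derive_seed(spec$seed, "markers"))
  psym <- planted_gene_symbols(spec)

  # --- planted marker positions -------------------------------------------
  planted_pos <- function(sym, offset = 57L) {
    ex <- gm$exons[gm$exons$gene == sym, ][2, ]
    pos <- ex$start + offset
    while (any(markers$chrom == ex$chrom & markers$pos == pos))
      pos <- pos + 1L
    data.frame(chrom = ex$chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }
  snv_pos <- do.call(rbind, lapply(psym$snv, planted_pos))
  rownames(snv_pos) <- names(psym$snv)
  # cross-family variant: first intergenic spot past 55% of chr1
  cross_pos <- {
    bp <- spec$genome$bp_length[spec$genome$chrom == "chr1"]
    p <- as.integer(bp * 0.55)
    tx <- gm$genes[gm$genes$chrom == "chr1", ]
    lock <- locked_windows(gm)
    lock <- lock[lock$chrom == "chr1", ]
    repeat {
      clear <- !any(tx$tx_start - 1000 <= p & tx$tx_end + 1000 >= p) &&
        !any(lock$lo <= p & lock$hi >= p) &&
        !any(markers$chrom == "chr1" & markers$pos == p)
      if (clear) break
      p <- p + 10000L
    }
    data.frame(chrom = "chr1", pos = p, stringsAsFactors = FALSE)
  }
  planted <- rbind(snv_pos, cross = cross_pos)
  markers <- rbind(markers, planted)
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  map <- markers_to_map(markers, spec)
  M <- nrow(markers)
  pidx <- vapply(rownames(planted), function(r)
    which(markers$chrom == planted[r, "chrom"] &
            markers$pos == planted[r, "pos"]), 1L)

  # --- founders -------------------------------------------------------------
  founder_ids <- unlist(lapply(fams, function(p) p$id[is.na(p$father)]))
  fd <- simulate_founders(2L * length(founder_ids), M, spec$af_beta,
                          spec$fraction_rare,
                          derive_seed(spec$seed, "founders"))
  af <- fd$af
  founder_haps <- fd$haps
  af[pidx] <- 0
  founder_haps[, pidx] <- 0L
  founder_rows <- setNames(lapply(seq_along(founder_ids), function(k)
    c(2L * k - 1L, 2L * k)), founder_ids)

  # --- gene drop with planting retries --------------------------------------
  plant_at <- list(A = pidx[["A"]], B = c(pidx[["B"]], pidx[["cross"]]),
                   C = c(pidx[["C"]], pidx[["cross"]]), D = pidx[["D"]])
  origins <- list()
  attempts <- integer(0)
  for (f in names(fams)) {
    ped_f <- fams[[f]]
    aff <- ped_f$id[ped_f$affected]
    found <- NULL
    for (attempt in 0:2000) {
      org <- gene_drop(ped_f, founder_rows, map,
                       seed = derive_seed(spec$seed, paste0("drop:", f),
                                          attempt))
      hs <- vapply(plant_at[[f]], function(m)
        shared_founder_hap(org, aff, m), 1L)
      if (!any(is.na(hs))) { found <- list(org = org, hs = hs); break }
    }
    if (is.null(found))
      fv_abort(paste("impossible sharing: affected members of family", f,
                     "share no founder haplotype at the planted locus"))
    attempts[f] <- attempt
    origins[[f]] <- found$org
    for (k in seq_along(plant_at[[f]]))
      founder_haps[found$hs[k], plant_at[[f]][k]] <- 1L
  }

  # --- sequenced genotypes --------------------------------------------------
  families <- lapply(fams, function(p) p$id[p$affected])
  ref_ids <- sprintf("R%02d", seq_len(spec$n_reference))
  set.seed(derive_seed(spec$seed, "reference"))
  ref_haps <- matrix(rbinom(2L * spec$n_reference * M, 1L,
                            rep(af, each = 2L * spec$n_reference)),
                     nrow = 2L * spec$n_reference)
  ref_haps[, pidx] <- 0L
  # two reference carriers of the cross-family variant
  carrier_idx <- if (spec$n_reference >= 17L) c(3L, 17L) else
    seq_len(min(2L, spec$n_reference))
  ref_carriers <- ref_ids[carrier_idx]
  ref_haps[cbind(2L * carrier_idx - 1L, pidx[["cross"]])] <- 1L

  haps <- list()
  for (f in names(fams)) for (s in families[[f]])
    haps[[s]] <- haps_from_origins(origins[[f]][[s]], founder_haps)
  for (k in seq_len(spec$n_reference))
    haps[[ref_ids[k]]] <- ref_haps[c(2L * k - 1L, 2L * k), , drop = FALSE]
  sample_ids <- c(unlist(families, use.names = FALSE), ref_ids)
  geno <- vapply(sample_ids, function(s) haps[[s]][1, ] + haps[[s]][2, ],
                 integer(M))

  # genotype no-calls on background (never planted) markers
  if (spec$missing_frac > 0) {
    set.seed(derive_seed(spec$seed, "missing"))
    miss <- matrix(runif(length(geno)) < spec$missing_frac,
                   nrow = M)
    miss[pidx, ] <- FALSE
    geno[miss] <- NA_integer_
    for (s in sample_ids) haps[[s]][, miss[, match(s, sample_ids)]] <- NA_integer_
  }

  # --- annotations ----------------------------------------------------------
  syn <- synthesize_annotations(markers, af, gm, spec$annotation,
                                derive_seed(spec$seed, "annot"))
  v <- syn$variants
  pred <- syn$pred
  # planted overrides: rare, deleterious, clean
  pl_effect <- c(A = "nonsynonymous", B = "frameshift", C = "nonsynonymous",
                 D = "nonsynonymous", cross = "intergenic")
  pl_cadd <- c(A = 25.1, B = 28.4, C = 33.0, D = 24.3, cross = 12.2)
  for (r in names(pidx)) {
    i <- pidx[[r]]
    v$effect[i] <- pl_effect[[r]]
    v$cadd_phred[i] <- pl_cadd[[r]]
    v$pop_af[i] <- NA_real_
    v$in_pon[i] <- FALSE
    v$quality_pass[i] <- TRUE
    v$gene[i] <- if (r == "cross") "" else psym$snv[[r]]
    pred[i, ] <- c(rep("pathogenic", 4), "benign")
    if (r == "B") {
      # frameshift deletion anchored at the planted position
      v$ref[i] <- "CAT"; v$alt[i] <- "C"
    }
  }

  vs <- variant_set(v, geno = geno, pred = pred)
  pon_tab <- v[v$in_pon, c("chrom", "pos", "ref", "alt")]

  # --- structural variants --------------------------------------------------
  svres <- build_svs(spec, gm, families, psym,
                     derive_seed(spec$seed, "sv"))

  # --- patients -------------------------------------------------------------
  set.seed(derive_seed(spec$seed, "patients"))
  ref_age <- round(pmin(75, pmax(29, rnorm(spec$n_reference, 51, 11))))
  ref_stage <- sample(c("IA", "IB", "IC"), spec$n_reference, replace = TRUE)
  ref_stage[min(7L, spec$n_reference)] <- "IIIA"  # one metastatic (~3%)
  patients <- rbind(FAMILIAL_PATIENTS,
                    data.frame(id = ref_ids, family = "reference",
                               age = ref_age, stage = ref_stage,
                               stringsAsFactors = FALSE))
  class(patients) <- c("patient_records", "data.frame")

  ped_all <- do.call(rbind, lapply(fams, as.data.frame))
  ped_all <- pedigree(ped_all)

  truth <- list(
    planted_snv = data.frame(
      id = variant_key(markers$chrom[pidx], markers$pos[pidx],
                       v$ref[pidx], v$alt[pidx]),
      label = names(pidx),
      families = c("A", "B", "C", "D", "B,C"),
      gene = c(psym$snv, cross = ""),
      stringsAsFactors = FALSE),
    cross_reference_carriers = ref_carriers,
    planted_sv = svres$truth,
    drop_attempts = attempts,
    expected_degrees = data.frame(
      family = c("A", "B", "C", "D"),
      degree = c(5L, 1L, 2L, 5L), stringsAsFactors = FALSE),
    background_branch_a_max_rate = 1e-3)

  structure(list(spec = spec, vs = vs, haps = haps, map = map,
                 ped = ped_all, cohort = family_cohort(families, ref_ids),
                 gm = gm, pon = pon_tab, svs = svres$svs,
                 sv_catalogue = svres$catalogue, patients = patients,
                 truth = truth),
            class = "sim_cohort")
}

# truncated-normal breakend jitter that can never break the grouping slack
sv_jitter <- function(n, sd, max_gap) {
  j <- round(rnorm(n, 0, sd))
  pmax(pmin(j, max_gap - 1L), -(max_gap - 1L))
}

#' Generate planted, decoy and catalogue structural variants
#'
#' One family-shared deletion per family spanning a designated gene (every
#' affected member carries a jittered copy, jitter truncated inside the
#' grouping slack so planted copies always group), one duplication shared
#' by two families, per-sample decoy deletions placed far apart (never
#' within ten grouping gaps of each other), and a catalogue matching one
#' decoy per sample plus unmatched extras.
#'
#' @param spec a [sim_spec()].
#' @param gm a [gene_models()].
#' @param families named list: family -> affected sample ids.
#' @param psym planted gene symbols (internal).
#' @param seed integer seed.
#' @return list: `svs` ([breakend_pairs()]), `catalogue`, `truth`.
#' @export
build_svs <- function(spec, gm, families, psym, seed) {
  set.seed(seed)
  gap <- spec$sv$max_gap
  sd <- spec$sv$jitter_sd
  rows <- list()
  truth <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  span_for <- function(sym, pad) {
    g <- gm$genes[gm$genes$gene == sym, ][1, ]
    c(g$tx_start - pad, g$tx_end + pad, g$chrom)
  }
  for (f in names(families)) {
    sym <- pick_isolated_gene(gm, psym$sv[[f]])
    sp <- span_for(sym, 5000L)
    for (s in families[[f]]) {
      add(data.frame(sv_id = paste0("SV_", f, "_", s), sv_type = "DEL",
                     chrom1 = sp[3], pos1 = as.integer(sp[1]) +
                       sv_jitter(1, sd, gap),
                     orient1 = "+", chrom2 = sp[3],
                     pos2 = as.integer(sp[2]) + sv_jitter(1, sd, gap),
                     orient2 = "-", ci1_lo = -20L, ci1_hi = 20L,
                     ci2_lo = -20L, ci2_hi = 20L, sample = s,
                     stringsAsFactors = FALSE))
    }
    truth[[f]] <- data.frame(family = f, gene = sym, sv_type = "DEL",
                             stringsAsFactors = FALSE)
  }
  # duplication shared by families B and C -> the one recurrent SV gene
  sym2 <- pick_isolated_gene(gm, psym$sv2)
  sp2 <- span_for(sym2, 2000L)
  for (s in c(families$B, families$C)) {
    add(data.frame(sv_id = paste0("SV_BC_", s), sv_type = "DUP",
                   chrom1 = sp2[3], pos1 = as.integer(sp2[1]) +
                     sv_jitter(1, sd, gap),
                   orient1 = "-", chrom2 = sp2[3],
                   pos2 = as.integer(sp2[2]) + sv_jitter(1, sd, gap),
                   orient2 = "+", ci1_lo = -20L, ci1_hi = 20L,
                   ci2_lo = -20L, ci2_hi = 20L, sample = s,
                   stringsAsFactors = FALSE))
  }
  truth$cross <- data.frame(family = "B,C", gene = sym2, sv_type = "DUP",
                            stringsAsFactors = FALSE)

  # decoys on a reserved lattice: slots 10*gap apart can never co-group
  all_samples <- unlist(families, use.names = FALSE)
  bp2 <- spec$genome$bp_length[spec$genome$chrom == "chr2"]
  band <- as.integer(bp2 * 0.30)
  cat_rows <- list()
  slot <- 0L
  for (s in all_samples) {
    for (j in seq_len(spec$sv$decoys_per_sample)) {
      slot <- slot + 1L
      p1 <- band + slot * 50L * gap
      p2 <- p1 + 20000L
      id <- paste0("DECOY_", s, "_", j)
      add(data.frame(sv_id = id, sv_type = "DEL", chrom1 = "chr2",
                     pos1 = p1, orient1 = "+", chrom2 = "chr2", pos2 = p2,
                     orient2 = "-", ci1_lo = 0L, ci1_hi = 0L, ci2_lo = 0L,
                     ci2_hi = 0L, sample = s, stringsAsFactors = FALSE))
      if (j == 1L) {
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          sv_id = paste0("CAT_", id), sv_type = "DEL", chrom1 = "chr2",
          pos1 = p1 + sample(-(gap - 1L):(gap - 1L), 1L), orient1 = "+",
          chrom2 = "chr2", pos2 = p2, orient2 = "-", sample = "catalogue",
          stringsAsFactors = FALSE)
      }
    }
  }
  for (e in seq_len(spec$sv$catalogue_extra)) {
    slot <- slot + 1L
    cat_rows[[length(cat_rows) + 1L]] <- data.frame(
      sv_id = paste0("CAT_EXTRA_", e), sv_type = "DUP", chrom1 = "chr2",
      pos1 = band + slot * 50L * gap, orient1 = "-", chrom2 = "chr2",
      pos2 = band + slot * 50L * gap + 30000L, orient2 = "+",
      sample = "catalogue", stringsAsFactors = FALSE)
  }
  list(svs = breakend_pairs(do.call(rbind, rows)),
       catalogue = breakend_pairs(do.call(rbind, cat_rows)),
       truth = do.call(rbind, truth))
}

#' Emit a simulated cohort as a mutually consistent file bundle
#'
#' Writes the annotated multi-sample VCF (phased genotypes), SV VCF, PED,
#' exon BED, pool-of-normals TSV, SV-catalogue TSV, genetic-map TSV,
#' patients TSV and the ground-truth JSON sidecar (read by tests only,
#' never by the pipeline). Re-emitting the same spec and seed reproduces
#' every file byte for byte.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return named character vector of paths, invisibly.
#' @export
emit_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             sv = file.path(dir, "cohort.sv.vcf"),
             ped = file.path(dir, "cohort.ped"),
             bed = file.path(dir, "genes.bed"),
             pon = file.path(dir, "pon.tsv"),
             catalogue = file.path(dir, "sv_catalogue.tsv"),
             map = file.path(dir, "genetic_map.tsv"),
             patients = file.path(dir, "patients.tsv"),
             truth = file.path(dir, "truth.json"))
  sm <- variant_samples(cohort$vs)
  gt <- vapply(sm, function(s) {
    h <- cohort$haps[[s]]
    ifelse(is.na(h[1, ]) | is.na(h[2, ]), ".",
           paste0(h[1, ], "|", h[2, ]))
  }, character(n_variants(cohort$vs)))
  write_vcf(cohort$vs, paths["vcf"], phased_gt = gt)
  write_sv_vcf(cohort$svs, paths["sv"])
  write_ped(cohort$ped, paths["ped"])
  write_gene_bed(cohort$gm, paths["bed"])
  utils::write.table(cohort$pon, paths["pon"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(cohort$sv_catalogue), paths["catalogue"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$map, paths["map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$patients, paths["patients"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d variants, %d samples (%d familial + %d reference), %d SVs\n",
              n_variants(x$vs), length(variant_samples(x$vs)),
              length(unlist(x$cohort$families)),
              length(x$cohort$reference_samples), nrow(x$svs)))
  invisible(x)
}
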