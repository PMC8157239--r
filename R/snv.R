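#' Variants shared by every affected member of a family
#'
#' A variant is "shared" when every affected, sequenced family member
#' carries at least one alternate allele. A missing genotype in any member
#' disqualifies the variant: no-calls must not manufacture candidates.
#' Het/hom mixtures count as shared (carrier status only).
#'
#' @param vs a [variant_set()].
#' @param members character vector of >= 2 sample ids.
#' @return the shared subset (a `variant_set`).
#' @export
shared_within_family <- function(vs, members) {
  if (length(members) < 2L)
    fv_abort("a family needs at least 2 sequenced affected members")
  missing_cols <- setdiff(members, variant_samples(vs))
  if (length(missing_cols))
    fv_abort(paste("samples absent from genotype columns:",
                   paste(missing_cols, collapse = ", ")))
  g <- vs$geno[, members, drop = FALSE]
  keep <- rowSums(!is.na(g) & g >= 1L) == length(members)
  vs[which(keep)]
}

#' Drop variants failing the caller quality filter
#' @param vs a [variant_set()].
#' @return subset with `quality_pass == TRUE`.
#' @export
filter_quality <- function(vs) vs[which(vs$variants$quality_pass)]

#' Population-frequency (rarity) filter
#'
#' Keeps variants with population allele frequency at or below
#' `pop_af_max`, treating a missing frequency as rare: absence from
#' population databases is evidence of rarity, and the original filter
#' removed variants *present* above 1:1000.
#'
#' @param vs a [variant_set()].
#' @param pop_af_max frequency ceiling (default 0.001, i.e. 1:1000).
#' @return the rare subset.
#' @export
filter_rare <- function(vs, pop_af_max = 0.001) {
  af <- vs$variants$pop_af
  vs[which(is.na(af) | af <= pop_af_max)]
}

#' Flag pool-of-normals membership by normalized variant key
#'
#' Matches on the parsimony-trimmed (chrom, pos, ref, alt) representation so
#' differently padded representations of the same indel still match.
#'
#' @param vs a [variant_set()].
#' @param pon data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return `vs` with `in_pon` updated.
#' @export
apply_pon <- function(vs, pon) {
  if (!nrow(pon)) return(vs)
  pn <- normalize_variant_set(pon[, c("chrom", "pos", "ref", "alt")])
  keys <- variant_key(pn$chrom, pn$pos, pn$ref, pn$alt)
  nv <- normalize_variant_set(vs)
  hit <- variant_key(nv$variants$chrom, nv$variants$pos,
                     nv$variants$ref, nv$variants$alt) %in% keys
  vs$variants$in_pon <- vs$variants$in_pon | hit
  vs
}

#' Pool-of-normals filter
#'
#' Removes frequent variants and recurrent sequencing artefacts: drops every
#' variant flagged `in_pon` (optionally flagging against a supplied panel
#' first via [apply_pon()]).
#'
#' @param vs a [variant_set()].
#' @param pon optional data.frame panel (`chrom`, `pos`, `ref`, `alt`).
#' @return the subset not in the pool of normals.
#' @export
filter_pon <- function(vs, pon = NULL) {
  if (!is.null(pon)) vs <- apply_pon(vs, pon)
  vs[which(!vs$variants$in_pon)]
}

#' Exonic-window filter with gene assignment
#'
#' Keeps variants whose reference span touches any exon of any transcript,
#' padded `pad` base pairs into the introns (boundaries inclusive). The
#' `gene` field is set to the comma-joined sorted symbols of all hit genes;
#' the full variant-to-gene mapping (one row per hit, so a variant inside
#' two overlapping genes appears once per gene) is attached as attribute
#' `gene_hits`.
#'
#' @param vs a [variant_set()].
#' @param gm a [gene_models()].
#' @param pad intronic padding in bp (default 10).
#' @return the exonic subset with genes assigned.
#' @export
exonic_window <- function(vs, gm, pad = 10L) {
  if (n_variants(vs) == 0) {
    out <- vs
    attr(out, "gene_hits") <- data.frame(id = character(0),
                                         gene = character(0))
    return(out)
  }
  qry <- GenomicRanges::GRanges(
    vs$variants$chrom,
    IRanges::IRanges(vs$variants$pos,
                     vs$variants$pos + nchar(vs$variants$ref) - 1L))
  hits <- GenomicRanges::findOverlaps(qry, exons_granges(gm, pad))
  hit_df <- unique(data.frame(
    id = vs$variants$id[S4Vectors::queryHits(hits)],
    gene = S4Vectors::mcols(exons_granges(gm, pad))$gene[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  keep_ids <- unique(hit_df$id)
  out <- subset_variants(vs, intersect(vs$variants$id, keep_ids))
  gene_of <- vapply(split(hit_df$gene, hit_df$id), function(g)
    paste(sort(unique(g)), collapse = ","), "")
  out$variants$gene <- unname(gene_of[out$variants$id])
  attr(out, "gene_hits") <- hit_df[order(hit_df$id, hit_df$gene), ]
  out
}

LOF_EFFECTS <- c("frameshift", "stop_gain", "stop_loss", "start_loss")

#' Consequence and pathogenicity-consensus filter
#'
#' Retains loss-of-function classes (frameshift, stop gain/loss, start loss)
#' unconditionally, and nonsynonymous variants called pathogenic by at least
#' `predictor_min` of the five predictors (a missing call counts against the
#' consensus: the denominator is fixed at 5). Nonsynonymous near-misses with
#' exactly `predictor_min - 1` pathogenic calls are dropped but reported on
#' the side (attribute `exceptions`), mirroring the practice of flagging a
#' rare tumor-suppressor variant that narrowly misses the consensus; the
#' flag never auto-includes.
#'
#' @param vs a [variant_set()].
#' @param predictor_min consensus threshold (default 3 of 5).
#' @return the retained subset, with attribute `exceptions` (a
#'   `variant_set` of near-miss nonsynonymous variants).
#' @export
consequence_filter <- function(vs, predictor_min = 3L) {
  npath <- pathogenic_calls(vs)
  eff <- vs$variants$effect
  keep <- eff %in% LOF_EFFECTS |
    (eff == "nonsynonymous" & npath >= predictor_min)
  near <- eff == "nonsynonymous" & npath == predictor_min - 1L
  out <- vs[which(keep)]
  attr(out, "exceptions") <- vs[which(near)]
  out
}

#' Annotate (never filter) cancer-gene membership
#'
#' Sets a `cancer_gene` flag by gene-symbol membership in a user-supplied
#' census list. Matching is case-insensitive; a case-insensitive-only match
#' triggers a warning so symbol-case inconsistencies surface.
#'
#' @param vs a [variant_set()] (gene field may hold comma-joined symbols).
#' @param gene_list character vector of census symbols.
#' @return `vs` with a logical `cancer_gene` column added.
#' @export
annotate_cancer_genes <- function(vs, gene_list) {
  symbols <- strsplit(vs$variants$gene, ",", fixed = TRUE)
  exact <- vapply(symbols, function(s) any(s %in% gene_list), logical(1))
  ci <- vapply(symbols, function(s)
    any(toupper(s) %in% toupper(gene_list)), logical(1))
  if (any(ci & !exact))
    warning("cancer-gene match differs only by case for: ",
            paste(vs$variants$id[ci & !exact], collapse = ", "))
  vs$variants$cancer_gene <- ci
  vs
}

#' CADD deleteriousness tiers
#'
#' Assigns the highest applicable tier: `annotate` for PHRED `>= 5`
#' (inclusive), `assess` for `>= 20` (inclusive), `highlight` strictly
#' `> 30`, and `none` otherwise or when the score is missing.
#'
#' @param vs a [variant_set()].
#' @param annotate,assess,highlight tier thresholds.
#' @return character vector of tiers, one per variant.
#' @export
cadd_tier <- function(vs, annotate = 5, assess = 20, highlight = 30) {
  if (!(annotate <= assess && assess <= highlight))
    fv_abort("CADD thresholds must satisfy annotate <= assess <= highlight")
  s <- vs$variants$cadd_phred
  tier <- rep("none", length(s))
  tier[!is.na(s) & s >= annotate] <- "annotate"
  tier[!is.na(s) & s >= assess] <- "assess"
  tier[!is.na(s) & s > highlight] <- "highlight"
  tier
}

#' Variants shared by at least k families
#'
#' Intersects per-family shared sets on the normalized variant key and
#' reports, for each variant carried by `>= min_families` families, the full
#' set of carrying families.
#'
#' @param shared named list: family id -> `variant_set` of variants shared
#'   within that family.
#' @param min_families minimum number of carrying families (default 2).
#' @return data.frame: `id`, `chrom`, `pos`, `ref`, `alt`, `families`
#'   (comma-joined), `n_families`.
#' @export
cross_family_variants <- function(shared, min_families = 2L) {
  rows <- lapply(names(shared), function(f) {
    v <- shared[[f]]$variants
    if (!nrow(v)) return(NULL)
    data.frame(key = variant_key(v$chrom, v$pos, v$ref, v$alt),
               chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               family = f, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  empty <- data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), families = character(0),
                      n_families = integer(0), stringsAsFactors = FALSE)
  if (is.null(all) || !nrow(all)) return(empty)
  sp <- split(all, all$key)
  out <- lapply(sp, function(d) {
    fams <- sort(unique(d$family))
    data.frame(id = d$key[1], chrom = d$chrom[1], pos = d$pos[1],
               ref = d$ref[1], alt = d$alt[1],
               families = paste(fams, collapse = ","),
               n_families = length(fams), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$n_families >= min_families, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
}

#' Genes hit by qualifying variants in at least two families
#'
#' Maps each family's qualifying variants to gene symbols (splitting
#' comma-joined assignments) and reports genes with qualifying variants in
#' `>= min_families` families. Blacklisted genes (case-insensitive) and
#' genes whose support consists only of quality-failing variants are
#' removed; removals are recorded in the `removed` attribute with a reason.
#'
#' @param qualifying named list: family id -> `variant_set`.
#' @param blacklist character vector of gene symbols (ships empty).
#' @param min_families minimum number of families (default 2).
#' @return data.frame: `gene`, `families`, `n_families`; attribute
#'   `removed` records blacklist/quality removals.
#' @export
recurrent_genes <- function(qualifying, blacklist = character(0),
                            min_families = 2L) {
  rows <- lapply(names(qualifying), function(f) {
    v <- qualifying[[f]]$variants
    if (!nrow(v)) return(NULL)
    genes <- strsplit(v$gene, ",", fixed = TRUE)
    data.frame(gene = unlist(genes),
               family = rep(f, sum(lengths(genes))),
               quality_pass = rep(v$quality_pass, lengths(genes)),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  empty <- data.frame(gene = character(0), families = character(0),
                      n_families = integer(0), stringsAsFactors = FALSE)
  removed <- data.frame(gene = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(all) || !nrow(all)) {
    attr(empty, "removed") <- removed
    return(empty)
  }
  all <- all[all$gene != "", , drop = FALSE]
  sp <- split(all, all$gene)
  out <- lapply(names(sp), function(g) {
    d <- sp[[g]]
    fams <- sort(unique(d$family[d$quality_pass]))
    if (toupper(g) %in% toupper(blacklist)) {
      removed <<- rbind(removed, data.frame(gene = g, reason = "blacklist"))
      return(NULL)
    }
    if (!length(fams) && nrow(d)) {
      removed <<- rbind(removed,
                        data.frame(gene = g, reason = "quality_only"))
      return(NULL)
    }
    data.frame(gene = g, families = paste(fams, collapse = ","),
               n_families = length(fams), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    attr(empty, "removed") <- removed
    return(empty)
  }
  out <- out[out$n_families >= min_families, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Candidate-locus scan around named genes
#'
#' Returns every rarity-passing SNV and every structural variant whose
#' breakends or span intersect `[tx_start - flank, tx_end + flank]` of each
#' requested gene (boundaries inclusive). An empty per-gene list reproduces
#' the "no rare variant near the locus" negative finding.
#'
#' @param vs a [variant_set()] (the rarity filter is applied internally).
#' @param svs a breakend-pair data.frame (see [breakend_pairs()]) or `NULL`.
#' @param gm a [gene_models()].
#' @param symbols gene symbols to scan.
#' @param flank flank in bp (default 75000).
#' @param pop_af_max rarity ceiling passed to [filter_rare()].
#' @return named list: symbol -> list(`snv` = variant table subset,
#'   `sv` = SV subset).
#' @export
locus_scan <- function(vs, svs, gm, symbols, flank = 75000L,
                       pop_af_max = 0.001) {
  rare <- filter_rare(vs, pop_af_max)
  out <- list()
  for (sym in symbols) {
    tx <- gm$genes[gm$genes$gene == sym, , drop = FALSE]
    if (!nrow(tx)) {
      out[[sym]] <- list(snv = rare$variants[0, ], sv = NULL)
      next
    }
    lo <- min(tx$tx_start) - flank
    hi <- max(tx$tx_end) + flank
    ch <- tx$chrom[1]
    snv_hit <- rare$variants$chrom == ch &
      rare$variants$pos + nchar(rare$variants$ref) - 1L >= lo &
      rare$variants$pos <= hi
    sv_hit <- NULL
    if (!is.null(svs) && nrow(svs)) {
      intra <- svs$sv_type != "BND"
      span_hit <- intra & svs$chrom1 == ch & svs$pos1 <= hi & svs$pos2 >= lo
      bnd_hit <- !intra &
        ((svs$chrom1 == ch & svs$pos1 >= lo & svs$pos1 <= hi) |
           (svs$chrom2 == ch & svs$pos2 >= lo & svs$pos2 <= hi))
      sv_hit <- svs[span_hit | bnd_hit, , drop = FALSE]
    }
    out[[sym]] <- list(snv = rare$variants[snv_hit, , drop = FALSE],
                       sv = sv_hit)
  }
  out
}

#' Run the tiered SNV/indel prioritization pipeline
#'
#' Stage order: per-family sharing, caller-quality gate, rarity filter,
#' pool-of-normals filter; then branch A (exonic window, consequence
#' consensus, cancer-gene annotation) producing the candidate table, and
#' branch B (genome-wide CADD tiers on the union of family-shared variants,
#' cross-family sharing, recurrent genes). The trace records the union count
#' across families at every stage, so the funnel is monotone.
#'
#' @param vs multi-sample [variant_set()] covering all family members.
#' @param cohort a [family_cohort()].
#' @param gm a [gene_models()].
#' @param config a [default_config()] list (thresholds).
#' @param cancer_genes character census symbols (annotation only).
#' @param blacklist recurrent-gene blacklist (ships empty).
#' @param pon optional pool-of-normals data.frame.
#' @return list: `trace` ([filter_trace()]), `candidates` (data.frame, one
#'   row per surviving variant with carrying families and flags),
#'   `exceptions` (near-miss table), `shared` / `qualifying` per-family
#'   sets, `cross_family`, `recurrent`, `tiers` (id -> tier for the shared
#'   union).
#' @export
run_snv_pipeline <- function(vs, cohort, gm, config = default_config(),
                             cancer_genes = character(0),
                             blacklist = character(0), pon = NULL) {
  th <- config$thresholds
  trace <- filter_trace()
  fams <- names(cohort$families)

  ids_all <- variant_ids(vs)
  shared0 <- lapply(cohort$families, function(m) shared_within_family(vs, m))
  u <- function(sets) unique(unlist(lapply(sets, variant_ids)))
  trace <- trace_stage(trace, "shared_within_family", ids_all, u(shared0))

  shared_q <- lapply(shared0, filter_quality)
  trace <- trace_stage(trace, "quality_pass", u(shared0), u(shared_q))

  shared_r <- lapply(shared_q, filter_rare, pop_af_max = th$pop_af_max)
  trace <- trace_stage(trace, "rare", u(shared_q), u(shared_r))

  shared_p <- lapply(shared_r, filter_pon, pon = pon)
  trace <- trace_stage(trace, "pool_of_normals", u(shared_r), u(shared_p))

  # branch A: coding candidates per family
  exonic <- lapply(shared_p, exonic_window, gm = gm, pad = th$exon_pad_bp)
  trace <- trace_stage(trace, "exonic_window", u(shared_p), u(exonic))

  qualifying <- lapply(exonic, consequence_filter,
                       predictor_min = th$predictor_min)
  trace <- trace_stage(trace, "consequence", u(exonic), u(qualifying))
  qualifying <- lapply(qualifying, annotate_cancer_genes,
                       gene_list = cancer_genes)
  exceptions <- lapply(exonic, function(e) attr(consequence_filter(
    e, predictor_min = th$predictor_min), "exceptions"))

  candidates <- candidate_table(qualifying)
  exception_tab <- candidate_table(exceptions)

  # branch B: genome-wide tiers and cross-family recurrence
  shared_union <- tryCatch(rbind_variant_sets(shared_p),
                           famvar_error = function(e) NULL)
  tiers <- if (is.null(shared_union)) character(0) else
    setNames(cadd_tier(shared_union, th$cadd_annotate, th$cadd_assess,
                       th$cadd_highlight),
             variant_ids(shared_union))
  cross <- cross_family_variants(shared_p, min_families = 2L)
  recurrent <- recurrent_genes(qualifying, blacklist = blacklist,
                               min_families = 2L)

  list(trace = trace, candidates = candidates, exceptions = exception_tab,
       shared = shared_p, qualifying = qualifying, cross_family = cross,
       recurrent = recurrent, tiers = tiers)
}

# flatten per-family variant sets into one candidate row per variant with
# its sharing scope
candidate_table <- function(per_family) {
  rows <- lapply(names(per_family), function(f) {
    v <- per_family[[f]]$variants
    if (!nrow(v)) return(NULL)
    v$family <- f
    v$n_pathogenic <- pathogenic_calls(per_family[[f]])
    v
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      effect = character(0), families = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- variant_key(all$chrom, all$pos, all$ref, all$alt)
  sp <- split(all, key)
  out <- lapply(sp, function(d) {
    d1 <- d[1, , drop = FALSE]
    d1$families <- paste(sort(unique(d$family)), collapse = ",")
    d1$family <- NULL
    d1
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
}
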