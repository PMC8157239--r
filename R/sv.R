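#' Breakend-pair table for structural variants
#'
#' One row per structural variant: two oriented breakends with confidence
#' intervals, the carrying sample and catalogue membership. Breakends are
#' canonicalized (lower chromosome/position first, with orientations and
#' confidence intervals swapped along), so slot-wise comparisons are
#' well-defined.
#'
#' @param df data.frame with `sv_id`, `sv_type` (DEL/DUP/INV/INS/BND),
#'   `chrom1`, `pos1`, `orient1`, `chrom2`, `pos2`, `orient2`, optional
#'   `ci1_lo`, `ci1_hi`, `ci2_lo`, `ci2_hi` (signed offsets containing 0,
#'   default 0), `sample`, optional `in_catalogue`.
#' @return canonicalized data.frame of class `breakend_pairs`.
#' @export
breakend_pairs <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sv_id", "sv_type", "chrom1", "pos1", "orient1",
           "chrom2", "pos2", "orient2", "sample")
  if (!all(req %in% names(df)))
    fv_abort(paste("breakend table needs columns:", paste(req, collapse = ", ")))
  for (col in c("ci1_lo", "ci2_lo")) if (is.null(df[[col]])) df[[col]] <- 0L
  for (col in c("ci1_hi", "ci2_hi")) if (is.null(df[[col]])) df[[col]] <- 0L
  if (is.null(df$in_catalogue)) df$in_catalogue <- FALSE
  df$pos1 <- as.integer(df$pos1); df$pos2 <- as.integer(df$pos2)
  if (!all(df$sv_type %in% c("DEL", "DUP", "INV", "INS", "BND")))
    fv_abort("sv_type must be DEL, DUP, INV, INS or BND")
  if (!all(c(df$orient1, df$orient2) %in% c("+", "-")))
    fv_abort("orientations must be '+' or '-'")
  if (any(df$ci1_lo > 0 | df$ci1_hi < 0 | df$ci2_lo > 0 | df$ci2_hi < 0))
    fv_abort("confidence intervals must contain offset 0")
  intra <- df$sv_type != "BND"
  if (any(intra & df$chrom1 != df$chrom2))
    fv_abort("non-BND types must have both breakends on one chromosome")

  swap <- df$chrom2 < df$chrom1 | (df$chrom1 == df$chrom2 & df$pos2 < df$pos1)
  if (any(swap)) {
    s <- which(swap)
    flip <- function(a, b) {
      tmp <- df[[a]][s]; df[[a]][s] <<- df[[b]][s]; df[[b]][s] <<- tmp
    }
    flip("chrom1", "chrom2"); flip("pos1", "pos2"); flip("orient1", "orient2")
    flip("ci1_lo", "ci2_lo"); flip("ci1_hi", "ci2_hi")
  }
  if (any(intra & df$pos1 > df$pos2))
    fv_abort("non-BND types must have pos1 <= pos2")
  class(df) <- c("breakend_pairs", "data.frame")
  df
}

# interval for one breakend slot expanded by its CI and max_gap
slot_interval <- function(df, slot, max_gap) {
  pos <- df[[paste0("pos", slot)]]
  lo <- pos + df[[paste0("ci", slot, "_lo")]] - max_gap
  hi <- pos + df[[paste0("ci", slot, "_hi")]] + max_gap
  list(lo = lo, hi = hi)
}

#' Do two structural variants share both breakpoints?
#'
#' True iff the types are compatible (identical, or either side a BND, in
#' which case both are compared as bare breakend junctions) and, for both
#' canonical breakend slots, chromosome and orientation agree and the
#' confidence-interval-expanded windows `[pos + ci_lo - max_gap,
#' pos + ci_hi + max_gap]` intersect. Requiring orientation agreement at
#' both slots keeps deletions and duplications at shared coordinates apart.
#'
#' @param a,b single-row `breakend_pairs` (or rows of one).
#' @param max_gap positional slack in bp beyond the CIs (default 100).
#' @return logical.
#' @export
breakends_overlap <- function(a, b, max_gap = 100L) {
  overlap_matrix(rbind(as.data.frame(a), as.data.frame(b)), max_gap)[1, 2]
}

# full pairwise overlap matrix (n small at desk scale)
overlap_matrix <- function(df, max_gap = 100L) {
  n <- nrow(df)
  type_ok <- outer(df$sv_type, df$sv_type, `==`) |
    outer(df$sv_type == "BND", rep(TRUE, n), `&`) |
    outer(rep(TRUE, n), df$sv_type == "BND", `&`)
  res <- type_ok
  for (slot in 1:2) {
    ch <- df[[paste0("chrom", slot)]]
    ot <- df[[paste0("orient", slot)]]
    iv <- slot_interval(df, slot, max_gap)
    res <- res & outer(ch, ch, `==`) & outer(ot, ot, `==`) &
      (outer(iv$lo, iv$hi, `<=`) & outer(iv$hi, iv$lo, `>=`))
  }
  res
}

#' Group structural variants by shared breakpoints
#'
#' Connected components of the pairwise [breakends_overlap()] graph
#' (transitive closure), so a chain a~b, b~c lands in one group even when a
#' and c do not overlap directly. Group identifiers are derived from the
#' sorted member ids, making the partition invariant under input order.
#'
#' @param svs a [breakend_pairs()] table (all samples pooled).
#' @param max_gap passed to [breakends_overlap()].
#' @return list with `membership` (the input with a `group_id` column) and
#'   `groups` (one row per group: `group_id`, `n_members`, `samples`,
#'   consensus breakends = rounded median positions of the members).
#' @export
group_svs <- function(svs, max_gap = 100L) {
  n <- nrow(svs)
  if (!n) {
    svs$group_id <- character(0)
    return(list(membership = svs,
                groups = data.frame(group_id = character(0),
                                    n_members = integer(0),
                                    samples = character(0))))
  }
  adj <- overlap_matrix(as.data.frame(svs), max_gap)
  # union-find over the overlap graph
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in which(adj[i, ] & seq_len(n) > i)) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  comp <- vapply(seq_len(n), find, 1L)
  # deterministic ids from sorted member lists
  key <- vapply(split(seq_len(n), comp), function(m)
    paste(sort(svs$sv_id[m]), collapse = "|"), "")
  ord <- order(key)
  gid <- setNames(sprintf("SVG%04d", order(ord)), names(key))
  svs$group_id <- unname(gid[as.character(comp)])

  groups <- do.call(rbind, lapply(split(seq_len(n), svs$group_id), function(m) {
    d <- svs[m, , drop = FALSE]
    data.frame(group_id = d$group_id[1], n_members = nrow(d),
               samples = paste(sort(unique(d$sample)), collapse = ","),
               sv_type = d$sv_type[1], chrom1 = d$chrom1[1],
               pos1 = as.integer(round(median(d$pos1))),
               chrom2 = d$chrom2[1],
               pos2 = as.integer(round(median(d$pos2))),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(membership = svs, groups = groups[order(groups$group_id), ])
}

#' Remove structural variants present in a known-SV catalogue
#'
#' Drops every SV whose breakends overlap (under [breakends_overlap()]) any
#' entry of the catalogue / SV pool of normals.
#'
#' @param svs a [breakend_pairs()] table.
#' @param catalogue a [breakend_pairs()]-shaped table of known SVs.
#' @param max_gap passed to the overlap test.
#' @return the subset of `svs` not matching the catalogue.
#' @export
filter_sv_catalogue <- function(svs, catalogue, max_gap = 100L) {
  if (!nrow(svs) || is.null(catalogue) || !nrow(catalogue)) return(svs)
  comb <- rbind(as.data.frame(svs)[, c("sv_id", "sv_type", "chrom1", "pos1",
                                       "orient1", "chrom2", "pos2", "orient2",
                                       "ci1_lo", "ci1_hi", "ci2_lo", "ci2_hi")],
                as.data.frame(catalogue)[, c("sv_id", "sv_type", "chrom1",
                                             "pos1", "orient1", "chrom2",
                                             "pos2", "orient2", "ci1_lo",
                                             "ci1_hi", "ci2_lo", "ci2_hi")])
  m <- overlap_matrix(comb, max_gap)
  nq <- nrow(svs)
  hit <- rowSums(m[seq_len(nq), -seq_len(nq), drop = FALSE]) > 0
  svs[!hit, , drop = FALSE]
}

#' Keep groups fully shared within at least one family
#'
#' A family is represented in a group only when every affected, sequenced
#' member of that family contributes a member SV. Groups represented by no
#' family are removed ("present in less than one family").
#'
#' @param grouped output of [group_svs()].
#' @param cohort a [family_cohort()].
#' @return `grouped$groups` subset with a `families` column (comma-joined
#'   fully-represented families).
#' @export
family_shared_groups <- function(grouped, cohort) {
  g <- grouped$groups
  mem <- grouped$membership
  fams <- lapply(seq_len(nrow(g)), function(k) {
    samp <- mem$sample[mem$group_id == g$group_id[k]]
    full <- names(cohort$families)[vapply(cohort$families, function(m)
      all(m %in% samp), logical(1))]
    paste(sort(full), collapse = ",")
  })
  g$families <- unlist(fams)
  g[g$families != "", , drop = FALSE]
}

#' Genes within a structural-variant region
#'
#' For intrachromosomal DEL/DUP/INV/INS, genes whose transcript span
#' intersects `[pos1, pos2]`; for BND junctions, genes intersecting either
#' breakend padded by `bnd_flank`.
#'
#' @param sv one group/consensus row (needs `sv_type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`).
#' @param gm a [gene_models()].
#' @param bnd_flank flank around unpaired breakends in bp (default 1000).
#' @return sorted character vector of gene symbols.
#' @export
genes_in_sv <- function(sv, gm, bnd_flank = 1000L) {
  tx <- gm$genes
  if (sv$sv_type != "BND") {
    hit <- tx$chrom == sv$chrom1 & tx$tx_start <= sv$pos2 &
      tx$tx_end >= sv$pos1
  } else {
    hit <- (tx$chrom == sv$chrom1 & tx$tx_start <= sv$pos1 + bnd_flank &
              tx$tx_end >= sv$pos1 - bnd_flank) |
      (tx$chrom == sv$chrom2 & tx$tx_start <= sv$pos2 + bnd_flank &
         tx$tx_end >= sv$pos2 - bnd_flank)
  }
  sort(unique(tx$gene[hit]))
}

#' Genes affected by family-shared SV groups in at least two families
#'
#' @param family_groups output of [family_shared_groups()].
#' @param gm a [gene_models()].
#' @param bnd_flank passed to [genes_in_sv()].
#' @param min_families minimum number of distinct families (default 2).
#' @return data.frame: `gene`, `families`, `n_families`.
#' @export
sv_recurrent_genes <- function(family_groups, gm, bnd_flank = 1000L,
                               min_families = 2L) {
  empty <- data.frame(gene = character(0), families = character(0),
                      n_families = integer(0), stringsAsFactors = FALSE)
  if (!nrow(family_groups)) return(empty)
  rows <- lapply(seq_len(nrow(family_groups)), function(k) {
    genes <- genes_in_sv(family_groups[k, ], gm, bnd_flank)
    if (!length(genes)) return(NULL)
    fams <- strsplit(family_groups$families[k], ",")[[1]]
    expand.grid(gene = genes, family = fams, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) return(empty)
  sp <- split(all$family, all$gene)
  out <- data.frame(gene = names(sp),
                    families = vapply(sp, function(f)
                      paste(sort(unique(f)), collapse = ","), ""),
                    n_families = vapply(sp, function(f)
                      length(unique(f)), 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$n_families >= min_families, , drop = FALSE]
}

#' Flag dosage-relevant germline SVs (chr14 gains, chr22 losses)
#'
#' Adult granulosa cell tumors recurrently show somatic chromosome 14 gain
#' with chromosome 22 loss; this check flags family-shared germline
#' duplication groups on the gain chromosome and deletion groups on the
#' loss chromosome, and marks whether any flag spans multiple families.
#'
#' @param family_groups output of [family_shared_groups()].
#' @param dup_chrom,del_chrom chromosome names (default `"chr14"`/`"chr22"`;
#'   bare `"14"`/`"22"` also match).
#' @return data.frame: `group_id`, `sv_type`, `chrom`, `families`,
#'   `n_families`, `multiple_families`.
#' @export
chrom_dosage_check <- function(family_groups, dup_chrom = "chr14",
                               del_chrom = "chr22") {
  norm <- function(x) sub("^chr", "", x)
  g <- family_groups
  flag <- (g$sv_type == "DUP" & norm(g$chrom1) == norm(dup_chrom)) |
    (g$sv_type == "DEL" & norm(g$chrom1) == norm(del_chrom))
  out <- g[flag, c("group_id", "sv_type", "chrom1", "families"), drop = FALSE]
  names(out)[3] <- "chrom"
  out$n_families <- vapply(strsplit(out$families, ","), length, 1L)
  out$multiple_families <- out$n_families >= 2L
  rownames(out) <- NULL
  out
}

#' Run the structural-variant prioritization pipeline
#'
#' Catalogue/pool-of-normals removal, breakpoint-overlap grouping,
#' family-sharing filter, gene annotation, cross-family gene recurrence and
#' the dosage check, with a funnel trace over SV ids / group ids.
#'
#' @param svs a [breakend_pairs()] table for all samples.
#' @param catalogue known-SV catalogue (may be `NULL`).
#' @param cohort a [family_cohort()].
#' @param gm a [gene_models()].
#' @param config a [default_config()] list.
#' @return list: `trace`, `groups` (all groups), `family_groups` (with
#'   `genes` column), `recurrent_genes`, `dosage_flags`.
#' @export
run_sv_pipeline <- function(svs, catalogue, cohort, gm,
                            config = default_config()) {
  th <- config$thresholds
  trace <- filter_trace()
  kept <- filter_sv_catalogue(svs, catalogue, th$sv_max_gap_bp)
  trace <- trace_stage(trace, "sv_catalogue", svs$sv_id, kept$sv_id)

  grouped <- group_svs(kept, th$sv_max_gap_bp)
  fam <- family_shared_groups(grouped, cohort)
  keep_ids <- grouped$membership$sv_id[
    grouped$membership$group_id %in% fam$group_id]
  trace <- trace_stage(trace, "family_shared", kept$sv_id, keep_ids)

  fam$genes <- vapply(seq_len(nrow(fam)), function(k)
    paste(genes_in_sv(fam[k, ], gm, th$bnd_flank_bp), collapse = ","), "")
  rec <- sv_recurrent_genes(fam, gm, th$bnd_flank_bp)
  dosage <- chrom_dosage_check(fam)

  list(trace = trace, groups = grouped, family_groups = fam,
       recurrent_genes = rec, dosage_flags = dosage)
}
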