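#' Gene models: transcripts with exon intervals
#'
#' A light container for exon-level gene models. Coordinates are 1-based
#' closed throughout the package; BED input is converted on read. A gene may
#' carry several transcripts (rows in `genes` sharing a symbol); a variant is
#' exonic if it qualifies for any transcript.
#'
#' @param genes data.frame: `gene`, `chrom`, `strand`, `tx_start`, `tx_end`.
#' @param exons data.frame: `gene`, `chrom`, `start`, `end` (1-based closed).
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "tx_start", "tx_end") %in% names(genes)),
            all(c("gene", "chrom", "start", "end") %in% names(exons)))
  if (is.null(genes$strand)) genes$strand <- "+"
  for (g in unique(exons$gene)) {
    ex <- exons[exons$gene == g, ]
    tx <- genes[genes$gene == g, ]
    if (!nrow(tx)) fv_abort(paste("exons for unknown gene:", g))
    if (!nrow(ex)) fv_abort(paste("gene without exons:", g))
    if (any(ex$start > ex$end)) fv_abort(paste("invalid exon interval in", g))
    if (any(ex$start < min(tx$tx_start)) || any(ex$end > max(tx$tx_end)))
      fv_abort(paste("exon outside transcript span in", g))
  }
  exons <- exons[order(exons$gene, exons$start), ]
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons\n",
              length(unique(x$genes$gene)), nrow(x$exons)))
  invisible(x)
}

exons_granges <- function(gm, pad = 0L) {
  GenomicRanges::GRanges(gm$exons$chrom,
                         IRanges::IRanges(pmax(1L, gm$exons$start - pad),
                                          gm$exons$end + pad),
                         gene = gm$exons$gene)
}

tx_granges <- function(gm, flank = 0L) {
  GenomicRanges::GRanges(gm$genes$chrom,
                         IRanges::IRanges(pmax(1L, gm$genes$tx_start - flank),
                                          gm$genes$tx_end + flank),
                         gene = gm$genes$gene)
}

#' Family cohort: who is sequenced in which family
#'
#' @param families named list: family id -> character vector of affected,
#'   sequenced sample ids (each family needs at least two).
#' @param reference_samples character vector of unrelated sample ids,
#'   disjoint from every family.
#' @return object of class `family_cohort`.
#' @export
family_cohort <- function(families, reference_samples = character(0)) {
  stopifnot(is.list(families), length(names(families)) == length(families))
  all_fam <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_fam))
    fv_abort("family sample lists must be disjoint")
  if (length(intersect(all_fam, reference_samples)))
    fv_abort("reference samples must be disjoint from family samples")
  short <- names(families)[vapply(families, length, 1L) < 2L]
  if (length(short))
    fv_abort(paste("each family needs >= 2 affected samples; violated by:",
                   paste(short, collapse = ", ")))
  structure(list(families = families, reference_samples = reference_samples),
            class = "family_cohort")
}

#' @export
print.family_cohort <- function(x, ...) {
  cat(sprintf("family_cohort: %d families (%s), %d reference samples\n",
              length(x$families),
              paste(vapply(x$families, length, 1L), collapse = "+"),
              length(x$reference_samples)))
  invisible(x)
}
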