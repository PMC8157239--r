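#' Parsimony-trim a single allele pair
#'
#' Removes the shared allele suffix, then the shared prefix, one base at a
#' time, advancing `pos` for every prefix base removed. At least one base is
#' always retained on each side, matching the representation `bcftools norm`
#' produces. Left-alignment against a reference sequence is out of scope:
#' trimmed representations are parsimonious but indels in repeat tracts keep
#' the input's anchor.
#'
#' @param pos 1-based position.
#' @param ref,alt allele strings (A/C/G/T/N).
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
trim_variant <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt))
    fv_abort(sprintf("malformed alleles at pos %s: %s>%s", pos, ref, alt))
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # shared suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # shared prefix, advancing pos
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Decompose and normalize one (possibly multiallelic) VCF-style record
#'
#' Splits a record into one biallelic variant per alternate allele,
#' parsimony-trims each allele pair with [trim_variant()], and recomputes
#' per-sample alternate-allele counts for each split allele from the original
#' genotype strings. The total alternate-allele count per sample is conserved
#' across the split (a `1/2` genotype contributes count 1 to each of the two
#' split variants).
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param ref reference allele.
#' @param alts character vector of alternate alleles (length >= 1).
#' @param gt optional named character vector of VCF genotype strings
#'   (`"0/1"`, `"1|2"`, `"./."`, ...); names are sample ids.
#' @param annot optional list of per-record annotations recycled onto every
#'   split variant (e.g. `gene`, `effect`, `quality_pass`); per-alt fields
#'   `pop_af` and `cadd_phred` may be vectors of length `length(alts)`.
#' @return list of variant rows; each a list with `chrom`, `pos`, `ref`,
#'   `alt`, per-sample `counts` (integer, `NA` = missing), and annotations.
#' @export
normalize_record <- function(chrom, pos, ref, alts, gt = NULL, annot = list()) {
  if (length(alts) < 1L) fv_abort("record must have at least one alt allele")
  alleles <- parse_gt(gt)
  out <- vector("list", length(alts))
  for (k in seq_along(alts)) {
    tr <- trim_variant(pos, ref, alts[[k]])
    counts <- if (is.null(alleles)) NULL else {
      cnt <- (alleles$a1 == k) + (alleles$a2 == k)
      as.integer(cnt)  # NA propagates from missing alleles
    }
    per_alt <- function(x) if (length(x) == length(alts)) x[[k]] else x
    row <- list(chrom = chrom, pos = tr$pos, ref = tr$ref, alt = tr$alt,
                counts = counts)
    for (nm in names(annot)) row[[nm]] <- per_alt(annot[[nm]])
    out[[k]] <- row
  }
  out
}

# split VCF GT strings into two allele indices (NA for '.'); haploid calls
# are treated as a single allele with the second index 0 (reference)
parse_gt <- function(gt) {
  if (is.null(gt)) return(NULL)
  sp <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
  a2v <- vapply(sp, function(x) if (length(x) >= 2L) x[[2L]] else "0", "")
  a2 <- suppressWarnings(as.integer(a2v))
  list(a1 = a1, a2 = a2, samples = names(gt))
}

#' Normalize the allele representation of every variant in a set
#'
#' Applies [trim_variant()] row-wise and recomputes ids. Idempotent:
#' normalizing a normalized set is a no-op. Used both on query variants and
#' on pool-of-normals lists so membership matching is representation-proof.
#'
#' @param x a `variant_set` or a data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return object of the same kind with trimmed alleles.
#' @export
normalize_variant_set <- function(x) {
  df <- if (inherits(x, "variant_set")) x$variants else x
  if (nrow(df)) {
    tr <- Map(trim_variant, df$pos, df$ref, df$alt)
    df$pos <- vapply(tr, `[[`, 1L, "pos")
    df$ref <- vapply(tr, `[[`, "", "ref")
    df$alt <- vapply(tr, `[[`, "", "alt")
    if (!is.null(df$id)) df$id <- NULL
  }
  if (inherits(x, "variant_set")) {
    variant_set(df, x$geno, x$pred)
  } else {
    df$id <- variant_key(df$chrom, df$pos, df$ref, df$alt)
    df
  }
}
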