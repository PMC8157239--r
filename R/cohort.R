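#' Age-at-diagnosis summary
#'
#' Arithmetic mean (raw, plus rounded half-away-from-zero to the nearest
#' integer, the convention used when quoting ages in years), midpoint median
#' for even n, and range.
#'
#' @param ages numeric vector of ages (> 0).
#' @return list: `n`, `mean`, `mean_rounded`, `median`, `min`, `max`.
#' @export
age_summary <- function(ages) {
  if (!length(ages)) fv_abort("age summary of an empty set")
  if (any(is.na(ages) | ages <= 0)) fv_abort("ages must be positive")
  list(n = length(ages), mean = mean(ages),
       mean_rounded = round_half_up(mean(ages)),
       median = median(ages), min = min(ages), max = max(ages))
}

#' Two-sample t test (Welch by default)
#'
#' Welch's unequal-variance statistic with Welch-Satterthwaite degrees of
#' freedom is the default; the pooled-variance Student variant is available
#' for sensitivity. Degenerate input (zero variance in both groups) with
#' equal means returns `p = 1` flagged as degenerate by convention; with
#' unequal means it returns `p = 0`, also flagged.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param variant `"welch"` or `"student"`.
#' @return list: `t`, `df`, `p`, `variant`, `degenerate`.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    fv_abort("each group needs at least 2 observations")
  if (var(x) == 0 && var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                df = NA_real_, p = if (eq) 1 else 0,
                variant = variant, degenerate = TRUE))
  }
  res <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, variant = variant, degenerate = FALSE)
}

#' Does a FIGO-like stage label lie beyond stage I?
#'
#' Parses the leading roman numeral; unknown/missing labels never satisfy
#' the predicate.
#'
#' @param stage character vector of stage labels (e.g. `"IA"`, `"IIB"`).
#' @return logical vector.
#' @export
stage_beyond_I <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  rank <- rep(NA_integer_, length(s))
  rank[grepl("^I($|[ABC])", s)] <- 1L
  rank[grepl("^II($|[ABC])", s)] <- 2L
  rank[grepl("^III($|[ABC])", s)] <- 3L
  rank[grepl("^IV($|[ABC])", s)] <- 4L
  !is.na(rank) & rank >= 2L
}

#' Proportion of patients satisfying a stage predicate
#'
#' The denominator is all records, including unknown stage; unknown never
#' satisfies the predicate (so all-unknown gives 0, not `NA`).
#'
#' @param records data.frame with a `stage` column.
#' @param predicate function mapping stage labels to logical
#'   (default [stage_beyond_I()], the "metastatic at diagnosis" proxy).
#' @return fraction in `[0, 1]`.
#' @export
stage_proportion <- function(records, predicate = stage_beyond_I) {
  if (!nrow(records)) fv_abort("stage proportion of an empty set")
  mean(predicate(records$stage))
}

#' Carrier counts of candidate variants in a reference cohort
#'
#' For each candidate, the number of reference samples carrying at least one
#' alternate allele, plus summary counts of candidates seen in `>= 1` and
#' `>= 2` reference samples.
#'
#' @param candidates a [variant_set()] of candidate variants.
#' @param reference_vs a [variant_set()] containing the reference samples'
#'   genotypes (matched on the normalized variant key; candidates absent
#'   from it count 0 carriers).
#' @param reference_samples character vector of reference sample ids.
#' @return list: `per_variant` (data.frame `id`, `carriers`), `n_ge1`,
#'   `n_ge2`.
#' @export
reference_presence <- function(candidates, reference_vs, reference_samples) {
  missing_cols <- setdiff(reference_samples, variant_samples(reference_vs))
  if (length(missing_cols))
    fv_abort(paste("reference samples absent from genotype columns:",
                   paste(missing_cols, collapse = ", ")))
  cv <- normalize_variant_set(candidates)
  rv <- normalize_variant_set(reference_vs)
  ckey <- variant_key(cv$variants$chrom, cv$variants$pos,
                      cv$variants$ref, cv$variants$alt)
  rkey <- variant_key(rv$variants$chrom, rv$variants$pos,
                      rv$variants$ref, rv$variants$alt)
  g <- rv$geno[, reference_samples, drop = FALSE]
  carriers <- integer(length(ckey))
  hit <- match(ckey, rkey)
  ok <- !is.na(hit)
  if (any(ok))
    carriers[ok] <- rowSums(!is.na(g[hit[ok], , drop = FALSE]) &
                              g[hit[ok], , drop = FALSE] >= 1L)
  list(per_variant = data.frame(id = candidates$variants$id,
                                carriers = carriers,
                                stringsAsFactors = FALSE),
       n_ge1 = sum(carriers >= 1L), n_ge2 = sum(carriers >= 2L))
}
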