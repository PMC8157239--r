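#' @name variant_set
#' @title Annotated variant container
#'
#' @description
#' A `variant_set` bundles a table of normalized biallelic SNVs/indels with a
#' per-sample allele-count matrix and a five-column pathogenicity-predictor
#' matrix. It is the unit every prioritization stage consumes and returns.
#'
#' The variant table carries one row per (chrom, pos, ref, alt) with:
#' `id`, `chrom`, `pos` (1-based), `ref`, `alt` (single alternate allele),
#' `gene` (symbol or `""`), `effect` (one of [effect_levels()]), `pop_af`
#' (population alternate-allele frequency, `NA` when absent from databases),
#' `cadd_phred` (`NA` when unscored), `in_pon` (pool-of-normals membership),
#' `quality_pass` (caller FILTER status).
#'
#' @param variants data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#'   Missing annotation columns are filled with defaults (`gene = ""`,
#'   `effect = "other"`, `pop_af = NA`, `cadd_phred = NA`, `in_pon = FALSE`,
#'   `quality_pass = TRUE`).
#' @param geno integer matrix (variants x samples) of alternate-allele counts
#'   in `{0, 1, 2, NA}`; `NA` is a genuine missing-genotype state.
#' @param pred character matrix (variants x up to 5) of predictor calls in
#'   `{"pathogenic", "benign", "missing"}`; fewer than five columns are padded
#'   with `"missing"` so the 3-of-5 consensus rule keeps a fixed denominator.
#' @return an object of class `variant_set`.
NULL

#' Allowed coding-effect classes
#' @return character vector of effect labels.
#' @export
effect_levels <- function() {
  c("frameshift", "stop_gain", "stop_loss", "start_loss", "nonsynonymous",
    "synonymous", "splice_region", "intronic", "intergenic", "other")
}

PRED_LEVELS <- c("pathogenic", "benign", "missing")

#' @rdname variant_set
#' @export
variant_set <- function(variants, geno = NULL, pred = NULL) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(v)))
    fv_abort(paste("variant table must have columns:", paste(req, collapse = ", ")))
  n <- nrow(v)
  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  v$gene <- if (is.null(v$gene)) rep("", n) else as.character(v$gene)
  v$effect <- if (is.null(v$effect)) rep("other", n) else as.character(v$effect)
  v$pop_af <- if (is.null(v$pop_af)) rep(NA_real_, n) else as.numeric(v$pop_af)
  v$cadd_phred <- if (is.null(v$cadd_phred)) rep(NA_real_, n) else as.numeric(v$cadd_phred)
  v$in_pon <- if (is.null(v$in_pon)) rep(FALSE, n) else as.logical(v$in_pon)
  v$quality_pass <- if (is.null(v$quality_pass)) rep(TRUE, n) else as.logical(v$quality_pass)
  if (is.null(v$id)) v$id <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v$id <- make.unique(as.character(v$id), sep = "_dup")
  v <- v[, c("id", req, "gene", "effect", "pop_af", "cadd_phred",
             "in_pon", "quality_pass")]

  validate_alleles(v)
  if (any(v$pos < 1L)) fv_abort("pos must be >= 1")
  if (any(v$ref == v$alt)) fv_abort("ref and alt must differ")
  bad_af <- !is.na(v$pop_af) & (v$pop_af < 0 | v$pop_af > 1)
  if (any(bad_af)) fv_abort("pop_af must lie in [0, 1]")
  if (!all(v$effect %in% effect_levels()))
    fv_abort(paste("unknown effect class:",
                   paste(unique(setdiff(v$effect, effect_levels())), collapse = ", ")))

  if (is.null(geno)) {
    geno <- matrix(integer(0), nrow = n, ncol = 0)
  } else {
    geno <- as.matrix(geno)
    storage.mode(geno) <- "integer"
    if (nrow(geno) != n) fv_abort("geno must have one row per variant")
    if (ncol(geno) > 0 && is.null(colnames(geno)))
      fv_abort("geno must have sample column names")
    ok <- is.na(geno) | (geno >= 0L & geno <= 2L)
    if (!all(ok)) fv_abort("allele counts must be 0, 1, 2 or NA")
  }
  rownames(geno) <- v$id

  pred <- pad_pred(pred, n)
  rownames(pred) <- v$id

  structure(list(variants = v, geno = geno, pred = pred), class = "variant_set")
}

pad_pred <- function(pred, n) {
  if (is.null(pred)) pred <- matrix(character(0), nrow = n, ncol = 0)
  pred <- as.matrix(pred)
  if (nrow(pred) != n && !(nrow(pred) == 0 && n == 0))
    fv_abort("pred must have one row per variant")
  if (ncol(pred) > 5L) fv_abort("pred has more than 5 predictor columns")
  if (ncol(pred) < 5L) {
    pad <- matrix("missing", nrow = n, ncol = 5L - ncol(pred))
    pred <- cbind(pred, pad)
  }
  pred[is.na(pred)] <- "missing"
  if (!all(pred %in% PRED_LEVELS))
    fv_abort("predictor calls must be 'pathogenic', 'benign' or 'missing'")
  colnames(pred) <- paste0("pred", 1:5)
  pred
}

validate_alleles <- function(v) {
  ok <- grepl("^[ACGTN]+$", v$ref) & grepl("^[ACGTN]+$", v$alt)
  if (!all(ok)) {
    bad <- v$id[!ok]
    fv_abort(paste0("malformed alleles (non-ACGTN or empty) in record(s): ",
                    paste(head(bad, 5), collapse = ", ")))
  }
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d samples\n",
              nrow(x$variants), ncol(x$geno)))
  if (nrow(x$variants)) print(head(x$variants, 5))
  invisible(x)
}

#' @export
`[.variant_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$variants$id)
  structure(list(variants = x$variants[i, , drop = FALSE],
                 geno = x$geno[i, , drop = FALSE],
                 pred = x$pred[i, , drop = FALSE]),
            class = "variant_set")
}

#' Number of variants in a variant_set
#' @param x a `variant_set`.
#' @return integer count.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Sample identifiers of a variant_set
#' @param x a `variant_set`.
#' @return character vector of sample ids (genotype columns).
#' @export
variant_samples <- function(x) colnames(x$geno)

#' Variant identifiers
#' @param x a `variant_set`.
#' @return character vector of variant ids.
#' @export
variant_ids <- function(x) x$variants$id

#' Subset a variant_set by id, keeping matrix slices aligned
#' @param x a `variant_set`.
#' @param ids character vector of variant ids to keep (order preserved).
#' @return a `variant_set`.
#' @export
subset_variants <- function(x, ids) x[match(ids, x$variants$id)]

#' Number of pathogenic predictor calls per variant
#' @param x a `variant_set`.
#' @return integer vector, one entry per variant.
#' @export
pathogenic_calls <- function(x) {
  if (nrow(x$pred) == 0) return(integer(0))
  as.integer(rowSums(x$pred == "pathogenic"))
}

#' Combine variant sets over the same samples
#' @param ... `variant_set` objects with identical sample columns.
#' @param dedupe drop rows with duplicate (chrom, pos, ref, alt) keys.
#' @return a `variant_set`.
#' @export
rbind_variant_sets <- function(..., dedupe = TRUE) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "variant_set"))
    xs <- xs[[1]]
  xs <- Filter(function(x) n_variants(x) > 0, xs)
  if (!length(xs)) fv_abort("nothing to combine")
  sn <- lapply(xs, variant_samples)
  if (length(unique(vapply(sn, paste, "", collapse = ","))) != 1L)
    fv_abort("sample columns differ between variant sets")
  v <- do.call(rbind, lapply(xs, function(x) x$variants))
  g <- do.call(rbind, lapply(xs, function(x) x$geno))
  p <- do.call(rbind, lapply(xs, function(x) x$pred))
  if (dedupe) {
    keep <- !duplicated(variant_key(v$chrom, v$pos, v$ref, v$alt))
    v <- v[keep, , drop = FALSE]
    g <- g[keep, , drop = FALSE]
    p <- p[keep, , drop = FALSE]
  }
  v$id <- NULL
  variant_set(v, g, p)
}
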