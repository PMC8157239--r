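#' Default run configuration
#'
#' All tunable thresholds of the pipeline in one structure. Defaults follow
#' the published analysis where it states a value (rarity 1:1000, CADD
#' annotate/assess at 5/20 inclusive and highlight strictly above 30,
#' 3-of-5 predictor consensus, exon padding 10 bp, 75 kb locus flanks) and
#' package decisions elsewhere (100 bp breakpoint slack, 1 kb BND flank,
#' 3 cM IBD floor, degrees reported to the 9th).
#'
#' @param ... named threshold overrides (must already exist).
#' @return list with elements `thresholds` (named list) and `seed`.
#' @export
default_config <- function(...) {
  th <- list(pop_af_max = 0.001,
             cadd_annotate = 5, cadd_assess = 20, cadd_highlight = 30,
             predictor_min = 3L,
             exon_pad_bp = 10L,
             locus_flank_bp = 75000L,
             sv_max_gap_bp = 100L,
             bnd_flank_bp = 1000L,
             ibd_min_cm = 3,
             ibd_min_maf = 0.05,
             max_degree = 9L,
             concordance_tolerance = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown))
    fv_abort(paste("unknown threshold(s):", paste(unknown, collapse = ", ")))
  th[names(dots)] <- dots
  cfg <- list(thresholds = th, seed = 1L)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (!(th$pop_af_max > 0 && th$pop_af_max < 1))
    fv_abort("pop_af_max must lie in (0, 1)")
  if (!(th$cadd_annotate <= th$cadd_assess &&
        th$cadd_assess <= th$cadd_highlight))
    fv_abort("CADD thresholds must be ordered annotate <= assess <= highlight")
  pads <- c(th$exon_pad_bp, th$locus_flank_bp, th$sv_max_gap_bp,
            th$bnd_flank_bp)
  if (any(pads < 0)) fv_abort("paddings must be >= 0")
  invisible(cfg)
}

#' Read a run configuration from a structured JSON file
#'
#' The file may override any threshold and the seed; unknown keys abort so
#' typos cannot silently fall back to defaults.
#'
#' @param path JSON file with optional `thresholds` object and `seed`.
#' @return a validated config list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(default_config, as.list(raw$thresholds %||% list()))
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  validate_config(cfg)
  cfg
}
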