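#' Default INFO key aliases for annotated VCFs
#'
#' The reader expects annotation bundled in INFO fields; deployments with
#' different key names remap here.
#'
#' @return named list of INFO keys.
#' @export
default_info_keys <- function() {
  list(pop_af = "POP_AF", cadd = "CADD", gene = "GENE",
       effect = "EFFECT", pred = "PRED", pon = "PON")
}

# vectorized parsimony trimmer; must agree with trim_variant() row-wise
trim_alleles_vec <- function(pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, nr, nr) == substr(alt, na, na)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 1L, nr[can] - 1L)
    alt[can] <- substr(alt[can], 1L, na[can] - 1L)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L & substr(ref, 1, 1) == substr(alt, 1, 1)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 2L, nr[can])
    alt[can] <- substr(alt[can], 2L, na[can])
    pos[can] <- pos[can] + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

pred_to_code <- c(pathogenic = "P", benign = "B", missing = "M")
code_to_pred <- c(P = "pathogenic", B = "benign", M = "missing")

#' Read an annotated multi-sample VCF into a variant_set
#'
#' Parses SNV/indel records with the annotation INFO bundle (population
#' allele frequency, CADD PHRED, gene, coding effect, five predictor calls,
#' pool-of-normals flag), decomposes multiallelic sites, parsimony-trims
#' alleles and recomputes per-sample allele counts per split allele.
#' Records failing the caller FILTER get `quality_pass = FALSE` but are not
#' dropped here; the quality gate is an explicit pipeline stage. Unsorted
#' files abort; a missing INFO key warns and sets the field to missing
#' (or aborts, configurable).
#'
#' @param path VCF 4.2+ file (plain or bgzipped).
#' @param sample_subset optional character vector restricting genotype
#'   columns.
#' @param info_keys key aliases, see [default_info_keys()].
#' @param on_missing_info `"warn"` (set missing) or `"abort"`.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path, sample_subset = NULL,
                     info_keys = default_info_keys(),
                     on_missing_info = c("warn", "abort")) {
  on_missing_info <- match.arg(on_missing_info)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) fv_abort(paste("unsorted VCF: contig", ch))
  }
  nrec <- length(rr)
  ref <- as.character(rr$REF)
  alt_list <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt_list)
  if (any(nalt < 1L)) fv_abort("record without an alt allele")
  filt <- rr$FILTER

  info <- VariantAnnotation::info(vcf)
  get_info <- function(field) {
    key <- info_keys[[field]]
    if (!key %in% colnames(info)) {
      msg <- paste0("INFO key '", key, "' absent from ", path)
      if (on_missing_info == "abort") fv_abort(msg)
      warning(msg, "; treating as missing")
      return(NULL)
    }
    info[[key]]
  }

  gtm <- if ("GT" %in% rownames(VariantAnnotation::geno(
    VariantAnnotation::header(vcf)))) VariantAnnotation::geno(vcf)$GT else
      matrix(character(0), nrow = nrec, ncol = 0)
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, colnames(gtm))
    if (length(missing_s))
      fv_abort(paste("samples not in VCF:", paste(missing_s, collapse = ", ")))
    gtm <- gtm[, sample_subset, drop = FALSE]
  }

  # expand multiallelics: one output row per (record, alt index)
  rec <- rep(seq_len(nrec), nalt)
  aidx <- sequence(nalt)
  alts <- unlist(lapply(seq_len(nrec), function(i)
    as.character(alt_list[[i]])))

  phased <- NULL
  if (ncol(gtm)) {
    sep <- grepl("[/|]", gtm)
    s1 <- sub("[/|].*$", "", gtm)
    s2 <- ifelse(sep, sub("^[^/|]*[/|]", "", gtm), "0")
    a1 <- suppressWarnings(matrix(as.integer(s1), nrow = nrec))
    a2 <- suppressWarnings(matrix(as.integer(s2), nrow = nrec))
    A1 <- a1[rec, , drop = FALSE]
    A2 <- a2[rec, , drop = FALSE]
    counts <- (A1 == aidx) + (A2 == aidx)  # aidx recycles down columns
    storage.mode(counts) <- "integer"
    colnames(counts) <- colnames(gtm)
    # preserve phase for downstream haplotype use when fully biallelic+phased
    if (all(nalt == 1L) && all(grepl("\\|", gtm) | gtm %in% c(".", "./."))) {
      phased <- list(a1 = a1, a2 = a2, samples = colnames(gtm))
    }
  } else {
    counts <- matrix(integer(0), nrow = length(rec), ncol = 0)
  }

  # per-alt aware INFO extraction
  expand_info <- function(x, default) {
    if (is.null(x)) return(rep(default, length(rec)))
    if (is.list(x) || is(x, "List")) {
      out <- rep(default, length(rec))
      lens <- S4Vectors::elementNROWS(x)
      for (i in which(lens > 0)) {
        rows <- which(rec == i)
        vals <- x[[i]]
        out[rows] <- if (length(vals) == nalt[i]) vals[aidx[rows]] else vals[1]
      }
      return(out)
    }
    x[rec]
  }
  pop_af <- as.numeric(expand_info(get_info("pop_af"), NA_real_))
  cadd <- as.numeric(expand_info(get_info("cadd"), NA_real_))
  gene <- as.character(expand_info(get_info("gene"), ""))
  gene[is.na(gene)] <- ""
  effect <- as.character(expand_info(get_info("effect"), "other"))
  effect[is.na(effect)] <- "other"
  unknown_eff <- !effect %in% effect_levels()
  if (any(unknown_eff)) {
    warning("unknown effect class(es) coerced to 'other': ",
            paste(unique(effect[unknown_eff]), collapse = ", "))
    effect[unknown_eff] <- "other"
  }
  pon_raw <- get_info("pon")
  in_pon <- if (is.null(pon_raw)) rep(FALSE, length(rec)) else
    as.logical(pon_raw)[rec]

  pred_raw <- get_info("pred")
  pred <- matrix("missing", nrow = length(rec), ncol = 5)
  if (!is.null(pred_raw)) {
    for (i in seq_len(nrec)) {
      vals <- unlist(pred_raw[i])
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      calls <- unname(code_to_pred[vals])
      calls[is.na(calls)] <- "missing"
      calls <- head(c(calls, rep("missing", 5)), 5)
      pred[rec == i, ] <- matrix(calls, nrow = sum(rec == i), ncol = 5,
                                 byrow = TRUE)
    }
  }

  tr <- trim_alleles_vec(pos[rec], ref[rec], alts)
  validate_alleles(data.frame(id = names(rr)[rec], ref = tr$ref,
                              alt = tr$alt, stringsAsFactors = FALSE))
  vs <- variant_set(data.frame(chrom = chrom[rec], pos = tr$pos,
                               ref = tr$ref, alt = tr$alt, gene = gene,
                               effect = effect, pop_af = pop_af,
                               cadd_phred = cadd, in_pon = in_pon,
                               quality_pass = filt[rec] %in% c("PASS", "."),
                               stringsAsFactors = FALSE),
                    geno = counts, pred = pred)
  attr(vs, "phased") <- phased
  vs
}

#' Write a variant_set as an annotated VCF
#'
#' Emits VCF 4.2 with the INFO annotation bundle and per-sample GT. Allele
#' counts map to unphased genotypes (`0/0`, `0/1`, `1/1`, `./.`) unless a
#' phased genotype-string matrix is supplied (as the simulator does, so
#' haplotype phase survives the round trip). Output is deterministic:
#' records sorted by (chrom, pos, alt), no timestamps.
#'
#' @param vs a [variant_set()].
#' @param path output path.
#' @param phased_gt optional character matrix (variants x samples) of
#'   ready-made GT strings (e.g. `"0|1"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, phased_gt = NULL) {
  v <- vs$variants
  ord <- order(v$chrom, v$pos, v$ref, v$alt)
  v <- v[ord, , drop = FALSE]
  geno <- vs$geno[ord, , drop = FALSE]
  pred <- vs$pred[ord, , drop = FALSE]
  if (!is.null(phased_gt)) phased_gt <- phased_gt[ord, , drop = FALSE]

  contigs <- vapply(split(v$pos + nchar(v$ref), v$chrom), max, 1)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs + 1000L)),
           "##INFO=<ID=POP_AF,Number=1,Type=Float,Description=\"Population alternate allele frequency\">",
           "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD PHRED deleteriousness score\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect class\">",
           "##INFO=<ID=PRED,Number=.,Type=String,Description=\"Five pathogenicity predictor calls (P/B/M)\">",
           "##INFO=<ID=PON,Number=0,Type=Flag,Description=\"Pool of normals membership\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (ncol(geno)) c("FORMAT", colnames(geno))),
                 collapse = "\t"))
  info <- paste0(
    ifelse(is.na(v$pop_af), "", sprintf("POP_AF=%.6g;", v$pop_af)),
    ifelse(is.na(v$cadd_phred), "", sprintf("CADD=%.6g;", v$cadd_phred)),
    ifelse(v$gene == "", "", paste0("GENE=", v$gene, ";")),
    "EFFECT=", v$effect,
    ";PRED=", apply(pred, 1, function(p)
      paste(pred_to_code[p], collapse = ",")),
    ifelse(v$in_pon, ";PON", ""))
  body_cols <- list(v$chrom, v$pos, v$id, v$ref, v$alt, ".",
                    ifelse(v$quality_pass, "PASS", "LowQual"), info)
  if (ncol(geno)) {
    gt <- if (!is.null(phased_gt)) phased_gt else {
      m <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
      m[!is.na(geno) & geno == 0L] <- "0/0"
      m[!is.na(geno) & geno == 1L] <- "0/1"
      m[!is.na(geno) & geno == 2L] <- "1/1"
      m
    }
    body_cols <- c(body_cols, list("GT"),
                   lapply(seq_len(ncol(geno)), function(j) gt[, j]))
  }
  writeLines(c(hdr, do.call(paste, c(body_cols, sep = "\t"))), path)
  invisible(path)
}
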