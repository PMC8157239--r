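# Breakend orientation conventions
#
# orient "+" at a breakend means the junction lies on the 3' side of pos
# (the retained segment extends leftward into the breakend); "-" means the
# junction is on the 5' side. Canonical intrachromosomal types:
#   DEL (+,-)   DUP (-,+)   INV (+,+)   INS (+,-)
# In BND ALT notation the local orientation is "+" when the record starts
# with the REF base (t[p[ or t]p]) and "-" when it ends with it.

sv_orients <- list(DEL = c("+", "-"), DUP = c("-", "+"),
                   INV = c("+", "+"), INS = c("+", "-"))

#' Read a structural-variant VCF into a breakend-pair table
#'
#' Supports symbolic records (`<DEL>` etc. with `SVTYPE`/`END`, optional
#' `CIPOS`/`CIEND`) and paired breakend (`BND`) records joined exactly once
#' via `MATEID`; an orphan breakend whose mate is absent is dropped with a
#' warning. Missing confidence intervals default to `[0, 0]`. The carrying
#' sample comes from the `SAMPLE` INFO key when present, otherwise from the
#' first carrier genotype column.
#'
#' @param path SV VCF file.
#' @return a [breakend_pairs()] table.
#' @export
read_sv_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ids <- names(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  altc <- vapply(seq_along(rr), function(i)
    as.character(VariantAnnotation::alt(vcf)[[i]][1]), "")
  svtype <- if ("SVTYPE" %in% colnames(info)) as.character(info$SVTYPE) else
    gsub("[<>]", "", altc)
  get_ci <- function(key, i) {
    if (!key %in% colnames(info)) return(c(0L, 0L))
    v <- info[[key]][[i]]
    if (length(v) < 2L || all(is.na(v))) c(0L, 0L) else as.integer(v[1:2])
  }
  smp <- function(i) {
    if ("SAMPLE" %in% colnames(info)) return(as.character(info$SAMPLE[i]))
    gtm <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (is.null(gtm)) return(NA_character_)
    carrier <- which(grepl("1", gtm[i, ]))
    if (length(carrier)) colnames(gtm)[carrier[1]] else NA_character_
  }

  rows <- list()
  sym <- which(svtype != "BND")
  for (i in sym) {
    endpos <- as.integer(info$END[i] %||% pos[i])
    if (is.na(endpos)) endpos <- pos[i]
    ci1 <- get_ci("CIPOS", i); ci2 <- get_ci("CIEND", i)
    ors <- sv_orients[[svtype[i]]] %||% c("+", "-")
    rows[[length(rows) + 1L]] <- data.frame(
      sv_id = ids[i], sv_type = svtype[i],
      chrom1 = chrom[i], pos1 = pos[i], orient1 = ors[1],
      chrom2 = chrom[i], pos2 = endpos, orient2 = ors[2],
      ci1_lo = ci1[1], ci1_hi = ci1[2], ci2_lo = ci2[1], ci2_hi = ci2[2],
      sample = smp(i), stringsAsFactors = FALSE)
  }

  bnd <- which(svtype == "BND")
  if (length(bnd)) {
    mate <- rep(NA_character_, length(rr))
    if ("MATEID" %in% colnames(info)) {
      mid <- info$MATEID
      mate[bnd] <- vapply(bnd, function(i) {
        v <- unlist(mid[i])
        if (length(v)) as.character(v[1]) else NA_character_
      }, "")
    }
    done <- character(0)
    local_orient <- function(a) if (grepl("^[A-Za-z]", a)) "+" else "-"
    for (i in bnd) {
      if (ids[i] %in% done) next
      j <- match(mate[i], ids)
      if (is.na(j)) {
        warning("orphan breakend dropped: ", ids[i])
        next
      }
      done <- c(done, ids[i], ids[j])
      ci1 <- get_ci("CIPOS", i); ci2 <- get_ci("CIPOS", j)
      # a mate pair named X_1/X_2 keeps its base id X
      base <- unique(sub("_[12]$", "", c(ids[i], ids[j])))
      pair_id <- if (length(base) == 1L) base else
        paste(sort(c(ids[i], ids[j])), collapse = "__")
      rows[[length(rows) + 1L]] <- data.frame(
        sv_id = pair_id,
        sv_type = "BND",
        chrom1 = chrom[i], pos1 = pos[i], orient1 = local_orient(altc[i]),
        chrom2 = chrom[j], pos2 = pos[j], orient2 = local_orient(altc[j]),
        ci1_lo = ci1[1], ci1_hi = ci1[2], ci2_lo = ci2[1], ci2_hi = ci2[2],
        sample = smp(i), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(breakend_pairs(data.frame(
      sv_id = character(0), sv_type = character(0), chrom1 = character(0),
      pos1 = integer(0), orient1 = character(0), chrom2 = character(0),
      pos2 = integer(0), orient2 = character(0), sample = character(0),
      stringsAsFactors = FALSE)))
  }
  breakend_pairs(do.call(rbind, rows))
}

#' Write a breakend-pair table as an SV VCF
#'
#' Non-BND variants become symbolic records (`SVTYPE`, `END`, `CIPOS`,
#' `CIEND`, `SAMPLE`); BND pairs become two mutually mated breakend lines.
#' Deterministic output ordered by (chrom1, pos1, sv_id).
#'
#' @param svs a [breakend_pairs()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path) {
  svs <- svs[order(svs$chrom1, svs$pos1, svs$sv_id), , drop = FALSE]
  maxpos <- c(tapply(svs$pos1, svs$chrom1, max), tapply(svs$pos2, svs$chrom2, max))
  contig <- tapply(maxpos, names(maxpos), max)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contig),
                   as.integer(contig + 10000L)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of intrachromosomal variant\">",
           "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
           "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around END\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Carrying sample\">",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  lines <- character(0)
  for (k in seq_len(nrow(svs))) {
    s <- svs[k, ]
    if (s$sv_type != "BND") {
      info <- sprintf("SVTYPE=%s;END=%d;CIPOS=%d,%d;CIEND=%d,%d;SAMPLE=%s",
                      s$sv_type, s$pos2, s$ci1_lo, s$ci1_hi,
                      s$ci2_lo, s$ci2_hi, s$sample)
      lines <- c(lines, paste(s$chrom1, s$pos1, s$sv_id, "N",
                              paste0("<", s$sv_type, ">"), ".", "PASS",
                              info, sep = "\t"))
    } else {
      id1 <- paste0(s$sv_id, "_1"); id2 <- paste0(s$sv_id, "_2")
      bra <- function(orient_remote, loc) {
        if (orient_remote == "-") paste0("[", loc, "[") else
          paste0("]", loc, "]")
      }
      alt1 <- if (s$orient1 == "+")
        paste0("N", bra(s$orient2, paste0(s$chrom2, ":", s$pos2))) else
          paste0(bra(s$orient2, paste0(s$chrom2, ":", s$pos2)), "N")
      alt2 <- if (s$orient2 == "+")
        paste0("N", bra(s$orient1, paste0(s$chrom1, ":", s$pos1))) else
          paste0(bra(s$orient1, paste0(s$chrom1, ":", s$pos1)), "N")
      i1 <- sprintf("SVTYPE=BND;MATEID=%s;CIPOS=%d,%d;SAMPLE=%s",
                    id2, s$ci1_lo, s$ci1_hi, s$sample)
      i2 <- sprintf("SVTYPE=BND;MATEID=%s;CIPOS=%d,%d;SAMPLE=%s",
                    id1, s$ci2_lo, s$ci2_hi, s$sample)
      lines <- c(lines,
                 paste(s$chrom1, s$pos1, id1, "N", alt1, ".", "PASS", i1,
                       sep = "\t"),
                 paste(s$chrom2, s$pos2, id2, "N", alt2, ".", "PASS", i2,
                       sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
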