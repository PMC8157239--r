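#' Read a 6-column PED pedigree file
#'
#' Columns: family id, individual id, father, mother, sex (1 male, 2
#' female, 0 unknown), phenotype (2 = affected). Parent id 0 marks a
#' founder. Construction resolves parent links and rejects cycles and
#' unknown parent references.
#'
#' @param path PED file (whitespace-separated, no header).
#' @return a [pedigree()].
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family", "id", "father", "mother",
                                        "sex", "pheno"))
  pedigree(data.frame(id = as.character(df$id),
                      father = as.character(df$father),
                      mother = as.character(df$mother),
                      sex = ifelse(df$sex %in% 1:2, df$sex, NA_integer_),
                      affected = df$pheno == 2,
                      family = as.character(df$family),
                      stringsAsFactors = FALSE))
}

#' Write a pedigree as a 6-column PED file
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  df <- data.frame(ped$family, ped$id,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   ifelse(is.na(ped$sex), 0L, ped$sex),
                   ifelse(ped$affected, 2L, 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED
#'
#' Accepts BED12 (blocks become exons) or 4-column exon BED (one exon per
#' row, column 4 = gene symbol; rows of one gene form its transcript).
#' BED's 0-based half-open intervals are converted to the package's 1-based
#' closed convention on read.
#'
#' @param path BED file.
#' @return a [gene_models()].
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  if ("blocks" %in% colnames(md)) {
    ex <- do.call(rbind, lapply(seq_along(gr), function(i) {
      bl <- IRanges::shift(md$blocks[[i]], GenomicRanges::start(gr)[i] - 1L)
      data.frame(gene = md$name[i],
                 chrom = as.character(GenomicRanges::seqnames(gr)[i]),
                 start = IRanges::start(bl), end = IRanges::end(bl),
                 stringsAsFactors = FALSE)
    }))
    genes <- data.frame(gene = md$name,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        strand = as.character(GenomicRanges::strand(gr)),
                        tx_start = GenomicRanges::start(gr),
                        tx_end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
  } else {
    ex <- data.frame(gene = md$name,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    sp <- split(ex, ex$gene)
    genes <- do.call(rbind, lapply(sp, function(d)
      data.frame(gene = d$gene[1], chrom = d$chrom[1], strand = "+",
                 tx_start = min(d$start), tx_end = max(d$end),
                 stringsAsFactors = FALSE)))
  }
  gene_models(genes, ex)
}

#' Write gene models as 4-column exon BED (0-based half-open)
#' @param gm a [gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(gm, path) {
  ex <- gm$exons
  utils::write.table(data.frame(ex$chrom, ex$start - 1L, ex$end, ex$gene),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a pool-of-normals variant list (TSV: chrom, pos, ref, alt)
#' @param path TSV file with header.
#' @return data.frame with normalized allele representation.
#' @export
read_pon <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = "chrom")))
  normalize_variant_set(df[, c("chrom", "pos", "ref", "alt")])
}

#' Read an SV catalogue (TSV of breakend-pair columns)
#' @param path TSV with the [breakend_pairs()] columns.
#' @return a [breakend_pairs()] table.
#' @export
read_sv_catalogue <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (is.null(df$sample)) df$sample <- "catalogue"
  breakend_pairs(df)
}

#' Read a patients table (TSV: id, family, age, stage)
#'
#' `family` is a family id or `"reference"`; ages must be positive.
#'
#' @param path TSV file with header.
#' @return data.frame of class `patient_records`.
#' @export
read_patients <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("id", "family", "age", "stage") %in% names(df)))
  if (any(is.na(df$age) | df$age <= 0)) fv_abort("ages must be positive")
  df$stage <- as.character(df$stage)
  class(df) <- c("patient_records", "data.frame")
  df
}

#' Write the filtering report: funnel TSV, candidate TSV, JSON summary
#'
#' Deterministic output (fixed column order, sorted rows, no timestamps):
#' re-running the pipeline with the same inputs and seed reproduces the
#' files byte for byte.
#'
#' @param trace a [filter_trace()].
#' @param candidates candidate data.frame (may be empty; a header-only TSV
#'   is still written).
#' @param prefix output path prefix; writes `<prefix>.funnel.tsv`,
#'   `<prefix>.candidates.tsv`, `<prefix>.summary.json`.
#' @return character vector of the three paths, invisibly.
#' @export
write_report <- function(trace, candidates, prefix) {
  funnel_path <- paste0(prefix, ".funnel.tsv")
  cand_path <- paste0(prefix, ".candidates.tsv")
  json_path <- paste0(prefix, ".summary.json")
  utils::write.table(trace$stages, funnel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(candidates, cand_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    stages = trace$stages,
    n_candidates = nrow(candidates),
    surviving_ids = lapply(trace$ids, sort))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(funnel_path, cand_path, json_path))
}

#' Read a genetic map (TSV: chrom, pos, cm)
#' @param path TSV file with header.
#' @return data.frame with `chrom`, `pos`, `cm`.
#' @export
read_genetic_map <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("chrom", "cm") %in% names(df)))
  df
}
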