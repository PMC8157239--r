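# shared fixtures built in code

.fv_cache <- new.env(parent = emptyenv())

# the default synthetic cohort, simulated once per test run (~10 s)
default_cohort <- function() {
  if (is.null(.fv_cache$co))
    .fv_cache$co <- simulate_cohort(sim_spec(seed = 1))
  .fv_cache$co
}

# quick variant_set builder: n variants x samples, controllable columns
make_vs <- function(n = 5, samples = c("S1", "S2"), seed = 1, ...) {
  set.seed(seed)
  over <- list(...)
  v <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                  ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  alt = "T", stringsAsFactors = FALSE)
  v$alt[v$ref == "T"] <- "G"
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  geno <- matrix(1L, n, length(samples),
                 dimnames = list(NULL, samples))
  variant_set(v, geno = geno)
}

# random annotated cohort for property tests: nv variants, ns samples
random_vs <- function(nv, samples, seed) {
  set.seed(seed)
  v <- data.frame(
    chrom = sample(c("chr1", "chr2"), nv, replace = TRUE),
    pos = sample.int(1e6, nv),
    ref = sample(c("A", "C", "G", "T", "AT", "GCC"), nv, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
    effect = sample(effect_levels(), nv, replace = TRUE),
    pop_af = ifelse(runif(nv) < 0.3, NA, runif(nv)^3),
    cadd_phred = ifelse(runif(nv) < 0.2, NA, rexp(nv, 1 / 8)),
    in_pon = runif(nv) < 0.2,
    quality_pass = runif(nv) < 0.95,
    stringsAsFactors = FALSE)
  bad <- v$ref == v$alt
  v$alt[bad] <- ifelse(v$ref[bad] == "A", "C", "A")
  v <- v[!duplicated(v[, c("chrom", "pos", "ref", "alt")]), ]
  nv <- nrow(v)
  geno <- matrix(sample(c(0L, 0L, 0L, 1L, 1L, 2L, NA), nv * length(samples),
                        replace = TRUE), nv, length(samples),
                 dimnames = list(NULL, samples))
  pred <- matrix(sample(c("pathogenic", "benign", "missing"),
                        nv * 5, replace = TRUE, prob = c(.3, .6, .1)), nv, 5)
  variant_set(v, geno = geno, pred = pred)
}

# random gene models on chr1/chr2
random_gm <- function(n_genes = 10, seed = 1) {
  set.seed(seed)
  genes <- list(); exons <- list()
  for (k in seq_len(n_genes)) {
    ch <- sample(c("chr1", "chr2"), 1)
    s <- sample.int(9e5, 1)
    ex_start <- s + cumsum(sample(500:2000, 3))
    ex_end <- ex_start + sample(100:800, 3)
    genes[[k]] <- data.frame(gene = paste0("G", k), chrom = ch, strand = "+",
                             tx_start = s, tx_end = max(ex_end))
    exons[[k]] <- data.frame(gene = paste0("G", k), chrom = ch,
                             start = ex_start, end = ex_end)
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

# random breakend-pair tables for grouping property tests
random_svs <- function(n, seed, spread = 2000L) {
  set.seed(seed)
  pos1 <- sample.int(spread, n, replace = TRUE) + 1000L
  ch <- sample(c("chr1", "chr2"), n, replace = TRUE)
  breakend_pairs(data.frame(
    sv_id = sprintf("sv%03d", seq_len(n)),
    sv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
    chrom1 = ch, pos1 = pos1, orient1 = "+", chrom2 = ch,
    pos2 = pos1 + sample(500:1500, n, replace = TRUE), orient2 = "-",
    sample = sample(paste0("S", 1:4), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# trio pedigree
trio_ped <- function() {
  pedigree(data.frame(id = c("F", "M", "K"), father = c(NA, NA, "F"),
                      mother = c(NA, NA, "M"), sex = c(1, 2, 2),
                      affected = c(FALSE, TRUE, TRUE), family = "T",
                      stringsAsFactors = FALSE))
}
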