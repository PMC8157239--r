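# Independent naive oracles. These deliberately share no code with the
# package implementations they check: plain loops, no indexes, no vectorized
# shortcuts.

# strip shared suffix then prefix, one character at a time
naive_trim <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  repeat {
    if (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    } else break
  }
  repeat {
    if (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos <- pos + 1
    } else break
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# nested-loop reimplementation of the SNV filter stages on plain data frames
naive_shared <- function(v, geno, members) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (s in members) {
      g <- geno[i, s]
      if (is.na(g) || g < 1) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  v$id[keep]
}

naive_rare <- function(v, cutoff = 0.001) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v)))
    keep[i] <- is.na(v$pop_af[i]) || v$pop_af[i] <= cutoff
  v$id[keep]
}

naive_pon <- function(v) v$id[!v$in_pon]

naive_exonic <- function(v, exons, pad = 10) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    lo <- v$pos[i]; hi <- v$pos[i] + nchar(v$ref[i]) - 1
    for (k in seq_len(nrow(exons))) {
      if (exons$chrom[k] == v$chrom[i] &&
          hi >= exons$start[k] - pad && lo <= exons$end[k] + pad) {
        keep[i] <- TRUE; break
      }
    }
  }
  v$id[keep]
}

naive_consequence <- function(v, pred, predictor_min = 3) {
  lof <- c("frameshift", "stop_gain", "stop_loss", "start_loss")
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    np <- sum(pred[i, ] == "pathogenic")
    keep[i] <- v$effect[i] %in% lof ||
      (v$effect[i] == "nonsynonymous" && np >= predictor_min)
  }
  v$id[keep]
}

# O(n^3) transitive closure of a pairwise overlap matrix -> component labels
naive_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      nxt <- nxt + 1L
      labels[reach[i, ]] <- nxt
    }
  }
  labels
}

# permutation test of the Welch statistic (two-sided)
perm_t_p <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  tstat <- function(a, b)
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  tobs <- abs(tstat(x, y))
  all <- c(x, y); n1 <- length(x); n <- length(all)
  cnt <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n1)
    if (abs(tstat(all[idx], all[-idx])) >= tobs) cnt <- cnt + 1L
  }
  (cnt + 1) / (B + 1)
}

# Monte-Carlo gene-dropping estimate of the kinship coefficient: drop one
# unlinked locus many times, sample one allele from each of i and j, count
# identity by descent
mc_kinship <- function(ped, i, j, ndrops = 1e5, seed = 1) {
  set.seed(seed)
  ids <- ped$id
  fa <- match(ped$father, ids); mo <- match(ped$mother, ids)
  ord <- attr(ped, "topo")
  a1 <- matrix(0L, length(ids), ndrops)
  a2 <- matrix(0L, length(ids), ndrops)
  lab <- 0L
  for (k in ord) {
    if (is.na(fa[k])) {
      a1[k, ] <- lab + 1L; a2[k, ] <- lab + 2L; lab <- lab + 2L
    } else {
      pickf <- runif(ndrops) < 0.5
      a1[k, ] <- ifelse(pickf, a1[fa[k], ], a2[fa[k], ])
      pickm <- runif(ndrops) < 0.5
      a2[k, ] <- ifelse(pickm, a1[mo[k], ], a2[mo[k], ])
    }
  }
  ii <- match(i, ids); jj <- match(j, ids)
  si <- ifelse(runif(ndrops) < 0.5, a1[ii, ], a2[ii, ])
  sj <- ifelse(runif(ndrops) < 0.5, a1[jj, ], a2[jj, ])
  mean(si == sj)
}

# Mendelian-consistency check on allele counts (0/1/2)
mendel_consistent <- function(child, father, mother) {
  if (any(is.na(c(child, father, mother)))) return(TRUE)
  from_f <- if (father == 0) 0 else if (father == 2) 1 else c(0, 1)
  from_m <- if (mother == 0) 0 else if (mother == 2) 1 else c(0, 1)
  child %in% outer(from_f, from_m, `+`)
}
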