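#' Pedigree construction
#'
#' A pedigree is a table of individuals with optional father/mother links,
#' sex, affected status and a family id. Founders have both parent fields
#' `NA`. Construction validates that referenced parents exist and that the
#' parent relation is acyclic (an individual can never be its own ancestor).
#'
#' @param df data.frame with columns `id`, `father`, `mother` (ids or `NA`),
#'   and optionally `sex` (1 = male, 2 = female, NA = unknown), `affected`
#'   (logical) and `family` (character).
#' @return object of class `pedigree`: the validated data.frame with a
#'   topological order attribute (parents before children).
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("id", "father", "mother") %in% names(df)))
    fv_abort("pedigree needs columns id, father, mother")
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df$father[df$father %in% c("0", "")] <- NA_character_
  df$mother[df$mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id)) fv_abort("duplicate individual ids in pedigree")
  if (is.null(df$sex)) df$sex <- NA_integer_
  if (is.null(df$affected)) df$affected <- FALSE
  if (is.null(df$family)) df$family <- "F1"
  df$affected <- as.logical(df$affected)

  for (p in c(df$father, df$mother)) {
    if (!is.na(p) && !p %in% df$id)
      fv_abort(paste("unknown parent id referenced:", p))
  }

  ord <- topo_order(df)
  attr(df, "topo") <- ord
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn topological sort; reports a cycle path on failure
topo_order <- function(df) {
  ids <- df$id
  parents <- cbind(match(df$father, ids), match(df$mother, ids))
  n <- length(ids)
  indeg <- rowSums(!is.na(parents))
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed & indeg == 0)
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
    child_of <- which(parents[, 1] %in% ready | parents[, 2] %in% ready)
    for (ch in child_of)
      indeg[ch] <- sum(!is.na(parents[ch, ]) & !placed[parents[ch, ]])
  }
  if (length(ord) < n) {
    cyc <- ids[!placed]
    fv_abort(paste0("pedigree contains a cycle involving: ",
                    paste(cyc, collapse = " -> ")))
  }
  ord
}

#' Pedigree kinship matrix
#'
#' Computes the kinship coefficient phi for every pair of individuals by the
#' standard recursive algorithm over a topological order: founders are
#' unrelated and non-inbred (`phi(i,i) = 1/2`), `phi(i,i) = (1 +
#' phi(father_i, mother_i)) / 2`, and for `i` not an ancestor of `j`,
#' `phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2`. Inbreeding enters
#' through the self-kinship recursion.
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with dimnames = individual ids.
#' @export
kinship_matrix <- function(ped) {
  ids <- ped$id
  n <- length(ids)
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  ord <- attr(ped, "topo")
  for (i in ord) {
    phi[i, i] <- if (is.na(fa[i]) || is.na(mo[i])) 0.5 else
      0.5 * (1 + phi[fa[i], mo[i]])
    for (j in ord) {
      if (j == i) break  # only pairs with j placed before i
      pf <- if (is.na(fa[i])) 0 else phi[fa[i], j]
      pm <- if (is.na(mo[i])) 0 else phi[mo[i], j]
      phi[i, j] <- phi[j, i] <- 0.5 * (pf + pm)
    }
  }
  phi
}

#' Kinship coefficient between two pedigree members
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids.
#' @return kinship phi in `[0, 0.5]` (0.5 only for a fully inbred self pair).
#' @export
kinship_pedigree <- function(ped, i, j) {
  if (!all(c(i, j) %in% ped$id))
    fv_abort(paste("unknown individual id:",
                   paste(setdiff(c(i, j), ped$id), collapse = ", ")))
  kinship_matrix(ped)[i, j]
}

#' Classify a kinship coefficient into a relationship degree
#'
#' Uses the midpoint-in-log2 convention: degree `d` covers
#' `phi` in `(2^(-d-1.5), 2^(-d-0.5)]`, `self/MZ` is `phi > 2^(-1.5)`, and
#' anything at or below `2^(-max_degree-1.5)` is `unrelated`. Exact pedigree
#' values (1/4 parent-offspring, 1/8 aunt-niece, 1/64 second cousins) land
#' strictly inside their bands, so printed degrees (1, 2, 5) are recovered
#' exactly from exact phi.
#'
#' @param phi numeric vector of kinship coefficients in `[0, 0.5]`.
#' @param max_degree deepest degree reported before `unrelated` (default 9).
#' @return character vector: `"self/MZ"`, `"1"`..`"max_degree"`, `"unrelated"`.
#' @examples
#' degree_from_kinship(c(0.25, 0.125, 1/64, 0))
#' @export
degree_from_kinship <- function(phi, max_degree = 9L) {
  if (any(is.na(phi)) || any(phi < 0 | phi > 0.5))
    fv_abort("phi must lie in [0, 0.5]")
  out <- character(length(phi))
  for (k in seq_along(phi)) {
    p <- phi[k]
    if (p > 2^(-1.5)) { out[k] <- "self/MZ"; next }
    d <- which(vapply(seq_len(max_degree), function(dd)
      p > 2^(-dd - 1.5) && p <= 2^(-dd - 0.5), logical(1)))
    out[k] <- if (length(d)) as.character(d[1]) else "unrelated"
  }
  out
}

#' Numeric value of a degree label, for tolerance comparisons
#'
#' `self/MZ` maps to 0 and `unrelated` to `max_degree + 1`, so "both called
#' unrelated" compares as agreement.
#'
#' @param label character degree labels.
#' @param max_degree as in [degree_from_kinship()].
#' @return numeric vector.
#' @export
degree_numeric <- function(label, max_degree = 9L) {
  out <- suppressWarnings(as.numeric(label))
  out[label == "self/MZ"] <- 0
  out[label == "unrelated"] <- max_degree + 1
  out
}

#' All pairwise pedigree relationship degrees
#'
#' One row per unordered pair of the requested individuals. Individuals from
#' different families share no ancestors, so cross-family pairs come out
#' `unrelated` by construction.
#'
#' @param ped a [pedigree()] (may span several families).
#' @param ids individuals to compare; default all.
#' @param max_degree passed to [degree_from_kinship()].
#' @return data.frame with `id1`, `id2`, `phi`, `degree`.
#' @export
all_pairwise_degrees <- function(ped, ids = ped$id, max_degree = 9L) {
  if (length(ids) < 2L)
    return(data.frame(id1 = character(0), id2 = character(0),
                      phi = numeric(0), degree = character(0)))
  phi <- kinship_matrix(ped)[ids, ids, drop = FALSE]
  pr <- t(utils::combn(ids, 2L))
  p <- phi[cbind(pr[, 1], pr[, 2])]
  data.frame(id1 = pr[, 1], id2 = pr[, 2], phi = p,
             degree = degree_from_kinship(p, max_degree),
             stringsAsFactors = FALSE)
}

#' Affected members of each family in a pedigree
#' @param ped a [pedigree()].
#' @return named list: family id -> character vector of affected ids.
#' @export
affected_by_family <- function(ped) {
  aff <- ped[ped$affected, , drop = FALSE]
  split(aff$id, aff$family)
}
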