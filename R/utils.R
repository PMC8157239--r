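#' Derive a component seed from a run seed
#'
#' A single run seed fans out to per-component seeds so each simulator
#' component is independently reproducible. The derivation is a fixed integer
#' hash of the parent seed and a component tag; results stay within the
#' 32-bit signed range R requires of `set.seed()`.
#'
#' @param seed integer run seed.
#' @param tag character component tag (e.g. `"founders"`, `"family:B"`).
#' @param k optional integer offset for repeated draws under one tag.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  val <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + h * 7919 + k * 104729
  as.integer(val %% 2147483646)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable variant key used for joins and PoN matching
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

fv_abort <- function(msg, class = "famvar_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
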