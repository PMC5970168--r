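# Brute-force verification oracle for the Nei-Gojobori estimator.
#
# Independent re-derivation for small alignments: site fractions are
# counted by explicit neighbor-codon construction (no memoised tables)
# and pathway-averaged difference counts by recursive depth-first
# enumeration of substitution orderings (no permutation lists). Shares
# only the genetic-code constant and the method's conventions with
# compute_kaks, not its code paths.

.oracle_translate <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# Recursively enumerate every ordering of single-nucleotide steps from
# codon `a` to codon `b`, skipping branches that hit a stop codon.
# Returns a list of c(syn, nonsyn) per completed pathway.
.oracle_paths <- function(a, b) {
  if (identical(a, b)) return(list(c(0, 0)))
  out <- list()
  for (pos in 1:3) {
    if (substr(a, pos, pos) != substr(b, pos, pos)) {
      nxt <- a
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (.oracle_translate(nxt) == "*") next
      step_syn <- as.integer(.oracle_translate(a) == .oracle_translate(nxt))
      for (tail in .oracle_paths(nxt, b))
        out[[length(out) + 1L]] <- c(step_syn, 1L - step_syn) + tail
    }
  }
  out
}

#' Brute-force Ka/Ks oracle for small alignments
#'
#' Recomputes every [compute_kaks()] quantity by exhaustive enumeration:
#' direct per-codon site counting over all nine neighbor codons and
#' recursive enumeration of all substitution orderings per differing
#' codon. Intended as an independent cross-check in tests; limited to 50
#' codons.
#'
#' @param alignment A [codon_alignment()] with at most 50 codons.
#' @return Same one-row data frame as [compute_kaks()].
#' @export
kaks_oracle <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (length(alignment$codons_a) > 50L)
    stop("oracle limited to alignments of at most 50 codons")
  keep <- !alignment$masked
  ca <- alignment$codons_a[keep]; cb <- alignment$codons_b[keep]
  if (length(ca) == 0L)
    stop("no comparable codons after masking in pair '", alignment$id, "'")

  count_syn_sites <- function(codon) {
    aa <- .oracle_translate(codon)
    n_syn <- 0L
    for (pos in 1:3) {
      for (nt in c("A", "C", "G", "T")) {
        if (nt == substr(codon, pos, pos)) next
        alt <- codon
        substr(alt, pos, pos) <- nt
        if (.oracle_translate(alt) != "*" && .oracle_translate(alt) == aa)
          n_syn <- n_syn + 1L
      }
    }
    n_syn / 3
  }

  Sd <- 0; Nd <- 0; dead <- logical(length(ca))
  for (i in seq_along(ca)) {
    paths <- .oracle_paths(ca[[i]], cb[[i]])
    if (length(paths) == 0L) { dead[i] <- TRUE; next }
    m <- do.call(rbind, paths)
    Sd <- Sd + mean(m[, 1L]); Nd <- Nd + mean(m[, 2L])
  }
  if (any(dead)) {
    warning(sum(dead), " codon(s) masked in pair '", alignment$id,
            "': all mutational pathways pass through stop codons")
    ca <- ca[!dead]; cb <- cb[!dead]
  }
  if (length(ca) == 0L)
    stop("no comparable codons after masking in pair '", alignment$id, "'")
  S <- (sum(vapply(ca, count_syn_sites, numeric(1L))) +
          sum(vapply(cb, count_syn_sites, numeric(1L)))) / 2
  N <- 3 * length(ca) - S
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  selection <- if (is.na(ratio)) "undetermined"
  else if (abs(ratio - 1) <= 1e-9) "neutral"
  else if (ratio < 1) "purifying" else "positive"
  data.frame(pair_id = alignment$id, codons_compared = length(ca),
             S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, ratio = ratio, selection = selection,
             stringsAsFactors = FALSE)
}
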