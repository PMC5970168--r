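# Nei-Gojobori (1986) Ka/Ks estimation on codon-aligned sequence pairs,
# with Jukes-Cantor multiple-hit correction and selection classification.

NUCS <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- genetic_code()[codon]
  if (is.na(aa)) NA_character_ else unname(aa)
}

is_stop_codon <- function(codon) identical(translate_codon(codon), "*")

#' Construct a codon alignment
#'
#' @param seq_a,seq_b Aligned nucleotide strings (A/C/G/T, gap `-`,
#'   ambiguity `N`), equal length divisible by 3. Codons containing `-`
#'   or `N` in either sequence are masked pairwise before analysis; after
#'   masking, internal stop codons are rejected.
#' @param id Pair identifier.
#' @return A `codon_alignment` list with the codon triplets of both
#'   sequences and the mask.
#' @export
#' @examples
#' codon_alignment("AAACCC", "AAGCCC", id = "pair1")
codon_alignment <- function(seq_a, seq_b, id = "pair") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ") for pair '", id, "'")
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length ", nchar(seq_a), " not divisible by 3 for pair '",
         id, "'")
  for (s in c(seq_a, seq_b)) {
    bad <- which(!aa_split(s) %in% c(NUCS, "-", "N"))
    if (length(bad))
      stop("invalid nucleotide '", substr(s, bad[1L], bad[1L]),
           "' at position ", bad[1L], " in pair '", id, "'")
  }
  split_codons <- function(s)
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  masked <- grepl("[-N]", ca) | grepl("[-N]", cb)
  stops <- !masked & (vapply(ca, is_stop_codon, logical(1L)) |
                        vapply(cb, is_stop_codon, logical(1L)))
  if (any(stops))
    stop("internal stop codon at codon ", which(stops)[1L], " in pair '",
         id, "'")
  structure(list(id = id, codons_a = ca, codons_b = cb, masked = masked),
            class = "codon_alignment")
}

# Per-codon synonymous-site count: at each position, each of the three
# possible single-nucleotide changes contributes 1/3 of a synonymous site
# if it preserves the amino acid. Changes creating a stop codon count as
# nonsynonymous, which keeps S + N = 3 per codon. Memoised over the 61
# sense codons.
.syn_site_cache <- new.env(parent = emptyenv())
syn_sites <- function(codon) {
  hit <- .syn_site_cache[[codon]]
  if (!is.null(hit)) return(hit)
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (!is_stop_codon(alt) && identical(translate_codon(alt), aa))
        s <- s + 1 / 3
    }
  }
  .syn_site_cache[[codon]] <- s
  s
}

# All orderings of applying the nucleotide changes that turn codon a into
# codon b, as a list of position permutations.
.permute <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permute(v[-i]), function(p) c(v[i], p)))
  out
}

# Pathway-averaged (synonymous, nonsynonymous) difference counts for one
# codon pair. Pathways passing through a stop codon are excluded and the
# remaining pathways weighted equally. Returns c(NA, NA) if every pathway
# passes through a stop.
codon_pair_diffs <- function(a, b) {
  diff_pos <- which(aa_split(a) != aa_split(b))
  k <- length(diff_pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (ord in .permute(diff_pos)) {
    cur <- a; sd_p <- 0; nd_p <- 0; valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (is_stop_codon(nxt)) { valid <- FALSE; break }
      if (identical(translate_codon(cur), translate_codon(nxt)))
        sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      cur <- nxt
    }
    if (valid) {
      sd_tot <- sd_tot + sd_p; nd_tot <- nd_tot + nd_p
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(syn = NA_real_, nonsyn = NA_real_))
  c(syn = sd_tot / n_valid, nonsyn = nd_tot / n_valid)
}

# Jukes-Cantor multiple-hit correction; undefined (NA) at p >= 3/4.
jukes_cantor <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori Ka/Ks estimation for one codon-aligned pair
#'
#' Counting method of Nei & Gojobori (1986): synonymous site fractions
#' are computed per codon from the standard genetic code (single-
#' nucleotide changes to stop codons count as nonsynonymous, so S + N =
#' 3 x compared codons) and averaged between the two sequences;
#' multi-nucleotide codon differences are resolved by enumerating all
#' mutational pathways that avoid stop codons, weighted equally; the raw
#' proportions pS = Sd/S and pN = Nd/N receive the Jukes-Cantor
#' correction d = -(3/4) ln(1 - 4p/3). Selection is classified from
#' Ka/Ks: < 1 purifying, > 1 positive, = 1 (within 1e-9) neutral;
#' `undetermined` when the ratio is undefined (Ks = 0, or a proportion
#' >= 3/4 where the correction diverges).
#'
#' Codons whose every mutational pathway passes through a stop codon are
#' masked with a warning. The standard nuclear genetic code (translation
#' table 1) is assumed throughout.
#'
#' @param alignment A [codon_alignment()].
#' @return One-row data frame: `pair_id`, `codons_compared`, `S`, `N`
#'   (fractional site counts), `Sd`, `Nd` (pathway-weighted difference
#'   counts), `pS`, `pN`, `Ks`, `Ka`, `ratio` (Ka/Ks, NA if undefined),
#'   `selection` (purifying/neutral/positive/undetermined).
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
#' @examples
#' compute_kaks(codon_alignment("AAACCCGGGTTT", "AAGCCCGGGTTT"))
compute_kaks <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  keep <- !alignment$masked
  ca <- alignment$codons_a[keep]; cb <- alignment$codons_b[keep]
  if (length(ca) == 0L)
    stop("no comparable codons after masking in pair '", alignment$id, "'")
  diffs <- vapply(seq_along(ca),
                  function(i) codon_pair_diffs(ca[[i]], cb[[i]]),
                  numeric(2L))
  dead <- is.na(diffs[1L, ])
  if (any(dead)) {
    warning(sum(dead), " codon(s) masked in pair '", alignment$id,
            "': all mutational pathways pass through stop codons")
    ca <- ca[!dead]; cb <- cb[!dead]; diffs <- diffs[, !dead, drop = FALSE]
    if (length(ca) == 0L)
      stop("no comparable codons after masking in pair '", alignment$id, "'")
  }
  s_a <- sum(vapply(ca, syn_sites, numeric(1L)))
  s_b <- sum(vapply(cb, syn_sites, numeric(1L)))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(diffs[1L, ]); Nd <- sum(diffs[2L, ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jukes_cantor(pS); Ka <- jukes_cantor(pN)
  ratio <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  selection <- if (is.na(ratio)) "undetermined"
  else if (abs(ratio - 1) <= 1e-9) "neutral"
  else if (ratio < 1) "purifying" else "positive"
  data.frame(pair_id = alignment$id, codons_compared = length(ca),
             S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, ratio = ratio, selection = selection,
             stringsAsFactors = FALSE)
}

#' Ka/Ks for a set of codon-aligned pairs
#'
#' @param alignments List of [codon_alignment()]s.
#' @return Data frame, one row per pair (see [compute_kaks()]).
#' @export
compute_kaks_table <- function(alignments) {
  do.call(rbind, lapply(alignments, compute_kaks))
}
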