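# Shared test helpers: independent random-instance generators that do
# not reuse package generator code paths.

GC1 <- Biostrings::GENETIC_CODE

random_sense_codon_h <- function() {
  repeat {
    codon <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                   collapse = "")
    if (GC1[[codon]] != "*") return(codon)
  }
}

# Random codon-aligned pair with arbitrary (including multi-hit) codon
# differences; both endpoint sequences are stop-free.
random_codon_pair <- function(n_codons = 10L, p_mut = 0.25, id = "rnd") {
  a <- vapply(seq_len(n_codons), function(i) random_sense_codon_h(),
              character(1L))
  b <- vapply(a, function(codon) {
    repeat {
      alt <- codon
      for (pos in 1:3) {
        if (runif(1) < p_mut)
          substr(alt, pos, pos) <- sample(c("A", "C", "G", "T"), 1L)
      }
      if (GC1[[alt]] != "*") return(alt)
    }
  }, character(1L))
  codon_alignment(paste(a, collapse = ""), paste(b, collapse = ""), id = id)
}

# Random tripartite edge list over small node sets.
random_tripartite_edges <- function(n_kkk = 4L, n_kk = 3L, n_k = 4L,
                                    p_edge = 0.5) {
  kkks <- sprintf("MEKK%d", seq_len(n_kkk))
  kks <- sprintf("MKK%d", seq_len(n_kk))
  ks <- sprintf("MPK%d", seq_len(n_k))
  up <- expand.grid(upstream = kkks, downstream = kks,
                    stringsAsFactors = FALSE)
  dn <- expand.grid(upstream = kks, downstream = ks,
                    stringsAsFactors = FALSE)
  up <- up[runif(nrow(up)) < p_edge, ]
  dn <- dn[runif(nrow(dn)) < p_edge, ]
  if (!nrow(up) || !nrow(dn)) return(NULL)
  up$tier <- "KKK-KK"; dn$tier <- "KK-K"
  rbind(up, dn)
}

# Brute-force module enumeration by triple scan (independent of the
# merge-based implementation).
brute_force_modules <- function(edges, exclusions = character()) {
  up <- edges[edges$tier == "KKK-KK", ]
  dn <- edges[edges$tier == "KK-K", ]
  count <- 0L
  for (i in seq_len(nrow(up))) for (j in seq_len(nrow(dn))) {
    if (up$downstream[i] == dn$upstream[j] &&
        !any(c(up$upstream[i], up$downstream[i], dn$downstream[j]) %in%
               exclusions))
      count <- count + 1L
  }
  count
}

# The twelve MAPKKKs surveyed by qRT-PCR: the 14 Y2H interactors minus
# the two low-expression genes.
investigated_genes <- function() {
  fx <- load_cotton_fixtures()
  setdiff(unique(fx$kkk_kk$upstream), c("MEKK19", "RAF17_2"))
}

# Planted qRT-PCR design for one treatment: listed genes at `fold_up`,
# every other investigated gene at fold 1.
planted_design <- function(treatment, induced_genes, genes, fold_up = 4) {
  data.frame(gene = genes, treatment = treatment,
             fold = ifelse(genes %in% induced_genes, fold_up, 1),
             peak_time_h = 12, stringsAsFactors = FALSE)
}
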