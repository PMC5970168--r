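# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Deterministic sub-stream seeds: one user-facing seed fans out to
# per-generator seeds so adding a generator never perturbs another's draws.
# Kept below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * stream) %% 2147483647)
}

# Numeric-aware ordering key for gene names such as MEKK4_2, MPK13:
# digit runs are zero-padded so MPK3 sorts before MPK13.
gene_sort_key <- function(x) {
  vapply(as.character(x), function(s) {
    toks <- regmatches(s, gregexpr("\\d+|\\D+", s))[[1L]]
    toks <- vapply(toks, function(tok) {
      if (grepl("^\\d+$", tok)) sprintf("%06d", as.integer(tok)) else tok
    }, character(1L))
    paste(toks, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

gene_order <- function(...) {
  keys <- lapply(list(...), gene_sort_key)
  do.call(order, keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Collapse a character vector of residues to a string and back.
aa_collapse <- function(x) paste(x, collapse = "")
aa_split <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
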