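# File format helpers: FASTA via Biostrings, TSV tables with a
# provenance header comment.

#' Read protein records from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return List of [protein_record()]s, named by FASTA id (first token
#'   of the header).
#' @export
read_proteins_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  setNames(Map(protein_record, ids, as.character(aa)), ids)
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1L),
                                         "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1L), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read codon-aligned pairs from paired FASTA
#'
#' Two records per pair, in order; record ids of the form `pairid|a` and
#' `pairid|b` are honored, otherwise consecutive records are paired and
#' the first id names the pair.
#'
#' @param path FASTA file of aligned nucleotide sequences.
#' @return List of [codon_alignment()]s.
#' @export
read_codon_pairs_fasta <- function(path) {
  nt <- Biostrings::readDNAStringSet(path)
  if (length(nt) %% 2L != 0L)
    stop("paired FASTA '", path, "' has an odd number of records")
  ids <- sub("\\s.*$", "", names(nt))
  out <- list()
  for (i in seq(1L, length(nt), 2L)) {
    pid <- sub("\\|[ab]$", "", ids[i])
    out[[pid]] <- codon_alignment(as.character(nt[[i]]),
                                  as.character(nt[[i + 1L]]), id = pid)
  }
  out
}

#' Write codon-aligned pairs to paired FASTA
#'
#' @param alignments List of [codon_alignment()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_pairs_fasta <- function(alignments, path) {
  seqs <- unlist(lapply(alignments, function(al)
    setNames(c(paste(al$codons_a, collapse = ""),
               paste(al$codons_b, collapse = "")),
             paste0(al$id, c("|a", "|b")))))
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read an FPKM expression table
#'
#' First column gene id, remaining columns tissues.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_fpkm_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  mat
}

#' Read a long-format qRT-PCR Ct table
#'
#' @param path TSV with columns gene, treatment, time_h, arm, replicate,
#'   ct_target, ct_reference.
#' @return Data frame.
#' @export
read_ct_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Read an interaction edge list
#'
#' @param path TSV with columns upstream, downstream, tier.
#' @return Validated [interaction_edges()] data frame.
#' @export
read_edges_tsv <- function(path) {
  interaction_edges(read.delim(path, stringsAsFactors = FALSE,
                               comment.char = "#"))
}

# Atomic TSV writer with a provenance header comment.
write_tsv_atomic <- function(df, path, provenance = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}
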