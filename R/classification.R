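# Subfamily classification of MAPKKK protein sequences by the conserved
# catalytic-domain signature motifs, plus name-based subfamily mapping.

# Signature patterns. X matches any of the 20 standard residues only.
AA_CLASS <- "[ACDEFGHIKLMNPQRSTVWY]"
SIGNATURES <- list(
  MEKK = paste0("G[TS]P", AA_CLASS, "[WYF]MAPEV"),
  ZIK  = "GTPEFMAPE[LVM][YFL]",
  Raf  = paste0("GT", AA_CLASS, AA_CLASS, "[WY]MAPE")
)
# Precedence: Raf's motif is the least specific (it contains many MEKK
# matches), and MEKK/ZIK motifs are mutually exclusive, so the most
# specific patterns are tried first.
SIGNATURE_PRECEDENCE <- c("MEKK", "ZIK", "Raf")

SUBFAMILY_LEVELS <- c("MEKK", "Raf", "ZIK", "unclassified")

# Gene-name prefix -> subfamily. CTR1 and EDR1 are Raf-subfamily members.
PREFIX_SUBFAMILY <- c(MEKK = "MEKK", ANP = "MEKK", YDA = "MEKK",
                      RAF = "Raf", CTR = "Raf", EDR = "Raf",
                      ZIK = "ZIK")

#' Construct a protein record
#'
#' @param id Unique identifier.
#' @param sequence Amino-acid sequence using the 20 standard one-letter
#'   codes; any other character is rejected with its position reported.
#' @param name Display name (e.g. `"MEKK4_2"`); defaults to `id`.
#' @return A `protein_record` list with elements `id`, `name`, `sequence`.
#' @export
#' @examples
#' protein_record("p1", "MSGTPAWMAPEVIR")
protein_record <- function(id, sequence, name = id) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for record '", id, "'")
  bad <- which(!aa_split(sequence) %in% AA20)
  if (length(bad)) {
    stop("non-standard residue '", substr(sequence, bad[1L], bad[1L]),
         "' at position ", bad[1L], " in record '", id, "'")
  }
  structure(list(id = id, name = name, sequence = sequence),
            class = "protein_record")
}

#' Classify a kinase sequence into a MAPKKK subfamily
#'
#' Scans the sequence for the conserved catalytic signatures
#' `G(T/S)PX(W/Y/F)MAPEV` (MEKK), `GTPEFMAPE(L/V/M)(Y/F/L)` (ZIK) and
#' `GTXX(W/Y)MAPE` (Raf), in that precedence order. The first subfamily
#' whose signature occurs anywhere in the sequence wins; within a
#' subfamily the leftmost occurrence is reported. MEKK is tried before
#' Raf because many MEKK signature instances also satisfy the looser Raf
#' motif; ZIK and MEKK motifs are mutually exclusive (ZIK requires E
#' where MEKK requires P at position 4).
#'
#' @param record A [protein_record()] (or a plain sequence string).
#' @return A one-row data frame: `id`, `subfamily` (factor with levels
#'   MEKK, Raf, ZIK, unclassified), `match_start` (1-based position, NA
#'   if unclassified), `matched_text`.
#' @export
#' @examples
#' classify_subfamily(protein_record("x", "AAAGTPAWMAPEVAAA"))
classify_subfamily <- function(record) {
  if (is.character(record)) record <- protein_record("seq", record)
  stopifnot(inherits(record, "protein_record"))
  for (fam in SIGNATURE_PRECEDENCE) {
    m <- regexpr(SIGNATURES[[fam]], record$sequence, perl = TRUE)
    if (m > 0L) {
      return(data.frame(
        id = record$id,
        subfamily = factor(fam, levels = SUBFAMILY_LEVELS),
        match_start = as.integer(m),
        matched_text = substr(record$sequence, m,
                              m + attr(m, "match.length") - 1L),
        stringsAsFactors = FALSE))
    }
  }
  data.frame(id = record$id,
             subfamily = factor("unclassified", levels = SUBFAMILY_LEVELS),
             match_start = NA_integer_, matched_text = NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify a set of protein records
#'
#' @param records List of [protein_record()]s or a named character vector
#'   of sequences.
#' @return Data frame, one row per record (see [classify_subfamily()]).
#' @export
classify_subfamilies <- function(records) {
  if (is.character(records)) {
    ids <- names(records) %||% paste0("seq", seq_along(records))
    records <- Map(protein_record, ids, records)
  }
  do.call(rbind, lapply(records, classify_subfamily))
}

#' Map a paper-convention gene name to its MAPKKK subfamily
#'
#' Names follow the convention prefix + number + optional `_variant`
#' (e.g. `MEKK4_2`, `RAF31_1`, `CTR1_1`, `ZIK1`). CTR1 and EDR1 are
#' Raf-subfamily members; ANP and YDA belong to the MEKK subfamily.
#'
#' @param name Character vector of gene names.
#' @return Character vector of subfamilies (`"MEKK"`, `"Raf"`, `"ZIK"`).
#' @export
#' @examples
#' subfamily_from_name(c("CTR1_1", "MEKK4_2", "ZIK1"))
subfamily_from_name <- function(name) {
  vapply(as.character(name), function(nm) {
    prefix <- sub("^([A-Za-z]+).*$", "\\1", nm)
    fam <- PREFIX_SUBFAMILY[toupper(prefix)]
    if (is.na(fam)) {
      stop("gene name '", nm, "' has no recognized MAPKKK subfamily prefix ",
           "(expected one of: ", paste(names(PREFIX_SUBFAMILY), collapse = ", "),
           ")")
    }
    unname(fam)
  }, character(1L), USE.NAMES = FALSE)
}

#' Tabulate subfamily calls
#'
#' @param calls Data frame of calls from [classify_subfamilies()], or a
#'   character vector of subfamily labels.
#' @return Named integer vector over MEKK, Raf, ZIK, unclassified;
#'   entries sum to the number of inputs.
#' @export
count_by_subfamily <- function(calls) {
  labels <- if (is.data.frame(calls)) as.character(calls$subfamily) else
    as.character(calls)
  out <- table(factor(labels, levels = SUBFAMILY_LEVELS))
  setNames(as.integer(out), names(out))
}
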