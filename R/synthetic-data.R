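# Synthetic-data generators with planted ground truth: proteins with
# planted subfamily signatures, codon pairs with controlled synonymous/
# nonsynonymous divergence, FPKM tissue matrices, and replicate qRT-PCR
# time courses with planted fold-change effects.

#' Simulation configuration
#'
#' @param seed Integer seed; all generator randomness flows from it via
#'   deterministic per-generator sub-streams.
#' @param n_per_subfamily Proteins generated per subfamily (default 5).
#' @param protein_length Residues per protein (default 60; must exceed
#'   the longest signature by at least 2).
#' @param codon_pair_spec List of `c(n_codons, n_syn, n_nonsyn)` triples.
#' @param n_tissues Tissues in FPKM matrices (default 8).
#' @param qpcr_noise_sd Gaussian Ct noise, in Ct units (default 0.1).
#' @param qpcr_replicates Replicates per arm and time point (default 3,
#'   minimum 2).
#' @param timepoints Sampling times in hours, strictly increasing
#'   (default 0, 0.5, 1, 2, 4, 6, 8, 10, 12, 24 h).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_per_subfamily = 5L,
                       protein_length = 60L,
                       codon_pair_spec = list(c(100, 3, 0), c(300, 6, 2)),
                       n_tissues = 8L,
                       qpcr_noise_sd = 0.1,
                       qpcr_replicates = 3L,
                       timepoints = c(0, 0.5, 1, 2, 4, 6, 8, 10, 12, 24)) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (qpcr_replicates < 2L) stop("qpcr_replicates must be >= 2")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (n_per_subfamily < 0L) stop("n_per_subfamily must be >= 0")
  if (protein_length < 13L)
    stop("protein_length must be >= signature length + 2 (13)")
  for (spec in codon_pair_spec) {
    if (length(spec) != 3L || spec[2L] + spec[3L] > spec[1L])
      stop("codon_pair_spec entries are c(n_codons, n_syn, n_nonsyn) with ",
           "n_syn + n_nonsyn <= n_codons")
  }
  structure(list(seed = as.integer(seed),
                 n_per_subfamily = as.integer(n_per_subfamily),
                 protein_length = as.integer(protein_length),
                 codon_pair_spec = codon_pair_spec,
                 n_tissues = as.integer(n_tissues),
                 qpcr_noise_sd = qpcr_noise_sd,
                 qpcr_replicates = as.integer(qpcr_replicates),
                 timepoints = timepoints),
            class = "sim_config")
}

# Draw one concrete signature instance for a subfamily.
sample_signature <- function(subfamily) {
  pick <- function(opts) sample(opts, 1L)
  switch(subfamily,
    MEKK = paste0("G", pick(c("T", "S")), "P", pick(AA20),
                  pick(c("W", "Y", "F")), "MAPEV"),
    ZIK  = paste0("GTPEFMAPE", pick(c("L", "V", "M")), pick(c("Y", "F", "L"))),
    Raf  = paste0("GT", pick(AA20), pick(AA20), pick(c("W", "Y")), "MAPE"))
}

#' Generate proteins with planted subfamily signatures
#'
#' Each record carries exactly one planted signature of its assigned
#' subfamily at a recorded position, embedded in background residues
#' drawn uniformly from the 20 standard amino acids. Candidates are
#' rejection-sampled until the classifier's call equals the planted
#' label at the planted position and no signature of any subfamily
#' occurs elsewhere, so label recovery is exact by construction (not
#' probabilistic). Note that some signature instances overlap across
#' subfamilies (e.g. a ZIK instance ending in V also satisfies the MEKK
#' motif); rejection resamples those.
#'
#' @param config A [sim_config()].
#' @param max_retries Bound on rejection attempts per record.
#' @return List: `records` (list of [protein_record()]s), `truth` (data
#'   frame: id, subfamily, match_start), `seed`.
#' @export
gen_proteins <- function(config, max_retries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  records <- list(); truth <- NULL
  for (fam in c("MEKK", "Raf", "ZIK")) {
    for (i in seq_len(config$n_per_subfamily)) {
      id <- sprintf("syn_%s_%02d", fam, i)
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        sig <- sample_signature(fam)
        n_bg <- config$protein_length - nchar(sig)
        pos <- sample.int(n_bg + 1L, 1L)  # 1-based signature start
        bg <- sample(AA20, n_bg, replace = TRUE)
        seqn <- paste0(aa_collapse(bg[seq_len(pos - 1L)]), sig,
                       aa_collapse(bg[seq(pos, length.out = n_bg - pos + 1L)]))
        call <- classify_subfamily(protein_record(id, seqn))
        clean <- all(vapply(SIGNATURES, function(pat) {
          m <- gregexpr(pat, seqn, perl = TRUE)[[1L]]
          all(m == -1L | m == pos)
        }, logical(1L)))
        if (as.character(call$subfamily) == fam && call$match_start == pos &&
            clean) {
          records[[id]] <- protein_record(id, seqn)
          truth <- rbind(truth, data.frame(id = id, subfamily = fam,
                                           match_start = pos,
                                           stringsAsFactors = FALSE))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("signature planting failed for ", id, " after ",
                    max_retries, " attempts")
    }
  }
  list(records = records,
       truth = truth %||% data.frame(id = character(),
                                     subfamily = character(),
                                     match_start = integer()),
       seed = config$seed)
}

random_sense_codon <- function() {
  repeat {
    codon <- paste(sample(NUCS, 3L, replace = TRUE), collapse = "")
    if (!is_stop_codon(codon)) return(codon)
  }
}

# Candidate single-nucleotide changes of a codon, split by class.
codon_single_changes <- function(codon) {
  syn <- character(); nonsyn <- character()
  aa <- translate_codon(codon)
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (is_stop_codon(alt)) next
      if (identical(translate_codon(alt), aa)) syn <- c(syn, alt)
      else nonsyn <- c(nonsyn, alt)
    }
  }
  list(syn = syn, nonsyn = nonsyn)
}

#' Generate codon-aligned pairs with planted substitution counts
#'
#' Each pair copies a random stop-free codon sequence and applies
#' exactly the requested numbers of synonymous and nonsynonymous
#' single-nucleotide changes, verified against the standard genetic
#' code, at distinct codons (so no codon is hit twice and the planted
#' counts are recoverable exactly). Codons admitting no change of the
#' required class (e.g. ATG or TGG for synonymous) are re-drawn.
#'
#' @param config A [sim_config()]; pairs follow `config$codon_pair_spec`.
#' @param max_retries Bound on codon re-draws per planted change.
#' @return List: `alignments` (list of [codon_alignment()]s), `truth`
#'   (data frame: pair_id, n_codons, syn, nonsyn), `seed`.
#' @export
gen_codon_pairs <- function(config, max_retries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2L))
  alignments <- list(); truth <- NULL
  for (p in seq_along(config$codon_pair_spec)) {
    spec <- config$codon_pair_spec[[p]]
    n_codons <- spec[1L]; n_syn <- spec[2L]; n_nonsyn <- spec[3L]
    codons_a <- vapply(seq_len(n_codons), function(i) random_sense_codon(),
                       character(1L))
    codons_b <- codons_a
    targets <- sample.int(n_codons, n_syn + n_nonsyn)
    classes <- rep(c("syn", "nonsyn"), c(n_syn, n_nonsyn))
    for (j in seq_along(targets)) {
      idx <- targets[j]
      done <- FALSE
      for (try in seq_len(max_retries)) {
        cands <- codon_single_changes(codons_a[idx])[[classes[j]]]
        if (length(cands)) {
          codons_b[idx] <- sample(cands, 1L)
          done <- TRUE
          break
        }
        # codon admits no change of this class: re-draw it in both seqs
        codons_a[idx] <- random_sense_codon()
        codons_b[idx] <- codons_a[idx]
      }
      if (!done) stop("could not plant a ", classes[j], " change (pair ", p,
                      ", codon ", idx, ") within ", max_retries, " retries")
    }
    id <- sprintf("syn_pair_%02d", p)
    alignments[[id]] <- codon_alignment(paste(codons_a, collapse = ""),
                                        paste(codons_b, collapse = ""),
                                        id = id)
    truth <- rbind(truth, data.frame(pair_id = id, n_codons = n_codons,
                                     syn = n_syn, nonsyn = n_nonsyn,
                                     stringsAsFactors = FALSE))
  }
  list(alignments = alignments, truth = truth, seed = config$seed)
}

#' Generate a synthetic FPKM expression matrix
#'
#' Log-normal draws per gene: a gene-level baseline (meanlog ~ N(3, 1))
#' with tissue-level lognormal variation (sdlog 1), giving nonnegative
#' right-skewed values typical of RNA-seq FPKM tables.
#'
#' @param config A [sim_config()] (uses `n_tissues`, `seed`).
#' @param n_genes Number of gene rows.
#' @return Numeric matrix, genes x tissues, with a `seed` attribute;
#'   the default eight tissues carry the standard panel names.
#' @export
gen_fpkm <- function(config, n_genes) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 2L) stop("n_tissues must be >= 2")
  set.seed(sub_seed(config$seed, 3L))
  meanlog <- rnorm(n_genes, mean = 3, sd = 1)
  mat <- t(vapply(seq_len(n_genes),
                  function(i) rlnorm(config$n_tissues, meanlog[i], 1),
                  numeric(config$n_tissues)))
  rownames(mat) <- sprintf("gene_%03d", seq_len(n_genes))
  colnames(mat) <- if (config$n_tissues == 8L) DEFAULT_TISSUES else
    sprintf("tissue_%d", seq_len(config$n_tissues))
  attr(mat, "seed") <- config$seed
  mat
}

#' Generate replicate qRT-PCR time courses with planted effects
#'
#' Emulates the paired treated/mock design: the reference gene Ct is
#' constant up to noise, the target Ct in the treated arm is shifted by
#' -log2(planted fold) at the designated peak time point and by half
#' that (in log2 space) at the two adjacent time points, with Gaussian
#' noise of sd `qpcr_noise_sd` per replicate. Mock controls are
#' simulated at every time point.
#'
#' @param design Data frame with columns `gene`, `treatment`, `fold`
#'   (planted peak E/C fold change, > 0) and optional `peak_time_h`
#'   (default 12 h; must be one of `config$timepoints`).
#' @param config A [sim_config()].
#' @return Long-format Ct table (gene, treatment, time_h, arm,
#'   replicate, ct_target, ct_reference) with a `seed` attribute,
#'   directly consumable by [call_inductions()].
#' @export
gen_qpcr <- function(design, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(design$fold <= 0)) stop("planted fold changes must be positive")
  if (is.null(design$peak_time_h)) design$peak_time_h <- 12
  if (!all(design$peak_time_h %in% config$timepoints))
    stop("peak_time_h values must be sampling time points")
  set.seed(sub_seed(config$seed, 4L))
  tps <- config$timepoints
  reps <- config$qpcr_replicates
  base_target <- 20; base_ref <- 15
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    peak_idx <- match(design$peak_time_h[i], tps)
    effect <- numeric(length(tps))
    effect[peak_idx] <- log2(design$fold[i])
    for (nb in c(peak_idx - 1L, peak_idx + 1L))
      if (nb >= 1L && nb <= length(tps)) effect[nb] <- log2(design$fold[i]) / 2
    n_cells <- length(tps) * 2L * reps
    grid <- expand.grid(replicate = seq_len(reps), arm = c("treated", "mock"),
                        time_h = tps, stringsAsFactors = FALSE)
    shift <- ifelse(grid$arm == "treated", effect[match(grid$time_h, tps)], 0)
    out[[i]] <- data.frame(
      gene = design$gene[i], treatment = design$treatment[i],
      time_h = grid$time_h, arm = grid$arm, replicate = grid$replicate,
      ct_target = base_target - shift + rnorm(n_cells, 0, config$qpcr_noise_sd),
      ct_reference = base_ref + rnorm(n_cells, 0, config$qpcr_noise_sd),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- config$seed
  res
}
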