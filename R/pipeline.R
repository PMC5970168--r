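# End-to-end pipeline: validated configuration, staged execution with
# atomic outputs, and a run report.

#' Pipeline configuration
#'
#' Paths are per-stage inputs; a `NULL` path skips that stage. With
#' `use_fixtures = TRUE` the cascade-assembly stage runs on the packaged
#' cotton edge lists, exclusions and response profiles.
#'
#' @param out_dir Output directory (created if needed).
#' @param proteins_fasta,codon_pairs_fasta,fpkm_tsv,qpcr_tsv,edges_tsv
#'   Optional input paths for the classification, Ka/Ks, z-score,
#'   induction-calling and cascade stages.
#' @param profiles_tsv Optional response-profile TSV (gene, treatment)
#'   for module annotation.
#' @param exclusions Character vector of genes excluded from cascade
#'   enumeration (default: the fixture exclusion set when
#'   `use_fixtures`, else empty).
#' @param use_fixtures Run the cascade stage on the packaged cotton
#'   fixtures (default FALSE).
#' @param fold_threshold,alpha1,alpha2 Induction-calling thresholds
#'   (defaults 2.0, 0.05, 0.01; `alpha2 <= alpha1` required).
#' @param seed Seed echoed into output provenance headers.
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            proteins_fasta = NULL, codon_pairs_fasta = NULL,
                            fpkm_tsv = NULL, qpcr_tsv = NULL,
                            edges_tsv = NULL, profiles_tsv = NULL,
                            exclusions = NULL, use_fixtures = FALSE,
                            fold_threshold = 2.0, alpha1 = 0.05,
                            alpha2 = 0.01, seed = 1L) {
  if (fold_threshold <= 0 || alpha1 <= 0 || alpha2 <= 0)
    stop("thresholds must be positive")
  if (alpha2 > alpha1) stop("alpha2 must be <= alpha1")
  cfg <- list(out_dir = out_dir, proteins_fasta = proteins_fasta,
              codon_pairs_fasta = codon_pairs_fasta, fpkm_tsv = fpkm_tsv,
              qpcr_tsv = qpcr_tsv, edges_tsv = edges_tsv,
              profiles_tsv = profiles_tsv, exclusions = exclusions,
              use_fixtures = isTRUE(use_fixtures),
              fold_threshold = fold_threshold, alpha1 = alpha1,
              alpha2 = alpha2, seed = as.integer(seed))
  for (field in c("proteins_fasta", "codon_pairs_fasta", "fpkm_tsv",
                  "qpcr_tsv", "edges_tsv", "profiles_tsv")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p))
      stop("configured input does not exist: ", field, " = ", p)
  }
  structure(cfg, class = "pipeline_config")
}

config_provenance <- function(config) {
  # out_dir is excluded so the same analysis written elsewhere carries
  # the same provenance hash
  echo <- config[!vapply(config, is.null, logical(1L))]
  echo$out_dir <- NULL
  hash <- substr(tools::md5sum(
    local({ f <- tempfile(); saveRDS(echo[order(names(echo))], f); f })),
    1L, 12L)
  sprintf("mapkCascades %s | config_hash=%s seed=%d",
          as.character(utils::packageVersion("mapkCascades")),
          unname(hash), config$seed)
}

#' Validate pipeline inputs
#'
#' Schema-checks every configured input file and reports each problem
#' with its file and location.
#'
#' @param config A [pipeline_config()].
#' @return Data frame of errors (`file`, `location`, `message`); zero
#'   rows when everything validates.
#' @export
validate_inputs <- function(config) {
  errors <- data.frame(file = character(), location = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(file, location, message)
    errors <<- rbind(errors, data.frame(file = file, location = location,
                                        message = message,
                                        stringsAsFactors = FALSE))
  check <- function(path, fn, what) {
    tryCatch(fn(path), error = function(e)
      add(path, what, conditionMessage(e)))
  }
  if (!is.null(config$proteins_fasta))
    check(config$proteins_fasta, read_proteins_fasta, "FASTA parse")
  if (!is.null(config$codon_pairs_fasta))
    check(config$codon_pairs_fasta, read_codon_pairs_fasta, "FASTA parse")
  if (!is.null(config$fpkm_tsv)) {
    mat <- tryCatch(read_fpkm_tsv(config$fpkm_tsv), error = function(e) {
      add(config$fpkm_tsv, "TSV parse", conditionMessage(e)); NULL })
    if (!is.null(mat)) {
      if (anyNA(mat)) {
        idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
        add(config$fpkm_tsv, sprintf("row %d, column %d", idx[1L], idx[2L]),
            "missing FPKM value")
      }
      neg <- which(mat < 0, arr.ind = TRUE)
      if (nrow(neg))
        add(config$fpkm_tsv,
            sprintf("gene %s, tissue %s", rownames(mat)[neg[1L, 1L]],
                    colnames(mat)[neg[1L, 2L]]),
            "negative FPKM value")
    }
  }
  if (!is.null(config$qpcr_tsv)) {
    ct <- tryCatch(read_ct_tsv(config$qpcr_tsv), error = function(e) {
      add(config$qpcr_tsv, "TSV parse", conditionMessage(e)); NULL })
    if (!is.null(ct)) {
      need <- c("gene", "treatment", "time_h", "arm", "replicate",
                "ct_target", "ct_reference")
      miss <- setdiff(need, names(ct))
      if (length(miss))
        add(config$qpcr_tsv, "header",
            paste("missing column(s):", paste(miss, collapse = ", ")))
      else if (!all(ct$arm %in% c("treated", "mock")))
        add(config$qpcr_tsv,
            sprintf("row %d", which(!ct$arm %in% c("treated", "mock"))[1L]),
            "arm must be 'treated' or 'mock'")
    }
  }
  if (!is.null(config$edges_tsv)) {
    raw <- tryCatch(read.delim(config$edges_tsv, stringsAsFactors = FALSE,
                               comment.char = "#"), error = function(e) {
      add(config$edges_tsv, "TSV parse", conditionMessage(e)); NULL })
    if (!is.null(raw))
      tryCatch(interaction_edges(raw), error = function(e)
        add(config$edges_tsv, "edge validation", conditionMessage(e)))
  }
  errors
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — subfamily classification
#' and protein stats, Ka/Ks estimation, expression z-scoring, qRT-PCR
#' induction calling, cascade assembly — writing one TSV per stage
#' (atomically, with a provenance header) plus `report.json`. Stages
#' without inputs are recorded as skipped. Identical config and inputs
#' reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Run report list: `stages` (per-stage record counts), `config`
#'   echo, `version`, `warnings`, `fixture_checksums` (when fixtures are
#'   used), `outputs`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errs <- validate_inputs(config)
  if (nrow(errs))
    stop("input validation failed: ", errs$file[1L], " (", errs$location[1L],
         "): ", errs$message[1L])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- config_provenance(config)
  report <- list(stages = list(), warnings = character(),
                 config = config[!vapply(config, is.null, logical(1L))],
                 version = as.character(utils::packageVersion("mapkCascades")),
                 outputs = character())
  note_warning <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, n_in, fn) {
    res <- tryCatch(withCallingHandlers(fn(), warning = note_warning),
                    error = function(e)
                      stop("stage '", name, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- list(skipped = FALSE, n_in = n_in,
                                   n_out = res)
  }
  skip_stage <- function(name)
    report$stages[[name]] <<- list(skipped = TRUE, n_in = 0L, n_out = 0L)
  out_file <- function(name) file.path(config$out_dir, name)

  # classify + protein stats
  if (!is.null(config$proteins_fasta)) {
    records <- read_proteins_fasta(config$proteins_fasta)
    run_stage("classify", length(records), function() {
      calls <- classify_subfamilies(records)
      stats <- do.call(rbind, lapply(records, protein_stats))
      tab <- merge(calls, stats[c("id", "mw_da", "pi")], by = "id")
      write_tsv_atomic(tab, out_file("subfamily_calls.tsv"), prov)
      report$outputs <<- c(report$outputs, out_file("subfamily_calls.tsv"))
      nrow(tab)
    })
  } else skip_stage("classify")

  # Ka/Ks
  if (!is.null(config$codon_pairs_fasta)) {
    alns <- read_codon_pairs_fasta(config$codon_pairs_fasta)
    run_stage("kaks", length(alns), function() {
      tab <- compute_kaks_table(alns)
      write_tsv_atomic(tab, out_file("kaks.tsv"), prov)
      report$outputs <<- c(report$outputs, out_file("kaks.tsv"))
      nrow(tab)
    })
  } else skip_stage("kaks")

  # z-score
  if (!is.null(config$fpkm_tsv)) {
    mat <- read_fpkm_tsv(config$fpkm_tsv)
    run_stage("zscore", nrow(mat), function() {
      z <- suppressMessages(zscore_normalize(mat))
      const <- attr(z, "constant_genes")
      if (length(const))
        report$warnings <<- c(report$warnings,
                              paste("constant expression rows:",
                                    paste(const, collapse = ", ")))
      tab <- data.frame(gene = rownames(z), as.data.frame(z),
                        check.names = FALSE)
      write_tsv_atomic(tab, out_file("zscores.tsv"), prov)
      report$outputs <<- c(report$outputs, out_file("zscores.tsv"))
      nrow(tab)
    })
  } else skip_stage("zscore")

  # induction calling
  calls <- NULL
  if (!is.null(config$qpcr_tsv)) {
    ct <- read_ct_tsv(config$qpcr_tsv)
    run_stage("induction", nrow(ct), function() {
      calls <<- call_inductions(ct, alpha1 = config$alpha1,
                                alpha2 = config$alpha2,
                                fold_threshold = config$fold_threshold)
      im <- induction_matrix(calls)
      status <- data.frame(gene = rownames(im$status),
                           as.data.frame(im$status), check.names = FALSE)
      write_tsv_atomic(calls, out_file("induction_calls.tsv"), prov)
      write_tsv_atomic(status, out_file("induction_status.tsv"), prov)
      jsonlite::write_json(
        list(up_per_treatment = as.list(im$up_per_treatment),
             up_per_gene = as.list(im$up_per_gene)),
        out_file("induction_summary.json"), auto_unbox = TRUE)
      report$outputs <<- c(report$outputs,
                           out_file(c("induction_calls.tsv",
                                      "induction_status.tsv",
                                      "induction_summary.json")))
      nrow(calls)
    })
  } else skip_stage("induction")

  # cascade assembly
  if (!is.null(config$edges_tsv) || config$use_fixtures) {
    if (config$use_fixtures) {
      fx <- load_cotton_fixtures()
      edges <- fx$edges
      exclusions <- config$exclusions %||% fx$exclusions$gene
      profiles <- cotton_response_profiles(fx)
      report$fixture_checksums <- as.list(
        jsonlite::read_json(fixture_path("MANIFEST.json"),
                            simplifyVector = TRUE))
    } else {
      edges <- read_edges_tsv(config$edges_tsv)
      exclusions <- config$exclusions %||% character()
      profiles <- if (!is.null(config$profiles_tsv))
        read.delim(config$profiles_tsv, stringsAsFactors = FALSE,
                   comment.char = "#") else NULL
      if (is.null(profiles) && !is.null(calls))
        profiles <- data.frame(gene = calls$gene[calls$status == "up"],
                               treatment = calls$treatment[calls$status == "up"],
                               provenance = "computed",
                               stringsAsFactors = FALSE)
    }
    run_stage("assemble", nrow(edges), function() {
      graph <- build_graph(edges)
      modules <- enumerate_modules(graph, exclusions)
      if (!is.null(profiles) && nrow(profiles))
        modules <- annotate_shared_responses(modules, profiles)
      write_tsv_atomic(modules, out_file("cascade_modules.tsv"), prov)
      write_graph_dot(graph, out_file("cascade_graph.dot"))
      report$outputs <<- c(report$outputs,
                           out_file(c("cascade_modules.tsv",
                                      "cascade_graph.dot")))
      nrow(modules)
    })
  } else skip_stage("assemble")

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  report
}
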