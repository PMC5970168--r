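# Synthetic-data generators: determinism, planted-truth recovery, and
# the packaged cotton fixtures.

test_that("config invariants are enforced", {
  expect_error(sim_config(seed = 1, qpcr_replicates = 1), "replicates")
  expect_error(sim_config(seed = 1, timepoints = c(0, 2, 1)), "increasing")
  expect_error(sim_config(seed = 1, protein_length = 5), "signature")
  expect_error(sim_config(seed = 1, codon_pair_spec = list(c(3, 2, 2))),
               "n_syn")
})

test_that("identical config and seed reproduce identical outputs", {
  cfg <- function() sim_config(seed = 71, n_per_subfamily = 2,
                               codon_pair_spec = list(c(30, 2, 1)))
  p1 <- gen_proteins(cfg()); p2 <- gen_proteins(cfg())
  expect_identical(p1, p2)
  c1 <- gen_codon_pairs(cfg()); c2 <- gen_codon_pairs(cfg())
  expect_identical(c1, c2)
  f1 <- gen_fpkm(cfg(), 5); f2 <- gen_fpkm(cfg(), 5)
  expect_identical(f1, f2)
  design <- data.frame(gene = "g", treatment = "JA", fold = 4,
                       peak_time_h = 12)
  expect_identical(gen_qpcr(design, cfg()), gen_qpcr(design, cfg()))
  expect_false(identical(gen_fpkm(sim_config(seed = 72), 5), f1))
})

test_that("generated proteins carry one planted signature each and the
          classifier recovers every planted label", {
  for (seed in c(1, 7, 99)) {
    pp <- gen_proteins(sim_config(seed = seed, n_per_subfamily = 4))
    expect_length(pp$records, 12L)
    expect_equal(unname(table(pp$truth$subfamily)[c("MEKK", "Raf", "ZIK")]),
                 rep(4L, 3), ignore_attr = TRUE)
    calls <- classify_subfamilies(pp$records)
    expect_equal(as.character(calls$subfamily), pp$truth$subfamily)
    expect_equal(calls$match_start, pp$truth$match_start)
    expect_equal(pp$seed, seed)
  }
  empty <- gen_proteins(sim_config(seed = 1, n_per_subfamily = 0))
  expect_length(empty$records, 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("codon-pair generator plants verified changes at distinct codons", {
  cfg <- sim_config(seed = 73,
                    codon_pair_spec = list(c(100, 0, 0), c(100, 3, 0)))
  cp <- gen_codon_pairs(cfg)
  al0 <- cp$alignments[[1]]
  expect_identical(al0$codons_a, al0$codons_b)
  al3 <- cp$alignments[[2]]
  changed <- which(al3$codons_a != al3$codons_b)
  expect_length(changed, 3L)
  # each planted change is a single-nucleotide synonymous substitution
  for (i in changed) {
    expect_equal(sum(strsplit(al3$codons_a[i], "")[[1]] !=
                       strsplit(al3$codons_b[i], "")[[1]]), 1L)
    expect_equal(GC1[[al3$codons_a[i]]], GC1[[al3$codons_b[i]]])
  }
  expect_equal(compute_kaks(al3)$Ka, 0)
})

test_that("FPKM tables are nonnegative with the configured shape", {
  cfg <- sim_config(seed = 74)
  mat <- gen_fpkm(cfg, n_genes = 10)
  expect_equal(dim(mat), c(10L, 8L))
  expect_true(all(mat >= 0))
  expect_equal(colnames(mat)[1], "root")
  expect_equal(attr(mat, "seed"), 74L)
  expect_error(gen_fpkm(sim_config(seed = 1, n_tissues = 1), 3), ">= 2")
})

test_that("qPCR generator: no planted effect means no induction calls", {
  cfg <- sim_config(seed = 75, qpcr_noise_sd = 0.05)
  design <- data.frame(gene = paste0("g", 1:4), treatment = "H2O2",
                       fold = 1, peak_time_h = 12)
  calls <- call_inductions(gen_qpcr(design, cfg))
  expect_true(all(calls$status == "none"))
  expect_error(gen_qpcr(data.frame(gene = "g", treatment = "JA",
                                   fold = -1), cfg), "positive")
})

test_that("qPCR generator shape: both arms at every time point, mock flat", {
  cfg <- sim_config(seed = 76)
  ct <- gen_qpcr(data.frame(gene = "g", treatment = "JA", fold = 4,
                            peak_time_h = 12), cfg)
  tab <- table(ct$time_h, ct$arm)
  expect_true(all(tab == cfg$qpcr_replicates))
  expect_equal(nrow(ct), length(cfg$timepoints) * 2 * cfg$qpcr_replicates)
  mock <- ct[ct$arm == "mock", ]
  expect_lt(diff(range(mock$ct_target)), 1)  # constant up to noise
  expect_equal(attr(ct, "seed"), 76L)
})

test_that("fixtures load with verified checksums and published counts", {
  fx <- load_cotton_fixtures()
  expect_equal(nrow(fx$kkk_kk), 18L)
  expect_equal(nrow(fx$kk_k), 16L)
  expect_equal(nrow(fx$exclusions), 3L)
  expect_setequal(fx$exclusions$gene, c("MKK10_1", "MEKK19", "RAF17_2"))
  counts <- lengths(fx$induced_lists)
  expect_equal(unname(counts[c("JA", "H2O2", "NaCl", "PEG", "cold_4C",
                               "heat_37C", "wounding")]),
               c(10L, 7L, 11L, 4L, 5L, 6L, 9L))
  # ABA flagged ambiguous, SA reconstructed
  expect_true(all(fx$induced$flag[fx$induced$treatment == "ABA"] ==
                    "ambiguous"))
  expect_true(all(fx$induced$flag[fx$induced$treatment == "SA"] ==
                    "reconstructed"))
  expect_true(all(fx$induced$treatment %in% treatment_families()$all))
})

test_that("fixture corruption is detected by checksum", {
  tmp_lib <- tempfile("extdata")
  dir.create(tmp_lib)
  src <- system.file("extdata", package = "mapkCascades")
  file.copy(list.files(src, full.names = TRUE), tmp_lib)
  # simulate corruption by editing a data file, keeping the manifest
  edges_file <- file.path(tmp_lib, "cotton_y2h_edges.tsv")
  writeLines(sub("MEKK4_2", "MEKK4_9", readLines(edges_file)), edges_file)
  expect_error(load_cotton_fixtures(dir = tmp_lib), "checksum mismatch")
  expect_silent(invisible(load_cotton_fixtures(verify = FALSE,
                                               dir = tmp_lib)))
})
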