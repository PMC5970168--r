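# Z-scoring, Livak relative expression, and induction calling.

test_that("z-score rows have mean 0 and sample sd 1; constants map to 0", {
  expect_equal(unname(zscore_normalize(rbind(c(1, 2, 3)))[1, ]),
               c(-1, 0, 1))
  z <- suppressMessages(zscore_normalize(
    rbind(g1 = c(5, 5, 5, 5, 5, 5, 5, 5), g2 = 1:8)))
  expect_equal(unname(z["g1", ]), rep(0, 8))
  expect_equal(attr(z, "constant_genes"), "g1")
  cfg <- sim_config(seed = 51)
  mat <- gen_fpkm(cfg, n_genes = 10)
  zz <- zscore_normalize(mat)
  expect_true(all(abs(rowMeans(zz)) < 1e-12))
  expect_true(all(abs(apply(zz, 1, sd) - 1) < 1e-12))
  # affine rescaling of a row leaves its z-scores unchanged (positive scale)
  expect_equal(unname(zscore_normalize(mat * 3 + 0)[1, ]),
               unname(zz[1, ]), tolerance = 1e-9)
})

test_that("z-scoring rejects degenerate inputs", {
  expect_error(zscore_normalize(matrix(1:3, ncol = 1)), "at least 2")
  expect_error(zscore_normalize(rbind(c(1, NA))), "missing")
  expect_error(zscore_normalize(rbind(c(-1, 2))), "negative")
})

test_that("Livak 2^-ddCt closed-form identities hold", {
  same <- list(ct_target = c(20, 20.1), ct_reference = c(15, 15.1))
  expect_equal(relative_expression(same, same), 1.0)
  expect_equal(relative_expression(
    list(ct_target = 20, ct_reference = 15),
    list(ct_target = 22, ct_reference = 15)), 4.0)
  # adding a constant to every Ct leaves the fold unchanged
  tr <- list(ct_target = c(19.8, 20.2), ct_reference = c(15.1, 14.9))
  mo <- list(ct_target = c(21.5, 21.7), ct_reference = c(15.0, 15.2))
  shift <- function(cell, c) lapply(cell, `+`, c)
  expect_equal(relative_expression(shift(tr, 3), shift(mo, 3)),
               relative_expression(tr, mo), tolerance = 1e-12)
  # log2 of the estimate is linear in -ddCt
  expect_equal(log2(relative_expression(tr, mo)),
               -((mean(tr$ct_target - tr$ct_reference)) -
                   mean(mo$ct_target - mo$ct_reference)), tolerance = 1e-12)
  expect_error(relative_expression(list(ct_target = 20), mo), "reference")
})

test_that("planted fold changes are recovered as up/none/down calls", {
  cfg <- sim_config(seed = 52, qpcr_noise_sd = 0.05)
  design <- data.frame(
    gene = c("up4", "flat", "down5"), treatment = "JA",
    fold = c(4, 1, 0.2), peak_time_h = c(12, 12, 8))
  calls <- call_inductions(gen_qpcr(design, cfg))
  calls <- calls[match(design$gene, calls$gene), ]
  expect_equal(calls$status, c("up", "none", "down"))
  expect_equal(calls$peak_time_h, c(12, NA, 8))
  expect_equal(calls$significance[1], "p<0.01")
  expect_gte(calls$max_fold_change[1], 2)
  expect_lte(calls$max_fold_change[3], 0.5)
  expect_equal(calls$significance[2], "ns")
})

test_that("identical treated and mock arms yield status none", {
  tps <- c(0, 4, 12)
  grid <- expand.grid(replicate = 1:3, arm = c("treated", "mock"),
                      time_h = tps, stringsAsFactors = FALSE)
  course <- data.frame(gene = "g", treatment = "SA", grid,
                       ct_target = 20, ct_reference = 15)
  call <- call_induction(course)
  expect_equal(call$status, "none")
  expect_equal(call$significance, "ns")
})

test_that("increasing a planted up-fold never demotes an up call", {
  # same residual noise (same sub-seeded draws) across increasing folds
  statuses <- vapply(c(2.5, 4, 8, 32), function(f) {
    cfg <- sim_config(seed = 53, qpcr_noise_sd = 0.1)
    design <- data.frame(gene = "g", treatment = "NaCl", fold = f,
                         peak_time_h = 12)
    call_inductions(gen_qpcr(design, cfg))$status
  }, character(1L))
  expect_true(all(statuses == "up"))
})

test_that("replicate and schema requirements are enforced", {
  cfg <- sim_config(seed = 54)
  ct <- gen_qpcr(data.frame(gene = "g", treatment = "JA", fold = 2,
                            peak_time_h = 12), cfg)
  expect_error(call_induction(ct[ct$replicate == 1, ]), "2 replicates")
  expect_error(call_induction(ct[, -match("arm", names(ct))]), "arm")
})

test_that("induction matrix aggregates calls with the legend codes", {
  expect_equal(induction_matrix(
    data.frame(gene = character(), treatment = character(),
               status = character(), significance = character()))$up_per_treatment,
    integer())
  calls <- data.frame(
    gene = c("A", "A", "B", "B"),
    treatment = c("JA", "NaCl", "JA", "NaCl"),
    status = c("up", "down", "up", "none"),
    significance = c("p<0.01", "p<0.05", "p<0.05", "ns"),
    stringsAsFactors = FALSE)
  im <- induction_matrix(calls)
  expect_equal(im$status["A", "JA"], "**")
  expect_equal(im$status["B", "JA"], "*")
  expect_equal(im$status["A", "NaCl"], "D")
  expect_equal(im$status["B", "NaCl"], "-")
  expect_equal(unname(im$up_per_treatment), c(2L, 0L))
  expect_equal(unname(im$up_per_gene), c(1L, 1L))
  expect_error(induction_matrix(rbind(calls, calls[1, ])), "duplicate")
})

test_that("planting the published JA list recovers its up-count and
          MEKK17 is up under all five abiotic stresses", {
  fx <- load_cotton_fixtures()
  genes <- investigated_genes()
  cfg <- sim_config(seed = 55, qpcr_noise_sd = 0.1)
  all_calls <- do.call(rbind, lapply(c("JA", ABIOTIC <- treatment_families()$abiotic),
    function(tr) {
      design <- planted_design(tr, fx$induced_lists[[tr]], genes)
      call_inductions(gen_qpcr(design, cfg))
    }))
  im <- induction_matrix(all_calls)
  expect_equal(unname(im$up_per_treatment["JA"]), 10L)
  expect_true(all(im$status["MEKK17", ABIOTIC] %in% c("*", "**")))
})
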