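# Tripartite graph construction, module enumeration, shared-response
# annotation, and interaction summaries.

test_that("fixture graph has the published layer sizes", {
  fx <- load_cotton_fixtures()
  g <- build_graph(fx$edges)
  expect_equal(unname(g$summary$n_nodes), c(14L, 6L, 11L))
  expect_equal(unname(g$summary$n_edges), c(18L, 16L))
  # every MKK node has at least one MAPKKK partner
  expect_true(all(g$layers$KK %in% fx$kkk_kk$downstream))
})

test_that("empty edge set builds an empty graph", {
  g <- build_graph(data.frame(upstream = character(),
                              downstream = character(),
                              tier = character()))
  expect_equal(unname(g$summary$n_nodes), c(0L, 0L, 0L))
  expect_equal(nrow(enumerate_modules(g)), 0L)
})

test_that("edge validation enforces tier/prefix agreement and uniqueness", {
  expect_error(interaction_edges(data.frame(
    upstream = "MPK6", downstream = "MKK1", tier = "KKK-KK")),
    "tier/prefix mismatch")
  expect_error(interaction_edges(data.frame(
    upstream = "MEKK1", downstream = "MPK3", tier = "KKK-KK")),
    "tier/prefix mismatch")
  expect_error(interaction_edges(data.frame(
    upstream = c("MEKK1", "MEKK1"), downstream = c("MKK1", "MKK1"),
    tier = "KKK-KK")), "duplicate")
  expect_error(interaction_edges(data.frame(
    upstream = "MEKK1", downstream = "MKK1", tier = "bogus")), "tier")
})

test_that("display alias MKK2 joins onto canonical MKK2_2", {
  edges <- data.frame(
    upstream = c("MEKK3_2", "MKK2"), downstream = c("MKK2", "MPK3"),
    tier = c("KKK-KK", "KK-K"))
  mods <- enumerate_modules(build_graph(edges))
  expect_equal(mods, data.frame(kkk = "MEKK3_2", kk = "MKK2_2", k = "MPK3"))
})

test_that("fixture enumeration yields 38 modules under the exclusions", {
  fx <- load_cotton_fixtures()
  mods <- enumerate_modules(build_graph(fx$edges), fx$exclusions$gene)
  expect_equal(nrow(mods), 38L)
  expect_false(any(unlist(mods[c("kkk", "kk", "k")]) %in%
                     fx$exclusions$gene))
  expect_false(anyDuplicated(mods) > 0)
  # deterministic ordering across runs
  expect_identical(mods, enumerate_modules(build_graph(fx$edges),
                                           fx$exclusions$gene))
})

test_that("toy 2x3 hub gives 6 modules; excluding all MKKs gives none", {
  edges <- data.frame(
    upstream = c("MEKK1", "MEKK2", "MKK9", "MKK9", "MKK9"),
    downstream = c("MKK9", "MKK9", "MPK1", "MPK2", "MPK3"),
    tier = c("KKK-KK", "KKK-KK", "KK-K", "KK-K", "KK-K"))
  expect_equal(nrow(enumerate_modules(build_graph(edges))), 6L)
  expect_equal(nrow(enumerate_modules(build_graph(edges), "MKK9")), 0L)
  fx <- load_cotton_fixtures()
  expect_equal(nrow(enumerate_modules(build_graph(fx$edges),
                                      unique(fx$kk_k$upstream))), 0L)
})

test_that("module count equals sum of in-degree x out-degree and matches
          brute force on random graphs; edge removal is monotone", {
  set.seed(61)
  for (rep in 1:15) {
    edges <- random_tripartite_edges()
    if (is.null(edges)) next
    exclusions <- if (runif(1) < 0.5) sample(unique(edges$upstream), 1) else
      character()
    mods <- enumerate_modules(build_graph(edges), exclusions)
    expect_equal(nrow(mods), brute_force_modules(edges, exclusions))
    kept <- edges[!(edges$upstream %in% exclusions |
                      edges$downstream %in% exclusions), ]
    up_deg <- table(kept$downstream[kept$tier == "KKK-KK"])
    dn_deg <- table(kept$upstream[kept$tier == "KK-K"])
    common <- intersect(names(up_deg), names(dn_deg))
    expect_equal(nrow(mods),
                 sum(as.integer(up_deg[common]) * as.integer(dn_deg[common])))
    if (nrow(edges) > 1) {
      fewer <- enumerate_modules(build_graph(edges[-1, ]), exclusions)
      expect_lte(nrow(fewer), nrow(mods))
    }
  }
})

test_that("shared-response annotation intersects member profiles", {
  mods <- data.frame(kkk = "MEKK20", kk = "MKK4", k = "MPK8")
  profiles <- data.frame(
    gene = rep(c("MEKK20", "MPK8"), each = 6),
    treatment = rep(c("JA", "ABA", "H2O2", "SA", "NaCl", "wounding"), 2))
  ann <- annotate_shared_responses(mods, profiles)  # MKK4 profile absent
  shared <- c(strsplit(ann$shared_signal, ",")[[1]],
              strsplit(ann$shared_abiotic, ",")[[1]])
  expect_length(shared, 6)
  expect_setequal(shared, c("JA", "ABA", "H2O2", "SA", "NaCl", "wounding"))
  expect_equal(ann$n_profiled, 2L)
  expect_false(ann$low_support)
  # disjoint profiles intersect to the empty set
  disj <- annotate_shared_responses(mods, data.frame(
    gene = c("MEKK20", "MPK8"), treatment = c("JA", "NaCl")))
  expect_equal(disj$shared_signal, "")
  expect_equal(disj$shared_abiotic, "")
  # single profiled member: shared set equals that profile, low support
  solo <- annotate_shared_responses(mods, data.frame(
    gene = "MPK8", treatment = c("JA", "PEG")))
  expect_equal(solo$shared_signal, "JA")
  expect_equal(solo$shared_abiotic, "PEG")
  expect_true(solo$low_support)
})

test_that("shared sets are subsets of every contributing profile", {
  fx <- load_cotton_fixtures()
  profiles <- cotton_response_profiles(fx)
  mods <- annotate_shared_responses(
    enumerate_modules(build_graph(fx$edges), fx$exclusions$gene), profiles)
  prof_sets <- split(profiles$treatment, profiles$gene)
  for (i in seq_len(nrow(mods))) {
    shared <- unlist(strsplit(c(mods$shared_signal[i],
                                mods$shared_abiotic[i]), ","))
    shared <- shared[nzchar(shared)]
    for (member in c(mods$kkk[i], mods$kk[i], mods$k[i])) {
      if (member %in% names(prof_sets))
        expect_true(all(shared %in% prof_sets[[member]]),
                    info = paste(member, "module", i))
    }
  }
})

test_that("interaction summary reproduces the published counts", {
  fx <- load_cotton_fixtures()
  s <- summarize_interactions(fx$edges)
  expect_equal(unname(s$n_pairs), c(18L, 16L))
  expect_equal(s$kkk_subfamily_pairs,
               c(MEKK = 9L, Raf = 7L, ZIK = 2L))
  expect_equal(unname(s$n_nodes), c(14L, 6L, 11L))
  single <- summarize_interactions(data.frame(
    upstream = "MEKK4_2", downstream = "MKK1", tier = "KKK-KK"))
  expect_equal(unname(single$n_pairs["KKK-KK"]), 1L)
  expect_equal(single$kkk_subfamily_pairs[["MEKK"]], 1L)
  expect_equal(s$mkk_partners$MKK1$upstream, c("MEKK10_1", "MEKK4_2"))
})
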