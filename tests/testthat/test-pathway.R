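test_that("formula masses reproduce independently computed monoisotopic values", {
  # frozen oracle values from an elemental-composition calculation
  expect_equal(formula_mass("C7H15NO3"), 161.105193, tolerance = 1e-6)   # carnitine
  expect_equal(formula_mass("C29H44O2"), 424.334131, tolerance = 1e-6)   # alpha-tocotrienol
  expect_equal(formula_mass("C11H12N2O2"), 204.089878, tolerance = 1e-6) # tryptophan
  expect_equal(formula_mass("C6H13O9P"), 260.029719, tolerance = 1e-6)   # fructose 6-P
  expect_error(formula_mass("C2Xx3"), "element")
})

test_that("the bundled toy reference is internally consistent", {
  ref <- load_toy_reference()
  expect_equal(ref$metabolites$neutral_mass,
               formula_mass(ref$metabolites$formula), tolerance = 1e-5)
  expect_true(all(ref$pathways$metabolite %in% ref$metabolites$metabolite))
  expect_true(all(c(ref$edges$from, ref$edges$to) %in% ref$metabolites$metabolite))
  expect_equal(length(unique(ref$pathways$pathway)), 4)
})

test_that("m/z annotation respects the ppm tolerance window", {
  ref <- load_toy_reference()
  carn <- ref$metabolites$neutral_mass[ref$metabolites$metabolite == "carnitine"]
  feats <- tibble::tibble(
    feature = c("exact", "off50ppm", "nowhere"),
    mz = c(carn + 1.007276, (carn + 1.007276) * (1 + 50e-6), 600.0)
  )
  hits <- annotate_mz(feats, ref, tol_ppm = 10)
  expect_equal(hits$feature, "exact")
  expect_equal(hits$metabolite, "carnitine")
  expect_equal(hits$ppm_error, 0, tolerance = 1e-6)
  # widening the tolerance can only add hits; shrinking never does
  hits50 <- annotate_mz(feats, ref, tol_ppm = 60)
  expect_true(all(paste(hits$feature, hits$metabolite) %in%
                    paste(hits50$feature, hits50$metabolite)))
  expect_gte(nrow(hits50), nrow(hits))
  expect_error(annotate_mz(feats, ref, tol_ppm = 0), "tol_ppm")
})

test_that("pathway scoring ranks covered pathways ahead of untouched ones", {
  ref <- load_toy_reference()
  carn_mets <- ref$pathways$metabolite[ref$pathways$pathway == "carnitine shuttle"]
  feats <- tibble::tibble(
    feature = paste0("f", seq_along(carn_mets)),
    mz = ref$metabolites$neutral_mass[match(carn_mets, ref$metabolites$metabolite)] +
      1.007276
  )
  noise <- tibble::tibble(feature = paste0("n", 1:30),
                          mz = seq(500, 950, length.out = 30))
  allf <- dplyr::bind_rows(feats, noise)
  hits <- annotate_mz(allf, ref)
  sc <- score_pathways(hits, feats$feature, allf$feature, ref,
                       n_perm = 199, seed = 2)
  p_carn <- sc$scores$p[sc$scores$pathway == "carnitine shuttle"]
  expect_true(all(p_carn <= sc$scores$p))
  expect_equal(sc$scores$overlap[sc$scores$pathway == "carnitine shuttle"],
               length(carn_mets))
  # evidence = count of distinct significant supporting features
  expect_equal(sc$evidence$evidence[sc$evidence$metabolite == "carnitine"], 1)

  # empty significant set: all overlaps 0, all p = 1 by convention
  sc0 <- suppressMessages(score_pathways(hits, character(), allf$feature, ref,
                                         n_perm = 99, seed = 3))
  expect_true(all(sc0$scores$overlap == 0))
  expect_true(all(sc0$scores$p == 1))
})

test_that("activity network applies the evidence cutoff and component modules", {
  ref <- load_toy_reference()
  carn <- ref$metabolites$neutral_mass[ref$metabolites$metabolite == "carnitine"]
  trp <- ref$metabolites$neutral_mass[ref$metabolites$metabolite == "tryptophan"]
  kyn <- ref$metabolites$neutral_mass[ref$metabolites$metabolite == "kynurenine"]
  # three distinct significant features annotate carnitine (evidence 3),
  # one annotates tryptophan (evidence 1 < cutoff)
  feats <- tibble::tibble(
    feature = c("c1", "c2", "c3", "t1", "k1"),
    mz = c(carn, carn * (1 + 3e-6), carn * (1 - 3e-6), trp, kyn) + 1.007276
  )
  hits <- annotate_mz(feats, ref)
  sc <- score_pathways(hits, feats$feature, c(feats$feature, paste0("x", 1:40)),
                       ref, n_perm = 99, seed = 4)
  # with a high p cutoff nothing enters via pathway significance
  net <- build_activity_network(hits, sc, ref, evidence_cutoff = 3,
                                p_cutoff = 1e-9)
  expect_equal(net$members$metabolite, "carnitine")
  expect_equal(net$n_modules, 1)

  # at cutoff 1, tryptophan and kynurenine join and share an edge -> one module
  net2 <- build_activity_network(hits, sc, ref, evidence_cutoff = 1,
                                 p_cutoff = 1e-9)
  mem <- net2$members
  expect_setequal(mem$metabolite, c("carnitine", "tryptophan", "kynurenine"))
  expect_equal(mem$module[mem$metabolite == "tryptophan"],
               mem$module[mem$metabolite == "kynurenine"])
  expect_false(mem$module[mem$metabolite == "carnitine"] ==
                 mem$module[mem$metabolite == "tryptophan"])
  # module membership partitions the included metabolites
  expect_equal(anyDuplicated(mem$metabolite), 0)

  # no metabolite at cutoff, no significant pathway -> empty network
  net0 <- build_activity_network(hits, sc, ref, evidence_cutoff = 99,
                                 p_cutoff = 1e-9)
  expect_equal(nrow(net0$members), 0)
  expect_equal(net0$n_modules, 0)
})

test_that("permutation p-values are valid when nothing is planted", {
  ref <- load_toy_reference()
  set.seed(9)
  rej <- vapply(1:60, function(i) {
    feats <- tibble::tibble(feature = paste0("f", 1:60),
                            mz = stats::runif(60, 100, 1000))
    hits <- annotate_mz(feats, ref)
    sig <- sample(feats$feature, 10)
    sc <- score_pathways(hits, sig, feats$feature, ref, n_perm = 99, seed = i)
    min(sc$scores$p) < 0.05
  }, logical(1))
  # family-wise over 4 pathways, so bound is loose but must not explode
  expect_lte(mean(rej), 0.2 + 0.1)
})

test_that("annotation merging deduplicates on feature-metabolite pairs", {
  a <- tibble::tibble(feature = "f1", mz = 1, metabolite = "m",
                      adduct = "[M+H]+", ppm_error = 0)
  b <- dplyr::bind_rows(a, tibble::tibble(feature = "f2", mz = 2,
                                          metabolite = "m", adduct = "[M+H]+",
                                          ppm_error = 1))
  m <- merge_annotations(a, b)
  expect_equal(nrow(m), 2)
  expect_setequal(m$feature, c("f1", "f2"))
})
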