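test_that("pedigree construction yields the requested consanguinity", {
  ped <- make_pedigree("first_cousin", 2, seed = 1)
  expect_s3_class(ped, "pedigree")
  expect_equal(sum(ped$affected), 2)
  # affected sibs' parents are first cousins: share one grandparental couple
  expect_equal(kinship_coefficient(ped, "FA", "MO"), 1 / 16)
  expect_true(has_consanguineous_loop(ped))

  ped2 <- make_pedigree("unrelated", 1, seed = 1)
  expect_false(has_consanguineous_loop(ped2))
  expect_equal(kinship_coefficient(ped2, "FA", "MO"), 0)

  expect_error(make_pedigree("third_cousin", 2), "consanguinity")
})

test_that("kinship recursion agrees with a path-counting oracle", {
  for (type in c("first_cousin", "double_first_cousin")) {
    ped <- make_pedigree(type, 3, seed = 7)
    expect_equal(kinship_coefficient(ped, "FA", "MO"),
                 path_kinship(ped, "FA", "MO"), info = type)
    expect_equal(kinship_coefficient(ped, "AFF1", "AFF2"),
                 path_kinship(ped, "AFF1", "AFF2"), info = type)
  }
  ped <- make_pedigree("first_cousin", 3, seed = 7)
  expect_equal(kinship_coefficient(ped, "FA", "MO"), 1 / 16)
  expect_equal(kinship_coefficient(
    make_pedigree("double_first_cousin", 1, seed = 2), "FA", "MO"), 1 / 8)
})

test_that("gene dropping respects Mendelian transmission", {
  ped <- make_pedigree("first_cousin", 2, seed = 3)
  founders <- pedigree_founders(ped)
  set.seed(42)
  fg <- matrix(sample(0:2, length(founders) * 200, TRUE),
               nrow = length(founders),
               dimnames = list(founders, sprintf("v%03d", 1:200)))
  g <- gene_drop(ped, fg)
  for (id in setdiff(ped$id, founders)) {
    r <- ped[ped$id == id, ]
    # a child allele must be transmissible: child count <= sum of parental
    # carriages and child cannot carry more alt than each parent can give
    gf <- g[r$father, ]; gm <- g[r$mother, ]
    expect_true(all(g[id, ] <= pmin(gf, 1) + pmin(gm, 1)))
    expect_true(all(g[id, ] >= pmax(gf - 1, 0) + pmax(gm - 1, 0)))
  }
})

test_that("unconditioned transmission to a grandchild matches closed form", {
  # GGP1 het at 10000 independent sites; P(grandchild FA carries) = 1/4
  ped <- make_pedigree("first_cousin", 2, seed = 5)
  founders <- pedigree_founders(ped)
  fg <- matrix(0L, length(founders), 10000,
               dimnames = list(founders, sprintf("s%05d", 1:10000)))
  fg["GGP1", ] <- 1L
  set.seed(99)
  g <- gene_drop(ped, fg)
  p_hat <- mean(g["FA", ] >= 1)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(p_hat - 0.25), 3 * se)
})

test_that("causal conditioning produces the recessive genotype pattern", {
  cfg <- synthetic_cohort_config(n_background_variants = 0, seed = 2)
  ped <- make_pedigree("first_cousin", 2, seed = 2)
  g <- drop_genotypes(ped, "chr1:100A>G", cfg, seed = 2)
  aff <- ped$id[ped$affected]
  expect_true(all(g[aff, 1] == 2L))
  expect_equal(unname(g["FA", 1]), 1L)  # obligate carriers
  expect_equal(unname(g["MO", 1]), 1L)
  expect_true(all(g[ped$id[!ped$affected], 1] < 2L))

  # single founder copy cannot become homozygous without a loop
  ped_u <- make_pedigree("unrelated", 2, seed = 2)
  expect_error(drop_genotypes(ped_u, "chr1:100A>G", cfg, seed = 2),
               "conditioning impossible")
})

test_that("compound-het conditioning plants the pair in trans", {
  cfg <- synthetic_cohort_config(n_background_variants = 0,
                                 causal_model = "compound_het", seed = 4)
  ped <- make_pedigree("unrelated", 2, seed = 4)
  g <- drop_genotypes(ped, c("chr1:1A>G", "chr1:2C>T"), cfg, seed = 4)
  aff <- ped$id[ped$affected]
  expect_true(all(g[aff, 1] == 1L & g[aff, 2] == 1L))
  expect_true(g["FA", 1] >= 1 && g["FA", 2] == 0)
  expect_true(g["MO", 2] >= 1 && g["MO", 1] == 0)
})

test_that("background variants at founder frequency zero stay hom-ref", {
  cfg <- synthetic_cohort_config(n_background_variants = 0,
                                 geno_missing_rate = 0, seed = 6)
  ped <- make_pedigree("first_cousin", 2, seed = 6)
  g <- drop_genotypes(ped, "chr1:5G>A", cfg,
                      background_af = c(b1 = 0, b2 = 0), seed = 6)
  expect_true(all(g[, c("b1", "b2")] == 0L))
})

test_that("causal annotations pass every evidence gate by construction", {
  for (cls in c("missense", "nonsense", "frameshift", "splice",
                "synonymous_splice")) {
    cfg <- synthetic_cohort_config(causal_class = cls,
                                   n_background_variants = 50, seed = 8)
    v <- make_family_variants_for_test(cfg, "F1", 8)
    ann <- simulate_annotations(v, cfg, seed = 9)
    ca <- ann[ann$is_causal, ]
    expect_equal(ca$quality, 99)
    expect_equal(ca$exac_af, 0)
    expect_false(ca$in_dbsnp)
    expect_equal(ca$n_damaging, 4L)
    if (cls == "missense") expect_gt(ca$cadd, 20)
    if (cls == "synonymous_splice") expect_true(ca$splice_predicted)
  }
})

test_that("background frequency-tier pass rate matches configured tail mass", {
  cfg <- synthetic_cohort_config(n_background_variants = 2000,
                                 bg_rare_prob = 0.3, seed = 10)
  v <- make_family_variants_for_test(cfg, "F1", 10)
  ann <- simulate_annotations(v, cfg, seed = 11)
  bg <- ann[!ann$is_causal, ]
  # passes the frequency tier iff absent from dbSNP or AF < 0.01; by
  # generator design that event has probability exactly bg_rare_prob
  pass <- mean(!bg$in_dbsnp | bg$exac_af < 0.01)
  se <- sqrt(0.3 * 0.7 / nrow(bg))
  expect_lt(abs(pass - 0.3), 3 * se)
})

test_that("synthetic outputs are bit-identical under one seed", {
  cfg <- synthetic_cohort_config(n_background_variants = 200, seed = 12)
  f1 <- simulate_family(cfg, "F1", seed = 12)
  f2 <- simulate_family(cfg, "F1", seed = 12)
  expect_identical(f1, f2)
  e1 <- simulate_expression(synthetic_expression_config(
    n_genes = 50, samples_per_cell = 4, seed = 12))
  e2 <- simulate_expression(synthetic_expression_config(
    n_genes = 50, samples_per_cell = 4, seed = 12))
  expect_identical(e1, e2)
})

test_that("planted expression module attains its target correlation", {
  mod <- sprintf("MOD%02d", 1:8)
  cfg <- synthetic_expression_config(
    n_genes = 100, samples_per_cell = 20, planted_module_genes = mod,
    module_correlation = 0.95, seed = 13)
  expr <- simulate_expression(cfg)
  meta <- expr$sample_meta
  cell <- meta$sample_id[meta$region_group == "frontal_cortex" &
                           meta$stage_group == "fetal"]
  r <- cor(t(expr$values[mod, cell]))
  mean_r <- mean(r[upper.tri(r)])
  expect_gte(mean_r, 0.85)
  expect_lte(mean_r, 1.0)
  # latent-factor closed form: rho = v / (v + noise_sd^2)
  v <- 0.95 * cfg$noise_sd^2 / (1 - 0.95)
  expect_equal(v / (v + cfg$noise_sd^2), 0.95)
  # outside the planted cell the module genes are independent
  other <- meta$sample_id[meta$region_group == "sub_cortical" &
                            meta$stage_group == "fetal"]
  r2 <- cor(t(expr$values[mod, other]))
  expect_lt(mean(abs(r2[upper.tri(r2)])), 0.5)
})

test_that("expression generator rejects degenerate cells and labels pcw", {
  expect_error(synthetic_expression_config(samples_per_cell = 2),
               "samples_per_cell")
  expr <- simulate_expression(synthetic_expression_config(
    n_genes = 20, samples_per_cell = 5, pcw_range = c(12L, 37L), seed = 1))
  meta <- expr$sample_meta
  expect_true(all(!is.na(meta$pcw[meta$stage_group == "fetal"])))
  expect_true(all(meta$pcw[meta$stage_group == "fetal"] >= 12))
  expect_true(all(meta$pcw[meta$stage_group == "fetal"] <= 37))
  expect_true(all(is.na(meta$pcw[meta$stage_group != "fetal"])))
  expect_equal(nrow(unique(meta[, c("region_group", "stage_group")])), 12)
})
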