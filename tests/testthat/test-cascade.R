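make_test_variants <- function(...) {
  rows <- list(...)
  base <- data.frame(key = sprintf("v%02d", seq_along(rows)),
                     chrom = "chr1", gene = "G1", quality = 99,
                     consequence = "missense", splice_predicted = FALSE,
                     cadd = 30, exac_af = 0, in_dbsnp = FALSE,
                     n_predictors = 4L, n_damaging = 4L,
                     stringsAsFactors = FALSE)
  for (i in seq_along(rows)) for (f in names(rows[[i]])) {
    base[i, f] <- rows[[i]][[f]]
  }
  base
}

test_that("quality tier removes low-quality and genotype-missing variants", {
  ped <- trio5_pedigree()
  v <- make_test_variants(list(quality = 10), list(quality = 50),
                          list(quality = 50))
  g <- matrix(2L, 5, 3, dimnames = list(ped$id, v$key))
  g["A1", "v03"] <- NA
  out <- tier_quality(v, g, filter_config(min_quality = 30))
  expect_equal(out$key, "v02")
  removed <- attr(out, "removed")
  expect_equal(removed$reason[removed$key == "v01"], "quality")
  expect_equal(removed$reason[removed$key == "v03"], "missing_genotype")
})

test_that("consequence tier keeps coding classes and predicted-splice
           synonymous only", {
  cfg <- filter_config()
  v <- make_test_variants(
    list(consequence = "missense"),
    list(consequence = "synonymous", splice_predicted = TRUE),
    list(consequence = "synonymous", splice_predicted = FALSE),
    list(consequence = "intergenic"),
    list(consequence = "weird_term"))
  expect_warning(out <- tier_consequence(v, cfg), "unknown consequence")
  expect_setequal(out$key, c("v01", "v02", "v05"))
})

test_that("frequency tier applies the dbSNP-absent-or-rare rule", {
  cfg <- filter_config()
  v <- make_test_variants(
    list(exac_af = 1942e-6, in_dbsnp = TRUE),   # rare known variant: kept
    list(exac_af = 0.02, in_dbsnp = TRUE),      # common: dropped
    list(exac_af = 0.02, in_dbsnp = FALSE),     # absent from dbSNP: kept
    list(exac_af = NA, in_dbsnp = TRUE))        # missing AF counts as 0
  out <- tier_frequency(v, cfg)
  expect_setequal(out$key, c("v01", "v03", "v04"))

  # 500 synthetic variants against a direct filter
  ccfg <- synthetic_cohort_config(n_background_variants = 499, seed = 41)
  ann <- simulate_annotations(make_family_variants_for_test(ccfg, "F", 41),
                              ccfg, 42)
  out2 <- tier_frequency(ann, cfg)
  expect_setequal(out2$key,
                  ann$key[!ann$in_dbsnp | ann$exac_af < cfg$af_max])
})

test_that("pathogenicity tier scores missense and exempts truncating", {
  cfg <- filter_config()
  v <- make_test_variants(
    list(cadd = 32, n_damaging = 3L),                      # kept
    list(cadd = 19),                                       # dropped
    list(cadd = NA, consequence = "frameshift"),           # exempt
    list(cadd = NA),                                       # missense no score
    list(cadd = 32, n_damaging = 2L))                      # 2/4 not majority
  model <- setNames(rep("homozygous", 5), v$key)
  out <- tier_pathogenicity(v, cfg, model)
  expect_setequal(out$key, c("v01", "v03"))
  removed <- attr(out, "removed")
  expect_equal(removed$reason[removed$key == "v04"], "no_score")
})

test_that("genotype-model tier labels homozygous and compound-het survivors", {
  ped <- trio5_pedigree()
  v <- make_test_variants(
    list(gene = "GA"),                       # hom in affected
    list(gene = "GB"), list(gene = "GB"),    # CH pair in trans
    list(gene = "GC"))                       # lone het: dropped
  g <- geno_matrix(list(
    FA = c(v01 = 1, v02 = 1, v03 = 0, v04 = 0),
    MO = c(v01 = 1, v02 = 0, v03 = 1, v04 = 1),
    A1 = c(v01 = 2, v02 = 1, v03 = 1, v04 = 1),
    A2 = c(v01 = 2, v02 = 1, v03 = 1, v04 = 1),
    U1 = c(v01 = 1, v02 = 1, v03 = 0, v04 = 0)))
  out <- tier_genotype_model(v, g, ped, filter_config())
  model <- attr(out, "model")
  expect_setequal(out$key, c("v01", "v02", "v03"))
  expect_equal(unname(model[c("v01", "v02", "v03")]),
               c("homozygous", "compound_het", "compound_het"))
  expect_equal(nrow(attr(out, "pairs")), 1)
})

test_that("control tier bars homozygotes and in-trans pair carriers", {
  cfg <- filter_config()
  v <- make_test_variants(list(), list(gene = "GB"), list(gene = "GB"))
  model <- setNames(c("homozygous", "compound_het", "compound_het"), v$key)
  pairs <- data.frame(key1 = "v02", key2 = "v03", phase_confirmed = TRUE,
                      gene = "GB", stringsAsFactors = FALSE)
  ctrl <- matrix(0L, 213, 3, dimnames = list(sprintf("C%03d", 1:213),
                                             v$key))
  out <- tier_controls(v, ctrl, cfg, model, pairs)
  expect_equal(nrow(out), 3)  # absent from all controls: all kept
  ctrl2 <- ctrl; ctrl2[1, "v01"] <- 2L          # one control homozygote
  out2 <- tier_controls(v, ctrl2, cfg, model, pairs)
  expect_false("v01" %in% out2$key)
  ctrl3 <- ctrl; ctrl3[5, c("v02", "v03")] <- 1L  # co-occurring het pair
  out3 <- tier_controls(v, ctrl3, cfg, model, pairs)
  expect_setequal(out3$key, "v01")
  # the lenient rule keeps the pair
  cfg2 <- filter_config(control_pair_rule = "hom_only")
  out4 <- tier_controls(v, ctrl3, cfg2, model, pairs)
  expect_equal(nrow(out4), 3)
  # small cohorts warn but proceed
  expect_warning(tier_controls(v, ctrl[1:50, ], cfg, model, pairs),
                 "control cohort")
})

test_that("the cascade recovers a planted homozygous causal variant", {
  cfg <- synthetic_cohort_config(n_background_variants = 1500, seed = 51)
  fam <- simulate_family(cfg, "F1", seed = 51)
  fam$controls <- simulate_controls(fam$variants, 213, fam$causal_keys,
                                    seed = 52)
  res <- run_cascade(fam, fam$controls)
  expect_true(all(fam$causal_keys %in% res$final_candidates$key))
  expect_equal(
    res$final_candidates$model[match(fam$causal_keys,
                                     res$final_candidates$key)],
    "homozygous")
  # survivor counts never increase down the cascade
  expect_true(all(diff(res$tiers$surviving) <= 0))
  expect_true(all(res$tiers$surviving <= res$tiers$input))
  # every removed variant carries exactly one (first-tier) reason
  expect_false(anyDuplicated(res$removed$key) > 0)
})

test_that("the cascade recovers a planted compound-het pair", {
  cfg <- synthetic_cohort_config(n_background_variants = 1500,
                                 causal_model = "compound_het",
                                 consanguinity = "unrelated", seed = 53)
  fam <- simulate_family(cfg, "F1", seed = 53)
  fam$controls <- simulate_controls(fam$variants, 213, fam$causal_keys,
                                    seed = 54)
  res <- run_cascade(fam, fam$controls)
  expect_true(all(fam$causal_keys %in% res$final_candidates$key))
  expect_true(all(res$final_candidates$model[
    res$final_candidates$key %in% fam$causal_keys] == "compound_het"))
  expect_gte(nrow(res$pairs), 1)
})

test_that("an empty variant table yields seven 0 -> 0 tier logs", {
  ped <- trio5_pedigree()
  v <- make_test_variants(list())[0, ]
  g <- matrix(integer(0), 5, 0, dimnames = list(ped$id, NULL))
  ctrl <- matrix(integer(0), 213, 0)
  res <- run_cascade(list(variants = v, genotypes = g, pedigree = ped),
                     ctrl)
  expect_equal(nrow(res$tiers), 7)
  expect_true(all(res$tiers$input == 0))
  expect_true(all(res$tiers$surviving == 0))
  expect_equal(nrow(res$final_candidates), 0)
})

test_that("pure per-variant tiers commute", {
  cfg <- filter_config()
  ccfg <- synthetic_cohort_config(n_background_variants = 800, seed = 61)
  ann <- simulate_annotations(make_family_variants_for_test(ccfg, "F", 61),
                              ccfg, 62)
  ped <- make_pedigree("first_cousin", 2, seed = 61)
  g <- matrix(2L, nrow(ped), nrow(ann),
              dimnames = list(ped$id, ann$key))
  orders <- list(
    function(x) tier_frequency(tier_consequence(tier_quality(x, g, cfg),
                                                cfg), cfg),
    function(x) tier_quality(tier_frequency(tier_consequence(x, cfg), cfg),
                             g, cfg))
  s1 <- orders[[1]](ann); s2 <- orders[[2]](ann)
  expect_setequal(s1$key, s2$key)
  # adding the pathogenicity screen in either position agrees too
  model <- setNames(rep("homozygous", nrow(ann)), ann$key)
  p1 <- tier_pathogenicity(s1, cfg, model)
  p2 <- orders[[1]](tier_pathogenicity(ann, cfg, model))
  expect_setequal(p1$key, p2$key)
})

test_that("relaxing a threshold never shrinks the final candidate set", {
  cfg <- synthetic_cohort_config(n_background_variants = 1000, seed = 71)
  fam <- simulate_family(cfg, "F1", seed = 71)
  fam$controls <- simulate_controls(fam$variants, 213, fam$causal_keys,
                                    seed = 72)
  strict <- run_cascade(fam, fam$controls, filter_config())
  for (relaxed_cfg in list(filter_config(af_max = 0.05),
                           filter_config(cadd_min = 10),
                           filter_config(min_quality = 10),
                           filter_config(predictor_majority = 0.25))) {
    relaxed <- run_cascade(fam, fam$controls, relaxed_cfg)
    expect_true(all(strict$final_candidates$key %in%
                      relaxed$final_candidates$key))
  }
})
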