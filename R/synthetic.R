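# Synthetic cohort generation: configuration, variant annotation fields,
# and the per-family simulate -> annotate -> drop pipeline. The generator is
# the ground-truth source for all cascade tests: a planted causal variant is
# constructed to satisfy every evidence tier, background variants follow
# explicit mixtures whose tier pass-rates are known in closed form.

#' Configuration for a synthetic consanguineous cohort
#'
#' @param n_families number of families to simulate.
#' @param consanguinity pedigree union type (see [make_pedigree()]).
#' @param n_affected_per_family affected children per family (>= 1).
#' @param n_background_variants benign background variants per family.
#' @param causal_class variant class of the planted causal allele: one of
#'   `"missense"`, `"nonsense"`, `"frameshift"`, `"splice"`,
#'   `"synonymous_splice"`.
#' @param causal_model `"homozygous"` or `"compound_het"`.
#' @param n_controls size of the matched control cohort (default 213).
#' @param bg_rare_prob probability a background variant is rare
#'   (population AF below 0.01); this is exactly the expected pass rate of
#'   the frequency tier on background variants.
#' @param bg_quality_pass_prob probability a background variant clears the
#'   default quality gate.
#' @param geno_missing_rate per-call missing-genotype rate on background
#'   variants.
#' @param max_conditioning_tries rejection-sampling cap for causal
#'   conditioning.
#' @param seed integer seed; fully determines all outputs.
#' @return a list of class `"synthetic_cohort_config"`.
#' @export
synthetic_cohort_config <- function(n_families = 1,
                                    consanguinity = "first_cousin",
                                    n_affected_per_family = 2,
                                    n_background_variants = 5000,
                                    causal_class = "missense",
                                    causal_model = "homozygous",
                                    n_controls = 213,
                                    bg_rare_prob = 0.3,
                                    bg_quality_pass_prob = 0.95,
                                    geno_missing_rate = 0.002,
                                    max_conditioning_tries = 10000,
                                    seed = 1) {
  stopifnot(n_controls >= 0, n_affected_per_family >= 1,
            n_background_variants >= 0,
            causal_class %in% c("missense", "nonsense", "frameshift",
                                "splice", "synonymous_splice"),
            causal_model %in% c("homozygous", "compound_het"),
            bg_rare_prob >= 0, bg_rare_prob <= 1)
  structure(as.list(environment()), class = "synthetic_cohort_config")
}

# consequence vocabulary used by the generator and the consequence tier
CONSEQUENCE_RETAINED <- c("missense", "nonsense", "frameshift", "splice")
CONSEQUENCE_DROPPED  <- c("synonymous", "intronic", "intergenic", "utr")

causal_hgvs <- function(class) {
  switch(class,
    missense           = list(c = "c.100A>G",    p = "p.(Lys34Glu)",
                              consequence = "missense"),
    nonsense           = list(c = "c.100C>T",    p = "p.(Gln34*)",
                              consequence = "nonsense"),
    frameshift         = list(c = "c.100delA",   p = "p.(Lys34Argfs*10)",
                              consequence = "frameshift"),
    splice             = list(c = "c.100+1G>A",  p = "p.?",
                              consequence = "splice"),
    synonymous_splice  = list(c = "c.102A>G",    p = "p.(Lys34Lys)",
                              consequence = "synonymous"))
}

#' Annotate variants with the fields used by the evidence tiers
#'
#' Adds to each variant: a site quality, a consequence term, a CADD-like
#' score, a population allele frequency, a dbSNP-membership flag, and
#' in-silico predictor calls (damaging out of total). Rows flagged
#' `is_causal` are set to pass every tier by construction: high quality,
#' class-appropriate HGVS/consequence, population AF 0, absent from dbSNP,
#' CADD 35 with 4/4 damaging calls (splice prediction set for the
#' synonymous-splice class).
#'
#' Background fields follow explicit mixtures: rare (AF < 0.01) with
#' probability `cfg$bg_rare_prob`, common otherwise (always in dbSNP);
#' quality clears the default gate with probability
#' `cfg$bg_quality_pass_prob`.
#'
#' @param variants data.frame with at least `key`, `gene`, `is_causal`
#'   (logical) and optionally `causal_class`.
#' @param cfg a [synthetic_cohort_config()].
#' @param seed integer seed.
#' @return the variant table with annotation columns appended.
#' @export
simulate_annotations <- function(variants, cfg, seed = cfg$seed) {
  n <- nrow(variants)
  with_seed(seed, {
    rare <- stats::runif(n) < cfg$bg_rare_prob
    af <- ifelse(rare, stats::runif(n, 0, 0.005), stats::runif(n, 0.01, 0.5))
    in_dbsnp <- ifelse(rare, stats::runif(n) < 0.5, TRUE)
    qual_pass <- stats::runif(n) < cfg$bg_quality_pass_prob
    quality <- ifelse(qual_pass, stats::runif(n, 30, 100),
                      stats::runif(n, 0, 30))
    consequence <- sample(c(CONSEQUENCE_RETAINED, CONSEQUENCE_DROPPED), n,
                          replace = TRUE,
                          prob = c(0.45, 0.02, 0.03, 0.02, 0.30, 0.10,
                                   0.05, 0.03))
    splice_predicted <- consequence == "synonymous" & stats::runif(n) < 0.02
    cadd <- ifelse(consequence == "missense", stats::runif(n, 0, 40),
                   NA_real_)
    n_predictors <- rep(4L, n)
    n_damaging <- stats::rbinom(n, 4L, 0.3)

    out <- variants
    out$quality <- quality
    out$consequence <- consequence
    out$splice_predicted <- splice_predicted
    out$cadd <- cadd
    out$exac_af <- af
    out$in_dbsnp <- in_dbsnp
    out$n_predictors <- n_predictors
    out$n_damaging <- n_damaging

    ic <- which(out$is_causal)
    for (i in ic) {
      cls <- if (!is.null(out$causal_class)) out$causal_class[i] else
        cfg$causal_class
      h <- causal_hgvs(cls)
      out$quality[i] <- 99
      out$consequence[i] <- h$consequence
      out$hgvs_c[i] <- h$c
      out$hgvs_p[i] <- h$p
      out$splice_predicted[i] <- cls == "synonymous_splice"
      out$cadd[i] <- if (h$consequence == "missense") 35 else NA_real_
      out$exac_af[i] <- 0
      out$in_dbsnp[i] <- FALSE
      out$n_damaging[i] <- 4L
    }
    out
  })
}

# variant scaffold for one family: causal row(s) + background rows
make_family_variants <- function(cfg, family_id, seed) {
  n_causal <- if (cfg$causal_model == "compound_het") 2L else 1L
  nbg <- cfg$n_background_variants
  with_seed(seed, {
    pos <- sample.int(2e8, n_causal + nbg)
    chrom <- sample(paste0("chr", 1:22), n_causal + nbg, replace = TRUE)
    chrom[seq_len(n_causal)] <- "chr2"       # causal site(s) share one gene
    ref <- sample(c("A", "C", "G", "T"), n_causal + nbg, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    gene <- c(rep(paste0("CAUSAL_", family_id), n_causal),
              sprintf("BG%05d", sample.int(99999, nbg)))
    data.frame(
      key = paste0(chrom, ":", pos, ref, ">", alt),
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      transcript = NA_character_, hgvs_c = NA_character_,
      hgvs_p = NA_character_, family_id = family_id,
      is_causal = c(rep(TRUE, n_causal), rep(FALSE, nbg)),
      causal_class = c(rep(cfg$causal_class, n_causal), rep(NA, nbg)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate one positive family: pedigree, annotated variants, genotypes
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param family_id family identifier.
#' @param seed integer seed for this family.
#' @return list with elements `pedigree`, `variants` (annotated),
#'   `genotypes` (GenotypeTable), `causal_keys`.
#' @export
simulate_family <- function(cfg, family_id = "FAM1", seed = cfg$seed) {
  if (cfg$causal_model == "compound_het" &&
      cfg$consanguinity == "first_cousin") {
    ped <- make_pedigree("first_cousin", cfg$n_affected_per_family,
                         seed = seed, family_id = family_id)
  } else if (cfg$causal_model == "compound_het") {
    ped <- make_pedigree("unrelated", cfg$n_affected_per_family,
                         seed = seed, family_id = family_id)
  } else {
    ped <- make_pedigree(cfg$consanguinity, cfg$n_affected_per_family,
                         seed = seed, family_id = family_id)
  }
  variants <- make_family_variants(cfg, family_id, seed = seed + 1L)
  ann <- simulate_annotations(variants, cfg, seed = seed + 2L)
  causal_keys <- ann$key[ann$is_causal]
  bg_af <- stats::setNames(ann$exac_af[!ann$is_causal],
                           ann$key[!ann$is_causal])
  geno <- drop_genotypes(ped, causal_keys, cfg, background_af = bg_af,
                         seed = seed + 3L)
  list(pedigree = ped, variants = ann, genotypes = geno,
       causal_keys = causal_keys)
}

#' Simulate a whole cohort plus its matched control genotypes
#'
#' @param cfg a [synthetic_cohort_config()].
#' @return list of per-family bundles (see [simulate_family()]); each bundle
#'   gains a `controls` GenotypeTable for that family's variants.
#' @export
simulate_cohort <- function(cfg) {
  lapply(seq_len(cfg$n_families), function(i) {
    fam <- simulate_family(cfg, family_id = sprintf("FAM%03d", i),
                           seed = cfg$seed + 101L * i)
    fam$controls <- simulate_controls(fam$variants, cfg$n_controls,
                                      causal_keys = fam$causal_keys,
                                      seed = cfg$seed + 101L * i + 50L)
    fam
  })
}
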