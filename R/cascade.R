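# The seven-tier filtration cascade for one family, realizing the six
# evidence categories (segregation; dbSNP absence or population AF < 0.01;
# absence in matched controls; CADD > 20; multi-program in-silico
# pathogenicity; recessive genotype model) behind a leading quality gate.
# Fixed order: quality -> consequence -> frequency -> genotype model ->
# segregation -> controls -> pathogenicity. Cheap per-variant filters run
# first; pedigree- and cohort-dependent filters follow.

#' Filtration cascade configuration
#'
#' @param min_quality minimum site quality retained by the quality tier.
#' @param coding_consequences consequence terms retained unconditionally by
#'   the consequence tier (synonymous is retained only with a splice
#'   prediction).
#' @param af_max maximum population allele frequency for variants present
#'   in dbSNP (absent variants pass regardless); default 0.01.
#' @param af_max_strict stricter frequency reported for surviving candidate
#'   sets (0.002); used in summaries, not as a filter.
#' @param cadd_min missense variants must exceed this CADD score (default
#'   20); truncating classes are exempt.
#' @param predictor_majority missense variants must have a damaging fraction
#'   of in-silico predictor calls strictly above this (default 0.5).
#' @param control_pair_rule how compound-het pairs are screened against
#'   controls: `"hom_or_trans"` (default) drops a pair when either partner
#'   is hom-alt in any control or both partners co-occur het in one
#'   control; `"hom_only"` drops only on a control homozygote.
#' @param n_controls_required_clean expected control-cohort size (default
#'   213); a smaller cohort triggers a warning, not an error.
#' @return a list of class `"filter_config"`.
#' @export
filter_config <- function(min_quality = 30,
                          coding_consequences = c("missense", "nonsense",
                                                  "frameshift", "splice"),
                          af_max = 0.01,
                          af_max_strict = 0.002,
                          cadd_min = 20,
                          predictor_majority = 0.5,
                          control_pair_rule = c("hom_or_trans", "hom_only"),
                          n_controls_required_clean = 213) {
  stopifnot(af_max >= 0, af_max <= 1, cadd_min >= 0)
  control_pair_rule <- match.arg(control_pair_rule)
  structure(as.list(environment()), class = "filter_config")
}

removed_df <- function(keys, reason) {
  data.frame(key = keys, reason = rep_len(reason, length(keys)),
             stringsAsFactors = FALSE)
}

#' Tier 1: site quality and genotype completeness
#'
#' Removes variants with quality below `cfg$min_quality` or with a missing
#' genotype in any analyzed (genotyped) family member.
#'
#' @param variants annotated variant data.frame (must carry `key`,
#'   `quality`).
#' @param genotypes GenotypeTable covering the analyzed members.
#' @param cfg a [filter_config()].
#' @return the surviving subset of `variants`, with a `removed` attribute
#'   (data.frame `key`, `reason`).
#' @export
tier_quality <- function(variants, genotypes, cfg) {
  qual <- ifelse(is.na(variants$quality), -Inf, variants$quality)
  low <- qual < cfg$min_quality
  has_missing <- apply(is.na(genotypes[, variants$key, drop = FALSE]), 2, any)
  drop <- low | has_missing
  reason <- ifelse(low, "quality", "missing_genotype")
  structure(variants[!drop, , drop = FALSE],
            removed = data.frame(key = variants$key[drop],
                                 reason = reason[drop],
                                 stringsAsFactors = FALSE))
}

#' Tier 2: coding consequence
#'
#' Keeps missense, nonsense (stop-gain), frameshift and canonical-splice
#' variants, plus synonymous variants with a positive splice prediction;
#' drops other synonymous, intronic, intergenic and UTR variants. Unknown
#' consequence terms are retained with a warning (conservative).
#'
#' @inheritParams tier_quality
#' @return surviving subset with `removed` attribute.
#' @export
tier_consequence <- function(variants, cfg) {
  cons <- tolower(variants$consequence)
  keep <- cons %in% cfg$coding_consequences |
    (cons == "synonymous" & isTRUE_vec(variants$splice_predicted))
  unknown <- !cons %in% c(cfg$coding_consequences, CONSEQUENCE_DROPPED)
  if (any(unknown & !keep)) {
    warning("unknown consequence term(s) retained: ",
            paste(unique(cons[unknown & !keep]), collapse = ", "),
            call. = FALSE)
    keep <- keep | unknown
  }
  structure(variants[keep, , drop = FALSE],
            removed = removed_df(variants$key[!keep], "consequence"))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Tier 3: population frequency
#'
#' Keeps variants absent from dbSNP, or present with population allele
#' frequency below `cfg$af_max`. Missing allele frequency is treated as 0.
#'
#' @inheritParams tier_quality
#' @return surviving subset with `removed` attribute.
#' @export
tier_frequency <- function(variants, cfg) {
  af <- ifelse(is.na(variants$exac_af), 0, variants$exac_af)
  keep <- !isTRUE_vec(variants$in_dbsnp) | af < cfg$af_max
  structure(variants[keep, , drop = FALSE],
            removed = removed_df(variants$key[!keep], "frequency"))
}

#' Tier 4: recessive genotype model
#'
#' Keeps variants homozygous-alt in every genotyped affected member
#' (labelled `homozygous`; hemizygous X-linked males count as hom-alt), plus
#' compound-heterozygous pairs found by [pair_compound_hets()] within each
#' gene (labelled `compound_het`).
#'
#' @inheritParams tier_quality
#' @param pedigree the family pedigree.
#' @return surviving subset with attributes `removed`, `model` (named
#'   character: `homozygous`/`compound_het` per key) and `pairs`
#'   (data.frame from [pair_compound_hets()]).
#' @export
tier_genotype_model <- function(variants, genotypes, pedigree, cfg) {
  samples <- intersect(pedigree$id, rownames(genotypes))
  ped <- pedigree[match(samples, pedigree$id), ]
  aff <- samples[ped$affected]
  if (!length(aff)) {
    stop("no affected member genotyped; family skipped", call. = FALSE)
  }
  male <- stats::setNames(ped$sex == 1L, ped$id)
  g_aff <- genotypes[aff, variants$key, drop = FALSE]
  xlinked <- is_x_chrom(variants$chrom)
  hom <- vapply(seq_along(variants$key), function(j) {
    g <- g_aff[, j]
    known <- !is.na(g)
    if (!any(known)) return(FALSE)
    if (xlinked[j]) {
      all(ifelse(male[aff][known], g[known] >= 1L, g[known] == 2L))
    } else {
      all(g[known] == 2L)
    }
  }, logical(1))

  het_all <- vapply(seq_along(variants$key), function(j) {
    g <- g_aff[, j]
    known <- !is.na(g)
    any(known) && all(g[known] == 1L)
  }, logical(1))
  pair_rows <- list()
  in_pair <- character(0)
  for (gene in unique(variants$gene[het_all & !hom])) {
    keys <- variants$key[het_all & !hom & variants$gene == gene]
    p <- pair_compound_hets(keys, genotypes, pedigree)
    if (nrow(p)) {
      p$gene <- gene
      pair_rows[[length(pair_rows) + 1]] <- p
      in_pair <- union(in_pair, c(p$key1, p$key2))
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  keep <- hom | variants$key %in% in_pair
  model <- ifelse(hom, "homozygous",
                  ifelse(variants$key %in% in_pair, "compound_het", NA))
  structure(variants[keep, , drop = FALSE],
            removed = removed_df(variants$key[!keep], "genotype_model"),
            model = stats::setNames(model[keep], variants$key[keep]),
            pairs = pairs)
}

is_x_chrom <- function(chrom) {
  if (is.null(chrom)) return(logical(0))
  grepl("^(chr)?x$", chrom, ignore.case = TRUE)
}

#' Tier 5: segregation
#'
#' Delegates to [check_recessive_segregation()] for homozygous-model
#' variants across all genotyped members; compound-het pairs have already
#' been validated (affected het for both, in trans, unaffected not carrying
#' both in trans) by [pair_compound_hets()] and are kept.
#'
#' @inheritParams tier_genotype_model
#' @param model named model labels from [tier_genotype_model()].
#' @param pairs pair table from [tier_genotype_model()].
#' @return surviving subset with attributes `removed`, `model`, `pairs`.
#' @export
tier_segregation <- function(variants, genotypes, pedigree, model,
                             pairs = NULL) {
  xlinked <- is_x_chrom(variants$chrom)
  keep <- vapply(seq_along(variants$key), function(j) {
    k <- variants$key[j]
    if (identical(model[[k]], "compound_het")) return(TRUE)
    check_recessive_segregation(k, genotypes, pedigree,
                                x_linked = xlinked[j])$consistent
  }, logical(1))
  structure(variants[keep, , drop = FALSE],
            removed = removed_df(variants$key[!keep], "segregation"),
            model = model[variants$key[keep]],
            pairs = pairs)
}

#' Tier 6: matched control cohort
#'
#' Drops any variant observed homozygous-alt in a control individual.
#' Compound-het pairs are additionally dropped when both partners co-occur
#' heterozygous in one control (`cfg$control_pair_rule = "hom_or_trans"`,
#' the default). A control cohort smaller than
#' `cfg$n_controls_required_clean` yields a warning and proceeds with the
#' available individuals.
#'
#' @inheritParams tier_segregation
#' @param control_genotypes GenotypeTable of the control cohort.
#' @return surviving subset with attributes `removed`, `model`, `pairs`,
#'   `n_controls_used`.
#' @export
tier_controls <- function(variants, control_genotypes, cfg, model,
                          pairs = NULL) {
  n_ctrl <- nrow(control_genotypes)
  if (nrow(variants) == 0) {
    return(structure(variants, removed = removed_df(character(0), "none"),
                     model = model[character(0)], pairs = pairs,
                     n_controls_used = n_ctrl))
  }
  if (n_ctrl < cfg$n_controls_required_clean) {
    warning(sprintf("control cohort has %d individuals (< %d required)",
                    n_ctrl, cfg$n_controls_required_clean), call. = FALSE)
  }
  cg <- control_genotypes[, variants$key, drop = FALSE]
  hom_in_ctrl <- apply(cg == 2L, 2, any, na.rm = TRUE)
  drop <- hom_in_ctrl
  reason <- ifelse(drop, "control_homozygote", NA_character_)
  if (!is.null(pairs) && nrow(pairs) && cfg$control_pair_rule ==
      "hom_or_trans") {
    for (i in seq_len(nrow(pairs))) {
      k1 <- pairs$key1[i]; k2 <- pairs$key2[i]
      if (!k1 %in% variants$key || !k2 %in% variants$key) next
      co_het <- any(cg[, k1] == 1L & cg[, k2] == 1L, na.rm = TRUE)
      if (co_het) {
        for (k in c(k1, k2)) {
          j <- match(k, variants$key)
          if (!drop[j]) { drop[j] <- TRUE; reason[j] <- "control_trans_pair" }
        }
      }
    }
  }
  surv <- variants[!drop, , drop = FALSE]
  pairs2 <- prune_pairs(pairs, surv$key)
  structure(surv,
            removed = data.frame(key = variants$key[drop],
                                 reason = reason[drop],
                                 stringsAsFactors = FALSE),
            model = model[surv$key],
            pairs = pairs2,
            n_controls_used = n_ctrl)
}

# drop pairs with a lost partner
prune_pairs <- function(pairs, alive) {
  if (is.null(pairs) || !nrow(pairs)) return(pairs)
  pairs[pairs$key1 %in% alive & pairs$key2 %in% alive, , drop = FALSE]
}

#' Tier 7: in-silico pathogenicity
#'
#' Missense variants are kept iff CADD exceeds `cfg$cadd_min` and the
#' damaging fraction of predictor calls exceeds `cfg$predictor_majority`;
#' missense with missing CADD is dropped (`no_score`). Nonsense,
#' frameshift, splice and splice-predicted synonymous variants are exempt
#' from the score tests (their CADD is typically unreported). A compound-het
#' partner orphaned by this tier is removed as well (`orphaned_pair`).
#'
#' @inheritParams tier_controls
#' @return surviving subset with attributes `removed`, `model`, `pairs`.
#' @export
tier_pathogenicity <- function(variants, cfg, model, pairs = NULL) {
  cons <- tolower(variants$consequence)
  missense <- cons == "missense"
  frac <- variants$n_damaging / variants$n_predictors
  no_score <- missense & is.na(variants$cadd)
  fail <- missense & !no_score &
    !(variants$cadd > cfg$cadd_min & frac > cfg$predictor_majority)
  drop <- no_score | fail
  reason <- ifelse(no_score, "no_score", "pathogenicity")
  surv <- variants[!drop, , drop = FALSE]
  pairs2 <- prune_pairs(pairs, surv$key)
  paired_keys <- if (!is.null(pairs2) && nrow(pairs2))
    unique(c(pairs2$key1, pairs2$key2)) else character(0)
  orphan <- !is.na(model[surv$key]) & model[surv$key] == "compound_het" &
    !surv$key %in% paired_keys
  removed <- rbind(
    data.frame(key = variants$key[drop], reason = reason[drop],
               stringsAsFactors = FALSE),
    removed_df(surv$key[orphan], "orphaned_pair"))
  surv <- surv[!orphan, , drop = FALSE]
  structure(surv, removed = removed, model = model[surv$key],
            pairs = pairs2)
}

#' Run the seven-tier filtration cascade for one family
#'
#' Applies, in order: quality -> consequence -> frequency -> genotype model
#' -> segregation -> controls -> pathogenicity, logging input and survivor
#' counts per tier and the first failing tier of every removed variant.
#'
#' @param family list with `variants` (annotated data.frame), `genotypes`
#'   (GenotypeTable), `pedigree`.
#' @param controls GenotypeTable of the matched control cohort.
#' @param cfg a [filter_config()].
#' @return object of class `"cascade_result"`: list with `family_id`,
#'   `tiers` (data.frame: `tier`, `input`, `surviving`), `removed`
#'   (data.frame: `key`, `tier`, `reason`), `final_candidates` (variant
#'   data.frame with a `model` column), `pairs`, `n_controls_used`.
#' @export
run_cascade <- function(family, controls, cfg = filter_config()) {
  v <- family$variants
  tiers <- c("quality", "consequence", "frequency", "genotype_model",
             "segregation", "controls", "pathogenicity")
  log <- data.frame(tier = tiers, input = NA_integer_,
                    surviving = NA_integer_, stringsAsFactors = FALSE)
  removed <- list()
  note_removed <- function(step, x) {
    r <- attr(x, "removed")
    if (!is.null(r) && nrow(r)) {
      r$tier <- step
      removed[[length(removed) + 1]] <<- r[, c("key", "tier", "reason")]
    }
  }
  run_step <- function(step, x, f) {
    log$input[log$tier == step] <<- nrow(x)
    out <- f(x)
    note_removed(step, out)
    log$surviving[log$tier == step] <<- nrow(out)
    out
  }

  s <- run_step("quality", v,
                function(x) tier_quality(x, family$genotypes, cfg))
  s <- run_step("consequence", s, function(x) tier_consequence(x, cfg))
  s <- run_step("frequency", s, function(x) tier_frequency(x, cfg))
  s <- run_step("genotype_model", s, function(x)
    tier_genotype_model(x, family$genotypes, family$pedigree, cfg))
  model <- attr(s, "model"); pairs <- attr(s, "pairs")
  s <- run_step("segregation", s, function(x)
    tier_segregation(x, family$genotypes, family$pedigree, model, pairs))
  model <- attr(s, "model"); pairs <- attr(s, "pairs")
  s <- run_step("controls", s, function(x)
    tier_controls(x, controls, cfg, model, pairs))
  model <- attr(s, "model"); pairs <- attr(s, "pairs")
  n_ctrl <- attr(s, "n_controls_used")
  s <- run_step("pathogenicity", s, function(x)
    tier_pathogenicity(x, cfg, model, pairs))
  model <- attr(s, "model"); pairs <- attr(s, "pairs")

  final <- s
  attr(final, "removed") <- NULL
  final$model <- unname(model[final$key])
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(key = character(0), tier = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(list(family_id = family$pedigree$family_id[1],
                 tiers = log, removed = removed_df,
                 final_candidates = final, pairs = pairs,
                 n_controls_used = n_ctrl),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("cascade_result for family", x$family_id, "\n")
  print(x$tiers, row.names = FALSE)
  cat(nrow(x$final_candidates), "final candidate variant(s)\n")
  invisible(x)
}
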