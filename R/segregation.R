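# Recessive segregation checks. Genotypes are 0/1/2/NA alt-allele counts
# (see genotypes.R). X-linked sites in hemizygous males are accepted as
# "alt" with a single allele: an affected male is consistent when his call
# is 1 or 2, and an unaffected male is violating when his call is >= 1.

#' Check consistency of a variant with recessive segregation
#'
#' A variant is consistent with an autosomal-recessive model when every
#' genotyped affected member is homozygous alt, no genotyped unaffected
#' member is homozygous alt, and every genotyped unaffected parent of an
#' affected member is heterozygous (obligate carrier). Under `x_linked =
#' TRUE`, males are treated as hemizygous: any alt call in an affected male
#' is consistent, any alt call in an unaffected male is a violation, and the
#' paternal obligate-carrier constraint is waived for affected sons.
#' Missing genotypes impose no constraint; they are recorded in `skipped`.
#'
#' With no relatives genotyped (affected-only data) any variant hom-alt in
#' the affected is vacuously consistent.
#'
#' @param variant_key column name of the variant in `genotypes`.
#' @param genotypes GenotypeTable (samples x variants).
#' @param pedigree a pedigree.
#' @param x_linked treat the site as X-linked (hemizygous males).
#' @return list of class `"segregation_verdict"`: `consistent` (logical),
#'   `violations` (data.frame: `sample_id`, `observed`, `expected`),
#'   `skipped` (ids with missing genotype).
#' @export
check_recessive_segregation <- function(variant_key, genotypes, pedigree,
                                        x_linked = FALSE) {
  samples <- intersect(pedigree$id, rownames(genotypes))
  g <- genotypes[samples, variant_key]
  names(g) <- samples
  ped <- pedigree[match(samples, pedigree$id), ]
  skipped <- samples[is.na(g)]
  viol <- list()
  note <- function(id, expected) {
    viol[[length(viol) + 1]] <<- data.frame(
      sample_id = id, observed = genotype_label(g[[id]]),
      expected = expected, stringsAsFactors = FALSE)
  }
  male <- stats::setNames(ped$sex == 1L, ped$id)
  is_alt_hom <- function(id) {
    if (x_linked && male[[id]]) g[[id]] >= 1L else g[[id]] == 2L
  }
  for (id in setdiff(samples, skipped)) {
    aff <- ped$affected[ped$id == id]
    if (aff && !is_alt_hom(id)) {
      note(id, if (x_linked && male[[id]]) "hemizygous_alt" else "hom_alt")
    } else if (!aff && is_alt_hom(id)) {
      note(id, if (x_linked && male[[id]]) "not_carrier" else "not_hom_alt")
    }
  }
  # obligate carriers: genotyped unaffected parents of affected members
  for (id in samples[ped$affected]) {
    r <- ped[ped$id == id, ]
    for (parent in c(r$father, r$mother)) {
      if (parent == "0" || !parent %in% samples || parent %in% skipped) next
      p_aff <- ped$affected[ped$id == parent]
      if (p_aff) next
      if (x_linked && male[[id]] && parent == r$father) next
      if (x_linked && male[[parent]]) next  # hemizygous father handled above
      if (g[[parent]] != 1L) note(parent, "het (obligate carrier)")
    }
  }
  violations <- if (length(viol)) {
    unique(do.call(rbind, viol))
  } else {
    data.frame(sample_id = character(0), observed = character(0),
               expected = character(0), stringsAsFactors = FALSE)
  }
  structure(list(consistent = nrow(violations) == 0L,
                 violations = violations, skipped = skipped),
            class = "segregation_verdict")
}

#' @export
print.segregation_verdict <- function(x, ...) {
  cat("segregation:", if (x$consistent) "consistent" else
    paste0("inconsistent (", nrow(x$violations), " violation(s))"), "\n")
  invisible(x)
}

#' Pair heterozygous variants of one gene into compound-het candidates
#'
#' Considers every unordered pair of the supplied variant keys (all assumed
#' to annotate one gene) and returns the pairs compatible with a
#' compound-heterozygous recessive model: every genotyped affected member is
#' heterozygous for both variants; when the affected members' parents are
#' genotyped the two variants must be in trans (each parent carries exactly
#' one of the two); and no genotyped unaffected member may carry both
#' variants in trans. When parental genotypes are unavailable the phase is
#' unknowable and the pair is retained with `phase_confirmed = FALSE`.
#'
#' @param gene_variants character vector of variant keys in one gene.
#' @param genotypes GenotypeTable.
#' @param pedigree a pedigree.
#' @return data.frame with columns `key1`, `key2`, `phase_confirmed`.
#' @export
pair_compound_hets <- function(gene_variants, genotypes, pedigree) {
  empty <- data.frame(key1 = character(0), key2 = character(0),
                      phase_confirmed = logical(0), stringsAsFactors = FALSE)
  if (length(gene_variants) < 2) return(empty)
  samples <- intersect(pedigree$id, rownames(genotypes))
  ped <- pedigree[match(samples, pedigree$id), ]
  aff <- samples[ped$affected]
  unaff <- samples[!ped$affected]
  carries <- function(id, k) {
    v <- genotypes[id, k]
    !is.na(v) && v >= 1L
  }
  out <- list()
  combs <- utils::combn(sort(gene_variants), 2)
  for (j in seq_len(ncol(combs))) {
    k1 <- combs[1, j]; k2 <- combs[2, j]
    g1 <- genotypes[aff, k1]; g2 <- genotypes[aff, k2]
    known <- !is.na(g1) & !is.na(g2)
    if (!any(known)) next
    if (!all(g1[known] == 1L & g2[known] == 1L)) next
    phase_confirmed <- FALSE
    phase_bad <- FALSE
    for (id in aff) {
      r <- ped[ped$id == id, ]
      if (r$father %in% samples && r$mother %in% samples &&
          !is.na(genotypes[r$father, k1]) && !is.na(genotypes[r$father, k2]) &&
          !is.na(genotypes[r$mother, k1]) && !is.na(genotypes[r$mother, k2])) {
        f1 <- carries(r$father, k1); f2 <- carries(r$father, k2)
        m1 <- carries(r$mother, k1); m2 <- carries(r$mother, k2)
        trans <- (f1 && !f2 && m2 && !m1) || (f2 && !f1 && m1 && !m2)
        if (trans) phase_confirmed <- TRUE else phase_bad <- TRUE
      }
    }
    if (phase_bad) next
    # unaffected members must not carry both variants in trans; trans origin
    # is demonstrable only when each parent carries exactly one variant
    sib_bad <- FALSE
    for (id in unaff) {
      if (!carries(id, k1) || !carries(id, k2)) next
      r <- ped[ped$id == id, ]
      if (r$father %in% samples && r$mother %in% samples) {
        f1 <- carries(r$father, k1); f2 <- carries(r$father, k2)
        m1 <- carries(r$mother, k1); m2 <- carries(r$mother, k2)
        trans <- (f1 && !f2 && m2 && !m1) || (f2 && !f1 && m1 && !m2)
        if (trans) sib_bad <- TRUE
      }
    }
    if (sib_bad) next
    out[[length(out) + 1]] <- data.frame(
      key1 = k1, key2 = k2, phase_confirmed = phase_confirmed,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty
}
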