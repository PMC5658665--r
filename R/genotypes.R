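# Genotypes are coded as integer alt-allele counts: 0 = hom_ref, 1 = het,
# 2 = hom_alt, NA = missing. A GenotypeTable is an integer matrix with one
# row per sample and one column per variant key.

GENOTYPE_LABELS <- c(`0` = "hom_ref", `1` = "het", `2` = "hom_alt")

#' Label integer genotype codes
#' @param g integer vector of 0/1/2/NA codes.
#' @return character vector of `hom_ref`/`het`/`hom_alt`/`missing`.
#' @export
genotype_label <- function(g) {
  out <- GENOTYPE_LABELS[as.character(g)]
  out[is.na(g)] <- "missing"
  unname(out)
}

#' Unconditioned Mendelian gene dropping
#'
#' Transmits founder genotypes down a pedigree: each non-founder receives one
#' allele from each parent, drawn uniformly from that parent's two alleles.
#' Vectorized over variants (columns).
#'
#' @param ped a pedigree.
#' @param founder_geno integer matrix (founders x variants) of 0/1/2 codes;
#'   rownames must be the founder ids.
#' @return integer matrix (all members x variants) of genotype codes.
#' @export
gene_drop <- function(ped, founder_geno) {
  founders <- pedigree_founders(ped)
  if (!all(founders %in% rownames(founder_geno))) {
    stop("founder_geno must cover all founders", call. = FALSE)
  }
  J <- ncol(founder_geno)
  geno <- matrix(NA_integer_, nrow = nrow(ped), ncol = J,
                 dimnames = list(ped$id, colnames(founder_geno)))
  geno[founders, ] <- founder_geno[founders, , drop = FALSE]
  for (id in pedigree_topo_order(ped)) {
    r <- ped[ped$id == id, ]
    if (r$father == "0") next
    pat <- stats::rbinom(J, 1L, geno[r$father, ] / 2)
    mat <- stats::rbinom(J, 1L, geno[r$mother, ] / 2)
    geno[id, ] <- pat + mat
  }
  geno
}

#' Find the sibship parents of a pedigree's affected members
#' @keywords internal
affected_parents <- function(ped) {
  aff <- ped[ped$affected, ]
  if (!nrow(aff)) stop("pedigree has no affected member", call. = FALSE)
  list(father = aff$father[1], mother = aff$mother[1])
}

# founders whose descendants include `id` (or `id` itself when a founder)
founder_ancestors_of <- function(ped, id) {
  founders <- pedigree_founders(ped)
  anc <- function(x) {
    if (x == "0") return(character(0))
    r <- ped[ped$id == x, ]
    c(x, anc(r$father), anc(r$mother))
  }
  intersect(anc(id), founders)
}

#' Drop genotypes for a synthetic family
#'
#' Plants the causal allele(s) in founder haplotypes and gene-drops through
#' the pedigree, conditioning by rejection sampling so that every affected
#' member fits the requested recessive model (`homozygous`: hom-alt in all
#' affected, no unaffected hom-alt; `compound_het`: both causal variants het
#' and in trans in all affected, no unaffected carrying both in trans).
#' Background variants are dropped unconditionally from founder genotypes
#' drawn under Hardy-Weinberg at the supplied allele frequencies.
#'
#' @param pedigree a pedigree.
#' @param causal character vector of causal variant keys: length 1 for the
#'   homozygous model, length 2 for compound het.
#' @param cfg a [synthetic_cohort_config()].
#' @param background_af named numeric vector of founder allele frequencies
#'   for the background variants (may be `NULL` for none).
#' @param seed integer seed.
#' @return integer GenotypeTable (members x variants); causal columns first.
#'   Attribute `causal_keys` records the planted keys.
#' @export
drop_genotypes <- function(pedigree, causal, cfg, background_af = NULL,
                           seed = cfg$seed) {
  model <- cfg$causal_model
  max_tries <- cfg$max_conditioning_tries
  founders <- pedigree_founders(pedigree)
  par <- affected_parents(pedigree)
  aff <- pedigree$id[pedigree$affected]
  unaff <- pedigree$id[!pedigree$affected]

  with_seed(seed, {
    causal_geno <- if (model == "homozygous") {
      if (length(causal) != 1) stop("homozygous model takes 1 causal key")
      shared <- intersect(founder_ancestors_of(pedigree, par$father),
                          founder_ancestors_of(pedigree, par$mother))
      if (!length(shared)) {
        stop("conditioning impossible: no founder is a common ancestor of ",
             "both parents, a single founder copy cannot become homozygous",
             call. = FALSE)
      }
      fg <- matrix(0L, length(founders), 1,
                   dimnames = list(founders, causal))
      fg[shared[1], 1] <- 1L
      ok <- FALSE
      for (i in seq_len(max_tries)) {
        g <- gene_drop(pedigree, fg)
        if (all(g[aff, 1] == 2L) && all(g[unaff, 1] < 2L)) { ok <- TRUE; break }
      }
      if (!ok) stop("conditioning failed after ", max_tries, " tries",
                    call. = FALSE)
      g
    } else if (model == "compound_het") {
      if (length(causal) != 2) stop("compound_het model takes 2 causal keys")
      fa_side <- setdiff(founder_ancestors_of(pedigree, par$father),
                         founder_ancestors_of(pedigree, par$mother))
      mo_side <- setdiff(founder_ancestors_of(pedigree, par$mother),
                         founder_ancestors_of(pedigree, par$father))
      if (!length(fa_side) || !length(mo_side)) {
        stop("conditioning impossible: no paternal-only/maternal-only ",
             "founder to hold each compound-het allele", call. = FALSE)
      }
      fg <- matrix(0L, length(founders), 2,
                   dimnames = list(founders, causal))
      fg[fa_side[1], 1] <- 1L
      fg[mo_side[1], 2] <- 1L
      ok <- FALSE
      for (i in seq_len(max_tries)) {
        g <- gene_drop(pedigree, fg)
        trans_ok <- all(g[aff, 1] == 1L) && all(g[aff, 2] == 1L) &&
          g[par$father, 1] >= 1L && g[par$father, 2] == 0L &&
          g[par$mother, 2] >= 1L && g[par$mother, 1] == 0L
        sib_ok <- !any(g[unaff, 1] >= 1L & g[unaff, 2] >= 1L)
        if (trans_ok && sib_ok) { ok <- TRUE; break }
      }
      if (!ok) stop("conditioning failed after ", max_tries, " tries",
                    call. = FALSE)
      g
    } else {
      stop("unknown causal model: ", model, call. = FALSE)
    }

    if (length(background_af)) {
      J <- length(background_af)
      fg <- matrix(
        stats::rbinom(length(founders) * J, 2L,
                      rep(background_af, each = length(founders))),
        nrow = length(founders),
        dimnames = list(founders, names(background_af)))
      bg <- gene_drop(pedigree, fg)
      if (cfg$geno_missing_rate > 0) {
        miss <- stats::runif(length(bg)) < cfg$geno_missing_rate
        bg[miss] <- NA_integer_
      }
      causal_geno <- cbind(causal_geno, bg)
    }
    structure(causal_geno, causal_keys = causal)
  })
}

#' Simulate a control-cohort genotype table
#'
#' Controls are unrelated individuals drawn under Hardy-Weinberg equilibrium
#' at each variant's population allele frequency. Causal variant keys are
#' forced absent (all hom-ref), emulating an ethnically matched control
#' cohort that does not carry the family's private allele.
#'
#' @param annotations annotated variant table with columns `key`, `exac_af`.
#' @param n_controls number of control individuals.
#' @param causal_keys keys forced hom-ref in every control.
#' @param seed integer seed.
#' @return integer GenotypeTable (controls x variants).
#' @export
simulate_controls <- function(annotations, n_controls, causal_keys = NULL,
                              seed = 1) {
  af <- ifelse(is.na(annotations$exac_af), 0, annotations$exac_af)
  with_seed(seed, {
    g <- matrix(
      stats::rbinom(n_controls * length(af), 2L, rep(af, each = n_controls)),
      nrow = n_controls,
      dimnames = list(sprintf("CTRL%04d", seq_len(n_controls)),
                      annotations$key))
    if (length(causal_keys)) g[, causal_keys] <- 0L
    g
  })
}
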