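# Shared fixtures and independent brute-force oracles used across tests.

make_family_variants_for_test <- function(cfg, family_id, seed) {
  recessid:::make_family_variants(cfg, family_id, seed)
}

# a trio + two extra children: father, mother, affected x2, unaffected sib
trio5_pedigree <- function() {
  ped <- data.frame(
    family_id = "T5",
    id = c("FA", "MO", "A1", "A2", "U1"),
    father = c("0", "0", "FA", "FA", "FA"),
    mother = c("0", "0", "MO", "MO", "MO"),
    sex = c(1L, 2L, 1L, 2L, 1L),
    affected = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# genotype matrix from a named list: list(FA = c(v1 = 1, v2 = 0), ...)
geno_matrix <- function(calls) {
  keys <- names(calls[[1]])
  m <- do.call(rbind, lapply(calls, function(x) as.integer(x[keys])))
  dimnames(m) <- list(names(calls), keys)
  m
}

# independent kinship oracle: common-ancestor path counting,
# phi(a,b) = sum over common ancestors A and disjoint path pairs of
# (1/2)^(n_a + n_b + 1) * (1 + F_A), for outbred ancestors F_A = 0
path_kinship <- function(ped, a, b) {
  paths_up <- function(id) {
    # all ancestor chains from id upward, as vectors of ids (incl. id)
    r <- ped[ped$id == id, ]
    out <- list(id)
    if (r$father != "0") {
      out <- c(out, lapply(paths_up(r$father), function(p) c(id, p)))
    }
    if (r$mother != "0") {
      out <- c(out, lapply(paths_up(r$mother), function(p) c(id, p)))
    }
    out
  }
  pa <- paths_up(a); pb <- paths_up(b)
  total <- 0
  for (p in pa) {
    for (q in pb) {
      anc <- p[length(p)]
      if (anc != q[length(q)]) next
      # paths must meet only at the common ancestor
      if (length(intersect(p[-length(p)], q[-length(q)])) > 0) next
      total <- total + 0.5^(length(p) - 1 + length(q) - 1 + 1)
    }
  }
  total
}

# rule-enumeration oracle for autosomal-recessive segregation on any
# pedigree: direct restatement of the constraints, no shared code with
# check_recessive_segregation()
oracle_segregation_consistent <- function(geno, ped) {
  # geno: named 0/1/2/NA vector over ped$id
  for (id in ped$id) {
    g <- geno[[id]]
    if (is.na(g)) next
    aff <- ped$affected[ped$id == id]
    if (aff && g != 2L) return(FALSE)
    if (!aff && g == 2L) return(FALSE)
  }
  for (id in ped$id[ped$affected]) {
    r <- ped[ped$id == id, ]
    for (par in c(r$father, r$mother)) {
      if (par == "0" || !par %in% ped$id) next
      if (ped$affected[ped$id == par]) next
      gp <- geno[[par]]
      if (!is.na(gp) && gp != 1L) return(FALSE)
    }
  }
  TRUE
}

# brute-force restatement of the seven tiers; returns per-tier survivor
# counts and the final candidate key set
oracle_cascade <- function(fam, controls, min_quality = 30, af_max = 0.01,
                           cadd_min = 20, predictor_majority = 0.5) {
  v <- fam$variants
  g <- fam$genotypes
  ped <- fam$pedigree
  aff <- ped$id[ped$affected]
  unaff <- ped$id[!ped$affected]
  counts <- integer(0)

  # 1 quality: quality >= min AND no missing genotype in any member
  keep <- v$quality >= min_quality &
    !apply(is.na(g[, v$key, drop = FALSE]), 2, any)
  v <- v[keep, ]; counts["quality"] <- nrow(v)
  # 2 consequence
  keep <- v$consequence %in% c("missense", "nonsense", "frameshift",
                               "splice") |
    (v$consequence == "synonymous" & v$splice_predicted)
  v <- v[keep, ]; counts["consequence"] <- nrow(v)
  # 3 frequency
  keep <- !v$in_dbsnp | v$exac_af < af_max
  v <- v[keep, ]; counts["frequency"] <- nrow(v)
  # 4 genotype model
  hom <- apply(g[aff, v$key, drop = FALSE] == 2L, 2, all)
  het <- apply(g[aff, v$key, drop = FALSE] == 1L, 2, all)
  pairs <- list()
  for (gene in unique(v$gene[het])) {
    keys <- v$key[het & v$gene == gene]
    if (length(keys) < 2) next
    for (i in seq_len(length(keys) - 1)) {
      for (j in seq(i + 1, length(keys))) {
        k1 <- keys[i]; k2 <- keys[j]
        ok <- TRUE
        for (id in aff) {
          fa <- ped$father[ped$id == id]; mo <- ped$mother[ped$id == id]
          if (fa %in% rownames(g) && mo %in% rownames(g)) {
            f1 <- g[fa, k1] >= 1; f2 <- g[fa, k2] >= 1
            m1 <- g[mo, k1] >= 1; m2 <- g[mo, k2] >= 1
            trans <- (f1 && !f2 && m2 && !m1) || (f2 && !f1 && m1 && !m2)
            if (!trans) ok <- FALSE
          }
        }
        for (id in unaff) {
          if (g[id, k1] >= 1 && g[id, k2] >= 1) {
            fa <- ped$father[ped$id == id]; mo <- ped$mother[ped$id == id]
            if (fa %in% rownames(g) && mo %in% rownames(g)) {
              f1 <- g[fa, k1] >= 1; f2 <- g[fa, k2] >= 1
              m1 <- g[mo, k1] >= 1; m2 <- g[mo, k2] >= 1
              if ((f1 && !f2 && m2 && !m1) || (f2 && !f1 && m1 && !m2)) {
                ok <- FALSE
              }
            }
          }
        }
        if (ok) pairs[[length(pairs) + 1]] <- c(k1, k2)
      }
    }
  }
  paired <- unique(unlist(pairs))
  keep <- hom | v$key %in% paired
  model <- ifelse(hom, "homozygous", "compound_het")
  v <- v[keep, ]; model <- model[keep]; counts["genotype_model"] <- nrow(v)
  # 5 segregation (hom variants; pairs already validated)
  keep <- vapply(seq_len(nrow(v)), function(i) {
    if (model[i] == "compound_het") return(TRUE)
    oracle_segregation_consistent(
      stats::setNames(g[ped$id, v$key[i]], ped$id), ped)
  }, logical(1))
  v <- v[keep, ]; model <- model[keep]; counts["segregation"] <- nrow(v)
  # 6 controls: no control homozygote; pairs also die on control het-het
  keep <- !apply(controls[, v$key, drop = FALSE] == 2L, 2, any)
  for (p in pairs) {
    if (all(p %in% v$key) &&
        any(controls[, p[1]] == 1L & controls[, p[2]] == 1L)) {
      keep[v$key %in% p] <- FALSE
    }
  }
  v <- v[keep, ]; model <- model[keep]; counts["controls"] <- nrow(v)
  # 7 pathogenicity (missense only) + orphaned pair pruning
  keep <- v$consequence != "missense" |
    (!is.na(v$cadd) & v$cadd > cadd_min &
       v$n_damaging / v$n_predictors > predictor_majority)
  v <- v[keep, ]; model <- model[keep]
  alive_pairs <- Filter(function(p) all(p %in% v$key), pairs)
  paired <- unique(unlist(alive_pairs))
  keep <- model != "compound_het" | v$key %in% paired
  v <- v[keep, ]; counts["pathogenicity"] <- nrow(v)
  list(counts = counts, final_keys = v$key)
}
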