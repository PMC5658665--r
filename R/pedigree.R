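#' recessid: recessive variant prioritization and brain co-expression enrichment
#'
#' Tools for prioritizing recessive intellectual-disability variants in
#' consanguineous families (a seven-tier filtration cascade with pedigree
#' segregation and compound-heterozygote pairing), for classifying variants
#' from HGVS nomenclature and summarizing loss-of-function burden, and for
#' testing co-expression of candidate gene sets in thresholded Pearson
#' correlation networks built per brain region and developmental stage,
#' against a permutation null with Bonferroni correction.
#'
#' @keywords internal
#' @aliases recessid-package
"_PACKAGE"

# ---- pedigree construction -------------------------------------------------

#' Construct a nuclear or consanguineous pedigree
#'
#' Builds a pedigree in the 6-column PED convention (family, individual,
#' father, mother, sex, phenotype; affected coded 2, founders have parent
#' ids "0"). For `consanguinity = "first_cousin"` the parents of the affected
#' sibship are first cousins (they share one grandparental couple, kinship
#' 1/16); for `"double_first_cousin"` they are double first cousins (kinship
#' 1/8); for `"unrelated"` both parents are founders.
#'
#' An unaffected sibling is always included so that segregation is testable.
#'
#' @param consanguinity one of `"first_cousin"`, `"double_first_cousin"`,
#'   `"unrelated"`.
#' @param n_affected number of affected children (>= 1).
#' @param seed integer seed; determines the sexes of the affected children.
#' @param family_id family identifier string.
#' @return a `data.frame` of class `"pedigree"` with columns
#'   `family_id, id, father, mother, sex, affected` (logical).
#' @export
make_pedigree <- function(consanguinity = c("first_cousin",
                                            "double_first_cousin",
                                            "unrelated"),
                          n_affected = 2, seed = 1, family_id = "FAM1") {
  if (!is.character(consanguinity) ||
      !consanguinity[1] %in% c("first_cousin", "double_first_cousin",
                               "unrelated")) {
    stop("unknown consanguinity type: ", paste(consanguinity[1]),
         call. = FALSE)
  }
  consanguinity <- consanguinity[1]
  stopifnot(n_affected >= 1)
  rows <- list()
  add <- function(id, father = "0", mother = "0", sex, affected = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      family_id = family_id, id = id, father = father, mother = mother,
      sex = sex, affected = affected, stringsAsFactors = FALSE)
  }
  if (consanguinity == "first_cousin") {
    # shared grandparental couple GGP1 x GGP2; their two children marry in
    add("GGP1", sex = 1L); add("GGP2", sex = 2L)
    add("U1", "GGP1", "GGP2", sex = 1L); add("U1W", sex = 2L)
    add("U2H", sex = 1L);                add("U2", "GGP1", "GGP2", sex = 2L)
    add("FA", "U1", "U1W", sex = 1L)
    add("MO", "U2H", "U2", sex = 2L)
  } else if (consanguinity == "double_first_cousin") {
    add("A1", sex = 1L); add("A2", sex = 2L)
    add("B1", sex = 1L); add("B2", sex = 2L)
    add("C1", "A1", "A2", sex = 1L); add("D1", "B1", "B2", sex = 2L)
    add("D2", "B1", "B2", sex = 1L); add("C2", "A1", "A2", sex = 2L)
    add("FA", "C1", "D1", sex = 1L)
    add("MO", "D2", "C2", sex = 2L)
  } else {
    add("FA", sex = 1L)
    add("MO", sex = 2L)
  }
  sexes <- with_seed(seed, sample(c(1L, 2L), n_affected + 1L, replace = TRUE))
  for (i in seq_len(n_affected)) {
    add(sprintf("AFF%d", i), "FA", "MO", sex = sexes[i], affected = TRUE)
  }
  add("SIB1", "FA", "MO", sex = sexes[n_affected + 1L], affected = FALSE)
  ped <- do.call(rbind, rows)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @keywords internal
validate_pedigree <- function(ped) {
  stopifnot(all(c("family_id", "id", "father", "mother", "sex",
                  "affected") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids", call. = FALSE)
  for (col in c("father", "mother")) {
    dangling <- ped[[col]] != "0" & !ped[[col]] %in% ped$id
    if (any(dangling)) {
      stop("dangling parent id(s): ",
           paste(unique(ped[[col]][dangling]), collapse = ", "),
           call. = FALSE)
    }
    if (any(ped[[col]] == ped$id)) {
      stop("individual listed as its own parent", call. = FALSE)
    }
  }
  invisible(ped)
}

#' Founders of a pedigree
#' @param ped a pedigree.
#' @return character vector of founder ids (both parents unknown).
#' @export
pedigree_founders <- function(ped) {
  ped$id[ped$father == "0" & ped$mother == "0"]
}

#' Order pedigree members so parents precede children
#' @keywords internal
pedigree_topo_order <- function(ped) {
  placed <- character(0)
  remaining <- ped$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (r$father == "0" || r$father %in% placed) &&
        (r$mother == "0" || r$mother %in% placed)
    }, logical(1))
    if (!any(ready)) stop("pedigree contains a cycle", call. = FALSE)
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

#' Kinship coefficient between two pedigree members
#'
#' Probability that a randomly drawn allele from `a` and one from `b` are
#' identical by descent, computed by the standard recursion
#' phi(a, b) = (phi(father_a, b) + phi(mother_a, b)) / 2 with
#' phi(a, a) = (1 + F_a) / 2. First cousins have kinship 1/16; double first
#' cousins 1/8; unrelated founders 0.
#'
#' @param ped a pedigree.
#' @param a,b individual ids.
#' @return kinship coefficient in `[0, 0.5]` (or above for inbred selves).
#' @export
kinship_coefficient <- function(ped, a, b) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  memo <- new.env(parent = emptyenv())
  is_anc <- function(anc, des) { # is `anc` an ancestor of `des`?
    if (des == "0") return(FALSE)
    r <- ped[idx[[des]], ]
    if (r$father == anc || r$mother == anc) return(TRUE)
    (r$father != "0" && is_anc(anc, r$father)) ||
      (r$mother != "0" && is_anc(anc, r$mother))
  }
  phi <- function(x, y) {
    if (x == "0" || y == "0") return(0)
    key <- paste(sort(c(x, y)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      r <- ped[idx[[x]], ]
      (1 + phi(r$father, r$mother)) / 2
    } else {
      # recurse on the member that is not an ancestor of the other
      if (is_anc(x, y)) {
        r <- ped[idx[[y]], ]
        (phi(x, r$father) + phi(x, r$mother)) / 2
      } else {
        r <- ped[idx[[x]], ]
        (phi(r$father, y) + phi(r$mother, y)) / 2
      }
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Does the pedigree contain a consanguineous union?
#' @param ped a pedigree.
#' @return `TRUE` if any mated pair (parents of a common child) has
#'   kinship > 0.
#' @export
has_consanguineous_loop <- function(ped) {
  kids <- ped[ped$father != "0" & ped$mother != "0", ]
  pairs <- unique(kids[, c("father", "mother")])
  for (i in seq_len(nrow(pairs))) {
    if (kinship_coefficient(ped, pairs$father[i], pairs$mother[i]) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

# ---- PED i/o ---------------------------------------------------------------

#' Read a 6-column PED file
#'
#' Whitespace-delimited PED: family, individual, father, mother, sex,
#' phenotype. Individuals are affected iff phenotype equals 2.
#'
#' @param path file path.
#' @return a pedigree `data.frame` (see [make_pedigree()]).
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6) stop("PED file must have 6 columns", call. = FALSE)
  ped <- data.frame(family_id = raw[[1]], id = raw[[2]], father = raw[[3]],
                    mother = raw[[4]], sex = as.integer(raw[[5]]),
                    affected = raw[[6]] == "2", stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Write a pedigree as a 6-column PED file
#' @param ped a pedigree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(ped$family_id, ped$id, ped$father, ped$mother, ped$sex,
                    ifelse(ped$affected, 2L, 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- seeding helper --------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
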