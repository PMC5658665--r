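# Variant-class calls from HGVS nomenclature and the cohort-level
# arithmetic: class histograms, LOF fractions, family categorization.

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                     "synonymous_splice")

#' Classify a variant from its HGVS strings
#'
#' Rules, in precedence order:
#' \itemize{
#'   \item cDNA change at a +/-1 or +/-2 intronic offset (canonical splice
#'     site, e.g. `c.2520+1G>T`, `c.139-2A>G`) -> `splice`;
#'   \item protein change containing `fs` -> `frameshift`;
#'   \item protein change ending in `*` (stop at a substituted residue,
#'     e.g. `p.(Gln1864*)`) -> `nonsense`;
#'   \item synonymous protein change (same residue, e.g. `p.(Arg744Arg)`)
#'     with a positive splice prediction -> `synonymous_splice`, without
#'     one -> `synonymous`;
#'   \item amino-acid substitution otherwise -> `missense`.
#' }
#'
#' @param hgvs_c cDNA-level HGVS string (`c.` prefix optional).
#' @param hgvs_p protein-level HGVS string, possibly `NA` or `"p.?"`.
#' @param splice_predicted logical: splice effect predicted in silico.
#' @return one of `"missense"`, `"nonsense"`, `"frameshift"`, `"splice"`,
#'   `"synonymous_splice"`, `"synonymous"`.
#' @export
classify_variant <- function(hgvs_c, hgvs_p = NA_character_,
                             splice_predicted = FALSE) {
  if (length(hgvs_c) > 1 || length(hgvs_p) > 1) {
    return(mapply(classify_variant, hgvs_c, hgvs_p,
                  splice_predicted, USE.NAMES = FALSE))
  }
  cstr <- if (is.na(hgvs_c)) "" else sub("^c\\.", "", hgvs_c)
  # canonical +/-1, +/-2 intronic offsets
  off <- regmatches(cstr, regexec("^[0-9]+(_[0-9]+)?([+-])([0-9]+)", cstr))[[1]]
  if (length(off) && as.integer(off[4]) <= 2L) return("splice")
  pstr <- if (is.na(hgvs_p)) "" else hgvs_p
  pstr <- gsub("[()]", "", sub("^p\\.", "", pstr))
  if (grepl("fs", pstr)) return("frameshift")
  if (grepl("\\*$", pstr) && nzchar(pstr)) return("nonsense")
  m <- regmatches(pstr,
                  regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$",
                          pstr))[[1]]
  if (length(m)) {
    if (m[2] == m[4]) {
      return(if (isTRUE(splice_predicted)) "synonymous_splice"
             else "synonymous")
    }
    return("missense")
  }
  stop("cannot classify variant from HGVS: c.=", hgvs_c, " p.=", hgvs_p,
       call. = FALSE)
}

#' Is a variant class predicted loss-of-function?
#'
#' LOF classes are nonsense, frameshift and splice-site variants; a
#' synonymous change with a predicted splice effect counts with the splice
#' class.
#'
#' @param cls character vector of variant classes.
#' @return logical vector.
#' @export
is_lof <- function(cls) {
  cls %in% c("nonsense", "frameshift", "splice", "synonymous_splice")
}

#' Histogram of variant classes
#'
#' Counts records per class, folding `synonymous_splice` into the `splice`
#' class (the printed tables count predicted-splice synonymous changes as
#' aberrant splicing).
#'
#' @param classes character vector of variant classes.
#' @return named integer vector over missense/nonsense/frameshift/splice.
#' @export
class_histogram <- function(classes) {
  folded <- ifelse(classes == "synonymous_splice", "splice", classes)
  counts <- table(factor(folded, levels = c("missense", "nonsense",
                                            "frameshift", "splice")))
  stats::setNames(as.integer(counts), names(counts))
}

#' Categorize families by the genes their segregating variants affect
#'
#' A family is `multi_variant` iff it carries segregating variants in two
#' or more genes; otherwise `known_single` iff its gene is in
#' `known_gene_list`, else `novel_single`. A compound-het pair in one gene
#' counts as one gene (two variants). Families with zero records are
#' excluded and logged.
#'
#' @param records variant data.frame with `family_id` and `gene` columns.
#' @param known_gene_list character vector of previously reported disease
#'   genes.
#' @return list of class `"cohort_summary"`: per category
#'   (`known_single`, `novel_single`, `multi_variant`) the family ids,
#'   family count, variant count, class histogram (when `records` carries a
#'   `class` column), LOF count and fraction, distinct gene count; plus
#'   `families_total` and `family_category` (named vector).
#' @export
categorize_families <- function(records, known_gene_list) {
  stopifnot(all(c("family_id", "gene") %in% names(records)))
  fams <- split(records, records$family_id)
  category <- vapply(fams, function(df) {
    genes <- unique(df$gene)
    if (length(genes) >= 2) "multi_variant"
    else if (genes %in% known_gene_list) "known_single"
    else "novel_single"
  }, character(1))
  per_cat <- lapply(c(known_single = "known_single",
                      novel_single = "novel_single",
                      multi_variant = "multi_variant"), function(cat) {
    ids <- names(category)[category == cat]
    df <- records[records$family_id %in% ids, , drop = FALSE]
    cls <- if ("class" %in% names(df)) df$class else
      classify_variant(df$hgvs_c, df$hgvs_p,
                       isTRUE_vec(df$splice_predicted))
    list(family_ids = ids,
         n_families = length(ids),
         n_variants = nrow(df),
         class_histogram = class_histogram(cls),
         n_lof = sum(is_lof(cls)),
         lof_fraction_variants = if (nrow(df)) sum(is_lof(cls)) / nrow(df)
           else NA_real_,
         n_genes = length(unique(df$gene)))
  })
  structure(c(per_cat,
              list(families_total = length(fams),
                   family_category = category)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (cat in c("known_single", "novel_single", "multi_variant")) {
    cat(sprintf("%-13s %3d families, %3d variants, %2d LOF\n", cat,
                x[[cat]]$n_families, x[[cat]]$n_variants, x[[cat]]$n_lof))
  }
  cat("families_total", x$families_total, "\n")
  invisible(x)
}

#' Loss-of-function fraction of a record set
#'
#' @param records variant data.frame carrying `class` (or HGVS columns from
#'   which the class is derived) and `family_id`.
#' @param denominator `"variants"` (LOF variants / all variants) or
#'   `"families"` (families carrying a LOF variant / all families).
#' @return list with `numerator`, `denominator`, `fraction`, `percent`.
#' @export
lof_fraction <- function(records, denominator = c("variants", "families")) {
  denominator <- match.arg(denominator)
  cls <- if ("class" %in% names(records)) records$class else
    classify_variant(records$hgvs_c, records$hgvs_p,
                     isTRUE_vec(records$splice_predicted))
  lof <- is_lof(cls)
  if (denominator == "variants") {
    den <- nrow(records); num <- sum(lof)
  } else {
    den <- length(unique(records$family_id))
    num <- length(unique(records$family_id[lof]))
  }
  if (den == 0) {
    return(list(numerator = 0L, denominator = 0L, fraction = NA_real_,
                percent = NA_real_, status = "undefined"))
  }
  list(numerator = num, denominator = den, fraction = num / den,
       percent = 100 * num / den, status = "ok")
}

#' Deterministic score aggregates over a record set
#'
#' @param records classified variant data.frame with `cadd`, `exac_af`,
#'   `gene`, `family_id` columns.
#' @return list with `min_cadd_missense`, `max_exac_af`,
#'   `class_histogram`, `n_distinct_genes`, `n_distinct_families`,
#'   `n_missing_cadd`, `n_missing_af`.
#' @export
summarize_scores <- function(records) {
  cls <- if ("class" %in% names(records)) records$class else
    classify_variant(records$hgvs_c, records$hgvs_p,
                     isTRUE_vec(records$splice_predicted))
  mis_cadd <- records$cadd[cls == "missense" & !is.na(records$cadd)]
  af <- records$exac_af[!is.na(records$exac_af)]
  list(min_cadd_missense = if (length(mis_cadd)) min(mis_cadd) else NA_real_,
       max_exac_af = if (length(af)) max(af) else NA_real_,
       class_histogram = class_histogram(cls),
       n_distinct_genes = length(unique(records$gene)),
       n_distinct_families = length(unique(records$family_id)),
       n_missing_cadd = sum(is.na(records$cadd)),
       n_missing_af = sum(is.na(records$exac_af)))
}
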