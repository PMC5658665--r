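# Standard-format i/o: multi-sample GT-only VCF v4.2 (read via vcfR, write
# via a minimal text writer), 6-column PED (pedigree.R), annotation TSVs,
# and the packaged fixture tables transcribed from the published variant
# lists, guarded by an MD5 manifest.

#' Read a multi-sample VCF into variant records and a genotype table
#'
#' Multi-allelic sites are split into one record per alt allele; the
#' genotype of a sample for alt allele k is the count of allele k in its
#' GT call (0 = hom_ref, 1 = het, 2 = hom_alt, NA = missing). Positions
#' stay 1-based per the VCF convention.
#'
#' @param path VCF path (v4.2, GT in FORMAT, diploid calls).
#' @return list with `variants` (data.frame: `key`, `chrom`, `pos`, `ref`,
#'   `alt`, `qual`) and `genotypes` (integer matrix samples x keys).
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field", call. = FALSE)
  samples <- colnames(gt_raw)
  recs <- list(); geno_cols <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    calls <- gt_raw[i, ]
    calls[is.na(calls)] <- "./."
    alleles <- strsplit(calls, "[/|]")
    bad <- !vapply(alleles, function(a)
      length(a) == 2L || all(a == "."), logical(1))
    if (any(bad)) {
      stop(sprintf("ploidy != 2 at record %d (%s:%s), sample %s", i,
                   fix[i, "CHROM"], fix[i, "POS"],
                   samples[which(bad)[1]]), call. = FALSE)
    }
    for (k in seq_along(alts)) {
      key <- paste0(fix[i, "CHROM"], ":", fix[i, "POS"], fix[i, "REF"],
                    ">", alts[k])
      recs[[length(recs) + 1]] <- data.frame(
        key = key, chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        stringsAsFactors = FALSE)
      geno_cols[[length(geno_cols) + 1]] <- vapply(alleles, function(a) {
        if (any(a == ".")) NA_integer_ else sum(a == as.character(k))
      }, integer(1))
    }
  }
  variants <- do.call(rbind, recs)
  genotypes <- do.call(cbind, geno_cols)
  dimnames(genotypes) <- list(samples, variants$key)
  list(variants = variants, genotypes = genotypes)
}

#' Write variant records and genotypes as a GT-only VCF v4.2
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `qual`.
#' @param genotypes integer GenotypeTable (samples x variants, same order
#'   as `variants`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  gt_str <- function(g) {
    out <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(g)]
    out[is.na(g)] <- "./."
    unname(out)
  }
  samples <- rownames(genotypes)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  qual <- if ("qual" %in% names(variants)) {
    ifelse(is.na(variants$qual), ".", format(variants$qual))
  } else "."
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], qual[i], "PASS", ".", "GT",
            gt_str(genotypes[, i])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read an annotation TSV
#'
#' Round-trip safe serialization of an annotated variant table.
#' @param annotations annotated variant data.frame.
#' @param path TSV path.
#' @return `path` (write) / the data.frame (read).
#' @export
write_annotation_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# ---- packaged fixture tables ----------------------------------------------

fixture_file <- function(name) {
  system.file("extdata", name, package = "recessid", mustWork = TRUE)
}

#' Verify the MD5 manifest of the packaged fixture tables
#'
#' @param files fixture file names to check (default: all in the manifest).
#' @return invisibly `TRUE`; stops with a corruption diagnostic otherwise.
#' @export
verify_fixture_manifest <- function(files = NULL) {
  man <- utils::read.delim(fixture_file("manifest_md5.tsv"),
                           stringsAsFactors = FALSE)
  if (!is.null(files)) man <- man[man$file %in% files, , drop = FALSE]
  for (i in seq_len(nrow(man))) {
    got <- unname(tools::md5sum(fixture_file(man$file[i])))
    if (!identical(got, man$md5[i])) {
      stop("fixture corruption: ", man$file[i], " has MD5 ", got,
           ", manifest expects ", man$md5[i], call. = FALSE)
    }
  }
  invisible(TRUE)
}

FIXTURE_TABLES <- c(T1 = "table1.tsv", T2 = "table2.tsv",
                    T3a = "table3a.tsv", T3b = "table3b.tsv")

#' Load a packaged variant table fixture
#'
#' The four packaged TSVs transcribe the published variant tables: T1
#' (homozygous variants in known disease genes, 30 records), T2 (novel
#' candidate genes, 31 records over 30 families; one family contributes a
#' compound-het pair), T3a (multiple known genes in one family, 4 records)
#' and T3b (multiple novel genes in one family, 15 records). The printed
#' ExAC allele-frequency column is in units of 1e-6 and is converted to a
#' fraction on load; a printed CADD of "NA" (truncating classes) loads as
#' `NA`. Each record is classified from its HGVS strings and the splice
#' prediction implied by a synonymous change printed as aberrant splicing.
#'
#' @param table_id one of `"T1"`, `"T2"`, `"T3a"`, `"T3b"`.
#' @param verify check the file against the MD5 manifest first.
#' @return data.frame of variant records: `family_id`, `gene`, `chrom`,
#'   `pos`, `transcript`, `hgvs_c`, `hgvs_p`, `variation` (printed class),
#'   `cadd`, `exac_af`, `omim`, `splice_predicted`, `class`, `table`.
#' @export
load_paper_fixture <- function(table_id = c("T1", "T2", "T3a", "T3b"),
                               verify = TRUE) {
  table_id <- match.arg(table_id)
  fname <- FIXTURE_TABLES[[table_id]]
  if (verify) verify_fixture_manifest(fname)
  raw <- utils::read.delim(fixture_file(fname), stringsAsFactors = FALSE,
                           na.strings = "NA")
  pos_m <- regmatches(raw$position,
                      regexec("^[Cc]hr([0-9XY]+):([0-9]+)", raw$position))
  chrom <- vapply(pos_m, function(m) paste0("chr", m[2]), character(1))
  pos <- vapply(pos_m, function(m) as.integer(m[3]), integer(1))
  pstr <- gsub("[()]", "", sub("^p\\.", "", ifelse(is.na(raw$hgvs_p), "",
                                                   raw$hgvs_p)))
  synonymous <- grepl("^([A-Z][a-z]{2})([0-9]+)\\1$", pstr)
  splice_predicted <- synonymous &
    grepl("splic", raw$variation, ignore.case = TRUE)
  out <- data.frame(
    family_id = raw$family, gene = raw$gene, chrom = chrom, pos = pos,
    transcript = raw$transcript, hgvs_c = raw$hgvs_c, hgvs_p = raw$hgvs_p,
    variation = raw$variation, cadd = as.numeric(raw$cadd),
    exac_af = as.numeric(raw$exac_af_e6) / 1e6,
    omim = if ("omim" %in% names(raw)) raw$omim else NA,
    splice_predicted = splice_predicted, table = table_id,
    stringsAsFactors = FALSE)
  out$class <- classify_variant(out$hgvs_c, out$hgvs_p,
                                out$splice_predicted)
  out
}

#' Load all four fixture tables as one record set
#' @param verify check the MD5 manifest first.
#' @return row-bound data.frame of [load_paper_fixture()] outputs.
#' @export
load_all_fixtures <- function(verify = TRUE) {
  do.call(rbind, lapply(names(FIXTURE_TABLES), load_paper_fixture,
                        verify = verify))
}

#' Load the packaged list of previously reported disease genes
#'
#' The genes of the known-gene tables (T1 and T3a), shipped as data so the
#' "previously reported" universe stays user-replaceable.
#'
#' @param verify check the MD5 manifest first.
#' @return character vector of gene symbols.
#' @export
load_known_genes <- function(verify = TRUE) {
  if (verify) verify_fixture_manifest("known_genes.txt")
  readLines(fixture_file("known_genes.txt"))
}
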