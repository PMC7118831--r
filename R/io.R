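#' Read a genotype matrix from VCF or delimited text
#'
#' Produces an n subjects x K variants matrix of minor-allele counts (or
#' dosages). For VCF input the GT field is counted (DS is used when GT is
#' absent); only biallelic records are kept, others are skipped with a
#' warning. Counts are always oriented to the in-sample minor allele: when
#' the alternate-allele frequency exceeds 0.5 the column is flipped
#' (counts become 2 - counts) and a message is logged. Missing genotypes
#' are mean-imputed per variant; variants that are monomorphic after
#' import are dropped with a warning.
#'
#' The matrix format is tab- or whitespace-delimited text with a header row
#' of variant ids and a first column of subject ids; variant ids of the
#' form `chrom:pos` let the variants be placed on the genome for region
#' assignment.
#'
#' @param path file path.
#' @param format `"vcf"` or `"matrix"`; default guesses from the file
#'   extension (`.vcf` / `.vcf.gz` means VCF).
#' @return numeric matrix with subject ids as rownames and variant ids as
#'   colnames, plus attributes `"chrom"` and `"pos"` (1-based, NA when
#'   unknown) aligned with the columns.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  }
  if (!file.exists(path)) af_error(sprintf("file not found: %s", path), "afset_io")
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_matrix(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  if (nrow(fx) == 0L) af_error("VCF contains no variant records", "afset_io")
  biallelic <- !grepl(",", fx[, "ALT"]) & fx[, "ALT"] != "." & !is.na(fx[, "ALT"])
  if (any(!biallelic)) {
    af_warn(sprintf("skipping %d non-biallelic record(s)", sum(!biallelic)),
            "afset_multiallelic_skipped")
  }
  if (ncol(v@gt) < 2L) af_error("VCF has no sample columns", "afset_io")
  has_gt <- any(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))
  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- matrix(vapply(gsub("\\|", "/", gt), function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(x, "/", fixed = TRUE)[[1]]) > 0)
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  } else {
    ds <- vcfR::extract.gt(v, element = "DS")
    if (all(is.na(ds))) af_error("VCF has neither GT nor DS genotype fields", "afset_io")
    cnt <- apply(ds, c(1, 2), as.numeric)
  }
  cnt <- cnt[biallelic, , drop = FALSE]
  fx <- fx[biallelic, , drop = FALSE]
  ids <- ifelse(is.na(fx[, "ID"]) | fx[, "ID"] == ".",
                paste0(fx[, "CHROM"], ":", fx[, "POS"]), fx[, "ID"])
  G <- t(cnt)                                  # subjects x variants
  colnames(G) <- ids
  finish_genotypes(G, chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]))
}

read_genotypes_matrix <- function(path) {
  df <- tryCatch(utils::read.table(path, header = TRUE, check.names = FALSE,
                                   row.names = 1),
                 error = function(e) af_error(
                   sprintf("malformed matrix file %s: %s", path, conditionMessage(e)),
                   "afset_io"))
  G <- as.matrix(df)
  if (!is.numeric(G)) af_error("matrix file must be numeric after the id column", "afset_io")
  cp <- parse_variant_positions(colnames(G))
  finish_genotypes(G, chrom = cp$chrom, pos = cp$pos)
}

# shared post-processing: minor-allele orientation, mean imputation,
# monomorphic drop; keeps chrom/pos attributes aligned with columns
finish_genotypes <- function(G, chrom, pos) {
  all_na <- colSums(!is.na(G)) == 0L
  if (any(all_na)) {
    af_warn(sprintf("dropping %d all-missing variant(s)", sum(all_na)),
            "afset_all_missing_dropped")
    G <- G[, !all_na, drop = FALSE]
    chrom <- chrom[!all_na]; pos <- pos[!all_na]
  }
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0L)) {
      G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  af <- colMeans(G) / 2
  flip <- af > 0.5
  if (any(flip)) {
    message(sprintf("flipping %d variant(s) to minor-allele orientation: %s",
                    sum(flip), paste(colnames(G)[flip], collapse = ", ")))
    G[, flip] <- 2 - G[, flip, drop = FALSE]
  }
  keep <- apply(G, 2, stats::var) > 0
  if (any(!keep)) {
    af_warn(sprintf("dropping %d monomorphic variant(s)", sum(!keep)),
            "afset_monomorphic_dropped")
    G <- G[, keep, drop = FALSE]
    chrom <- chrom[keep]; pos <- pos[keep]
  }
  attr(G, "chrom") <- as.character(chrom)
  attr(G, "pos") <- as.integer(pos)
  G
}

parse_variant_positions <- function(ids) {
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+)", ids))
  chrom <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_, character(1))
  pos <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3]) else NA_integer_, integer(1))
  list(chrom = chrom, pos = pos)
}

#' Write a genotype matrix in the delimited text format
#'
#' Inverse of [read_genotypes()] with `format = "matrix"`: header row of
#' variant ids, first column of subject ids, tab-separated.
#'
#' @param G genotype matrix with dimnames.
#' @param path output file.
#' @export
write_genotype_matrix <- function(G, path) {
  df <- data.frame(subject = rownames(G), as.data.frame(unclass(G)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene regions from a BED file
#'
#' BED intervals are 0-based half-open; a flank is added on both sides
#' (clipped at zero). Columns used: chrom, start, end and the name column
#' (4th; generated names are supplied when absent).
#'
#' @param path BED file path.
#' @param flank bases added upstream and downstream (default 5000).
#' @return data frame with `gene_id`, `chrom`, `start`, `end` (original
#'   0-based half-open coordinates) and `eff_start`, `eff_end` (flanked,
#'   still 0-based half-open).
#' @export
read_regions <- function(path, flank = 5000L) {
  if (flank < 0) af_error("flank must be >= 0", "afset_domain")
  df <- tryCatch(utils::read.table(path, header = FALSE, sep = "\t",
                                   stringsAsFactors = FALSE, fill = TRUE),
                 error = function(e) af_error(
                   sprintf("malformed BED file %s: %s", path, conditionMessage(e)),
                   "afset_io"))
  if (ncol(df) < 3L) af_error("BED file needs at least chrom, start, end columns", "afset_io")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    af_error("BED start/end columns must be integer", "afset_io")
  }
  if (any(df$start > df$end)) af_error("BED interval with start > end", "afset_io")
  gene_id <- if (ncol(df) >= 4L) as.character(df[[4]]) else sprintf("region%03d", seq_len(nrow(df)))
  data.frame(gene_id = gene_id, chrom = as.character(df$chrom),
             start = as.integer(df$start), end = as.integer(df$end),
             eff_start = pmax(0L, as.integer(df$start) - as.integer(flank)),
             eff_end = as.integer(df$end) + as.integer(flank),
             stringsAsFactors = FALSE)
}

#' Assign variants to (possibly overlapping) gene regions
#'
#' A variant belongs to a region when its position falls inside the flanked
#' interval; a variant inside two overlapping regions appears in both sets.
#' VCF positions are 1-based, BED intervals 0-based half-open, so variant
#' position p (1-based) is in \[start, end) iff start < p <= end.
#'
#' @param G genotype matrix from [read_genotypes()] (carries `"chrom"` and
#'   `"pos"` attributes).
#' @param regions data frame from [read_regions()].
#' @return named list of column-index vectors into `G`, one per region
#'   (regions with no variants are dropped with a message).
#' @export
assign_variants <- function(G, regions) {
  chrom <- attr(G, "chrom"); pos <- attr(G, "pos")
  if (is.null(chrom) || all(is.na(pos))) {
    af_error("genotype matrix has no variant positions; cannot assign regions",
             "afset_io")
  }
  sets <- lapply(seq_len(nrow(regions)), function(i) {
    which(chrom == regions$chrom[i] &
            !is.na(pos) &
            pos > regions$eff_start[i] &
            pos <= regions$eff_end[i])
  })
  names(sets) <- regions$gene_id
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    message(sprintf("%d region(s) contain no variants and are skipped: %s",
                    sum(empty), paste(names(sets)[empty], collapse = ", ")))
  }
  sets[!empty]
}

#' Read a phenotype or covariate table keyed by subject id
#'
#' Delimited text with a header; first column subject id, remaining
#' columns numeric.
#'
#' @param path file path.
#' @return data frame with subject ids as rownames.
#' @export
read_subject_table <- function(path) {
  df <- tryCatch(utils::read.table(path, header = TRUE, check.names = FALSE,
                                   row.names = 1, stringsAsFactors = FALSE),
                 error = function(e) af_error(
                   sprintf("malformed subject table %s: %s", path, conditionMessage(e)),
                   "afset_io"))
  if (!all(vapply(df, is.numeric, logical(1)))) {
    af_error(sprintf("non-numeric column in %s", path), "afset_io")
  }
  df
}

# align genotype/phenotype/covariate inputs by subject id (never row order)
align_subjects <- function(G, pheno, covar = NULL) {
  gid <- rownames(G)
  if (is.null(gid)) af_error("genotype matrix lacks subject ids", "afset_io")
  missing_ph <- setdiff(gid, rownames(pheno))
  if (length(missing_ph) > 0L) {
    af_error(sprintf("subjects missing from phenotype file: %s",
                     paste(utils::head(missing_ph, 5), collapse = ", ")),
             "afset_alignment")
  }
  out <- list(Y = pheno[gid, 1], C = NULL)
  if (!is.null(covar)) {
    missing_cv <- setdiff(gid, rownames(covar))
    if (length(missing_cv) > 0L) {
      af_error(sprintf("subjects missing from covariate file: %s",
                       paste(utils::head(missing_cv, 5), collapse = ", ")),
               "afset_alignment")
    }
    out$C <- as.matrix(covar[gid, , drop = FALSE])
  }
  out
}
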