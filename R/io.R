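## Readers and writers for the standard formats: VCF (via vcfR), PLINK .raw,
## delimited dosage matrices, phenotype tables, and result serialization.

#' Read a genotype dosage matrix
#'
#' Supported formats: biallelic VCF (GT field, parsed with vcfR;
#' multiallelic sites skipped with a warning), PLINK `.raw` additive coding
#' (allele suffix stripped from the header into SNP ids), and a delimited
#' numeric matrix with a header row of SNP ids (an optional leading
#' non-numeric column is taken as subject ids).  Missing genotypes are
#' imputed to the column's rounded mean dosage; SNPs whose missingness
#' exceeds `max_missing` are dropped.  Both actions are reported.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"vcf"`, `"plink_raw"`, `"tsv"`; `"auto"`
#'   keys on the file extension.
#' @param max_missing per-SNP missingness threshold above which the SNP is
#'   dropped (default 0.05).
#' @return a [genotype_matrix()] (subject ids, when present, as row names of
#'   `dosages`).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink_raw", "tsv"),
                           max_missing = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else if (grepl("\\.raw$", path, ignore.case = TRUE)) "plink_raw"
              else "tsv"
  }
  raw <- switch(format,
                vcf = .read_vcf_dosages(path),
                plink_raw = .read_plink_raw(path),
                tsv = .read_tsv_dosages(path))
  .finalize_dosages(raw$dosages, raw$ids, max_missing)
}

.finalize_dosages <- function(D, subject_ids, max_missing) {
  miss_frac <- colMeans(is.na(D))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    warning(sprintf("dropping %d SNP(s) with missingness > %g: %s",
                    sum(drop), max_missing,
                    paste(colnames(D)[drop], collapse = ", ")))
    D <- D[, !drop, drop = FALSE]
    miss_frac <- miss_frac[!drop]
  }
  n_imputed <- sum(is.na(D))
  if (n_imputed > 0) {
    message(n_imputed, " missing genotype(s) imputed to rounded column mean")
    for (m in which(miss_frac > 0)) {
      fill <- round(mean(D[, m], na.rm = TRUE))
      D[is.na(D[, m]), m] <- fill
    }
  }
  storage.mode(D) <- "integer"
  if (!is.null(subject_ids)) rownames(D) <- subject_ids
  genotype_matrix(D)
}

.read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning("skipping ", sum(!bi), " multiallelic VCF site(s)")
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles in GT strings like 0/1, 1|1, ./.
  count_alt <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(x) {
      if (any(x == "." | is.na(x))) NA_real_ else sum(x == "1")
    }, numeric(1))
  }
  D <- apply(gt, 2L, count_alt)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  D <- t(D)                       # subjects x SNPs
  ids <- unname(vcfR::getID(v))
  ids[is.na(ids)] <- paste0("snp", which(is.na(ids)))
  colnames(D) <- ids
  list(dosages = D, ids = rownames(D))
}

.read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    colnames(tab))
  snp_cols <- setdiff(colnames(tab), meta)
  D <- as.matrix(tab[, snp_cols, drop = FALSE])
  colnames(D) <- sub("_[ACGT0-9]+$", "", snp_cols)   # strip counted-allele suffix
  ids <- if ("IID" %in% meta) as.character(tab$IID) else NULL
  list(dosages = D, ids = ids)
}

.read_tsv_dosages <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- NULL
  if (ncol(tab) && !is.numeric(tab[[1L]])) {
    ids <- as.character(tab[[1L]])
    tab <- tab[, -1L, drop = FALSE]
  }
  bad <- !vapply(tab, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric dosage column(s): ", paste(colnames(tab)[bad], collapse = ", "))
  }
  list(dosages = as.matrix(tab), ids = ids)
}

#' Read an ordinal phenotype and covariates from a delimited table
#'
#' @param path delimited file with named columns.
#' @param pheno_col name of the phenotype column.
#' @param level_order ordered category labels, lowest first; every observed
#'   phenotype value must appear (see [remap_ordinal()]).
#' @param covar_cols character vector of covariate column names (may be
#'   empty).
#' @param id_col optional subject id column name.
#' @return list with integer `phenotype` (0..J-1), `covariates` matrix,
#'   `subject_ids` (or NULL), and `n_dropped` rows removed for missingness.
#' @export
read_phenotype_covariates <- function(path, pheno_col, level_order,
                                      covar_cols = character(0),
                                      id_col = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(pheno_col, covar_cols, id_col)
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols)) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(tab[, c(pheno_col, covar_cols), drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) dropped for missing phenotype/covariates")
  }
  tab <- tab[keep, , drop = FALSE]
  y <- remap_ordinal(tab[[pheno_col]], level_order)
  if (length(unique(y)) < 2L) {
    stop("degenerate phenotype: all subjects in one category")
  }
  covars <- if (length(covar_cols)) {
    as.matrix(tab[, covar_cols, drop = FALSE])
  } else NULL
  list(phenotype = y, covariates = covars,
       subject_ids = if (!is.null(id_col)) as.character(tab[[id_col]]) else NULL,
       n_dropped = n_dropped)
}

#' Write simulated data as delimited tables
#'
#' Genotypes go to `<prefix>_geno.tsv` (subject id + one column per SNP);
#' phenotype and covariates to `<prefix>_pheno.tsv`.
#'
#' @param dataset a [sim_dataset()] result.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_sim_tsv <- function(dataset, prefix) {
  Gd <- .dosage_matrix(dataset$genotypes)
  ids <- paste0("id", seq_len(nrow(Gd)))
  gpath <- paste0(prefix, "_geno.tsv")
  ppath <- paste0(prefix, "_pheno.tsv")
  utils::write.table(data.frame(subject = ids, Gd, check.names = FALSE),
                     gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(subject = ids, phenotype = dataset$y,
                                dataset$X, check.names = FALSE),
                     ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gpath, ppath))
}

#' Write a genotype matrix as a minimal biallelic VCF
#'
#' One pseudo-site per SNP (chromosome 1, consecutive positions, REF=A,
#' ALT=C), GT encoded from the dosage (0 -> 0/0, 1 -> 0/1, 2 -> 1/1).
#' Intended for round-trip testing of [read_genotypes()].
#'
#' @param G `genotype_matrix` or dosage matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genotypes_vcf <- function(G, path) {
  Gd <- .dosage_matrix(G)
  n <- nrow(Gd); M <- ncol(Gd)
  ids <- rownames(Gd)
  if (is.null(ids)) ids <- paste0("id", seq_len(n))
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (m in seq_len(M)) {
    writeLines(paste(c("1", m, colnames(Gd)[m], "A", "C", ".", "PASS", ".",
                       "GT", gt[Gd[, m] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Serialize test results to TSV or JSON
#'
#' TSV has the fixed header `set, n, M_used, M_dropped, T, T_star, xi, p,
#' method`; JSON additionally carries the eigenvalue spectrum summary and the
#' package version.  An empty result list yields a header-only TSV.
#'
#' @param results a `pomskat_result` or list of them.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "pomskat_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(set = r$set, n = r$n, M_used = r$M_used,
               M_dropped = r$M_dropped, T = r$statistic_T, T_star = r$T_star,
               xi = r$spectrum$xi, p = r$p_value, method = r$method)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), n = integer(0), M_used = integer(0),
               M_dropped = integer(0), T = numeric(0), T_star = numeric(0),
               xi = numeric(0), p = numeric(0), method = character(0))
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(
      version = as.character(utils::packageVersion("pomskat")),
      results = lapply(results, function(r) {
        list(set = r$set, n = r$n, M_used = r$M_used, M_dropped = r$M_dropped,
             T = r$statistic_T, T_star = r$T_star, xi = r$spectrum$xi,
             p = r$p_value, method = r$method,
             lambdas = r$spectrum$lambdas,
             ET = r$spectrum$ET, VarT = r$spectrum$VarT)
      }))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
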