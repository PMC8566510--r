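#' Read a GCT v1.2 expression file
#'
#' GCT is the two-header-line tab-delimited matrix format GTEx distributes
#' count data in: line 1 is the version tag (`#1.2`), line 2 declares
#' `n_genes<TAB>n_samples`, line 3 is `Name<TAB>Description<TAB>` followed by
#' sample ids. Gzip input is read transparently. Ensembl-style version
#' suffixes (".N") are stripped from gene ids at read time; the original ids
#' are kept in the `original_ids` attribute. Two ids that collide after
#' stripping are an error, never a merge.
#'
#' @param path file path (optionally `.gz`).
#' @param units units tag to stamp on the result (GTEx count files are
#'   `"raw_counts"`, the default).
#' @return an [expression_matrix()] with the Description column preserved.
#' @export
read_gct <- function(path, units = "raw_counts") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  version <- readLines(con, n = 1L)
  if (!grepl("^#1\\.2", version))
    stop("not a GCT v1.2 file (first line must be the version tag '#1.2'): ",
         path)
  dims <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop("GCT format error: second line must declare 'n_genes<TAB>n_samples'")
  n_genes <- as.integer(dims[1]); n_samples <- as.integer(dims[2])
  tab <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != n_samples + 2L)
    stop(sprintf("GCT format error: header declares %d samples but body has %d",
                 n_samples, ncol(tab) - 2L))
  if (nrow(tab) != n_genes)
    stop(sprintf("GCT format error: header declares %d genes but body has %d",
                 n_genes, nrow(tab)))
  raw_ids <- as.character(tab[[1]])
  ids <- strip_gene_version(raw_ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene ids after version stripping: ",
         paste(dup, collapse = ", "))
  }
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  em <- expression_matrix(values, units = units,
                          description = as.character(tab[[2]]))
  attr(em, "original_ids") <- stats::setNames(raw_ids, ids)
  em
}

#' Write a GCT v1.2 expression file
#'
#' Inverse of [read_gct()]: numeric content round-trips exactly for values
#' representable at the written precision (written with `format(..., digits =
#' 17)`, so doubles survive bit-exactly).
#'
#' @param x an [expression_matrix()].
#' @param path output path; a `.gz` suffix gzips the output.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  desc <- x$description
  if (is.null(desc)) desc <- rep("", nrow(x$values))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x$values), ncol(x$values), sep = "\t")), con)
  tab <- data.frame(Name = rownames(x$values), Description = desc,
                    check.names = FALSE, stringsAsFactors = FALSE)
  num <- as.data.frame(apply(x$values, 2, format, digits = 17, trim = TRUE,
                             scientific = FALSE, simplify = FALSE),
                       check.names = FALSE)
  utils::write.table(cbind(tab, num), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: drop Ensembl ".N" version suffixes
strip_gene_version <- function(ids) sub("\\.\\d+$", "", ids)

# canonical sample-table fields; those marked TRUE are mandatory
SAMPLE_FIELDS <- c(sample_id = TRUE, subject_id = FALSE, tissue = TRUE,
                   age = FALSE, sex = FALSE, ischemic_time = FALSE,
                   hardy_scale = FALSE, batch = FALSE, bmi = FALSE,
                   disease = FALSE)

#' Read a sample annotation table
#'
#' Parses a tab-delimited annotation file (mirroring the GTEx sample/subject
#' attribute files) into the canonical per-sample covariate table used by the
#' models: sample id, subject id, tissue code, age (years), sex, ischemic
#' time (minutes, SMTSISCH), Hardy scale (ordinal 0-4, DTHHRDY), experimental
#' batch (SMGEBTCH), BMI and disease label. A `schema` maps file columns onto
#' canonical fields so arbitrary header spellings can be ingested. Rows with
#' missing mandatory fields are flagged in the `flagged` attribute, never
#' silently dropped. Missing categorical covariates become an explicit
#' `"(missing)"` level; missing numeric covariates stay `NA` and exclude the
#' sample only from models that need the field.
#'
#' @param path TSV file with a header row (optionally gzipped).
#' @param schema named character vector mapping canonical field names to file
#'   column names, e.g. `c(sample_id = "SAMPID", tissue = "SMTSD")`. Fields
#'   `sample_id` and `tissue` are mandatory.
#' @param sex_codes named character vector recoding the sex column, e.g.
#'   `c("1" = "M", "2" = "F")`; values already `M`/`F` pass through.
#' @return a `data.frame` with the canonical columns present in `schema`;
#'   attribute `flagged` holds row indices with missing mandatory fields.
#' @export
read_sample_table <- function(path, schema, sex_codes = c("1" = "M", "2" = "F")) {
  if (!file.exists(path)) stop("file not found: ", path)
  unknown <- setdiff(names(schema), names(SAMPLE_FIELDS))
  if (length(unknown))
    stop("unknown canonical fields in schema: ", paste(unknown, collapse = ", "))
  need <- names(SAMPLE_FIELDS)[SAMPLE_FIELDS]
  if (!all(need %in% names(schema)))
    stop("schema must map mandatory fields: ",
         paste(setdiff(need, names(schema)), collapse = ", "))
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema), names(tab))
  if (length(missing_cols))
    stop("schema error: column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  out <- as.data.frame(lapply(stats::setNames(nm = names(schema)),
                              function(field) tab[[schema[[field]]]]),
                       stringsAsFactors = FALSE)
  out$sample_id <- as.character(out$sample_id)
  out$tissue <- as.character(out$tissue)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  for (num in intersect(c("age", "ischemic_time", "bmi"), names(out)))
    out[[num]] <- suppressWarnings(as.numeric(out[[num]]))
  if ("age" %in% names(out) && any(!is.na(out$age) & out$age <= 0))
    stop("age must be > 0 where present")
  if ("sex" %in% names(out)) {
    sx <- as.character(out$sex)
    hit <- sx %in% names(sex_codes)
    sx[hit] <- sex_codes[sx[hit]]
    bad <- !is.na(sx) & !sx %in% c("M", "F")
    if (any(bad))
      stop("unrecognized sex codes: ", paste(unique(sx[bad]), collapse = ", "))
    out$sex <- factor(sx, levels = c("M", "F"))
  }
  if ("hardy_scale" %in% names(out)) {
    h <- as.character(out$hardy_scale)
    h[is.na(h) | h == ""] <- "(missing)"
    bad <- !h %in% c(as.character(0:4), "(missing)")
    if (any(bad))
      stop("Hardy scale must be 0-4: ", paste(unique(h[bad]), collapse = ", "))
    out$hardy_scale <- factor(h, levels = c(as.character(0:4), "(missing)"))
  }
  if ("batch" %in% names(out)) {
    b <- as.character(out$batch)
    b[is.na(b) | b == ""] <- "(missing)"
    out$batch <- factor(b)
  }
  if ("disease" %in% names(out)) {
    d <- as.character(out$disease)
    d[is.na(d) | d == ""] <- "none"
    ok <- c("normal", "ventilator_injury", "ALI", "IPF", "cancer", "none")
    if (any(!d %in% ok))
      stop("unknown disease labels: ",
           paste(setdiff(unique(d), ok), collapse = ", "))
    out$disease <- factor(d, levels = ok)
  }
  flagged <- which(is.na(out$sample_id) | out$sample_id == "" |
                     is.na(out$tissue) | out$tissue == "")
  attr(out, "flagged") <- flagged
  out
}

MATRISOME_CATEGORIES <- c("collagens", "proteoglycans", "ECM_glycoproteins",
                          "ECM_regulators", "ECM_affiliated", "secreted_factors")
CORE_CATEGORIES <- c("collagens", "proteoglycans", "ECM_glycoproteins")

#' Read a matrisome gene catalog
#'
#' The matrisome catalog maps each ECM / ECM-associated gene to a division
#' (`core` or `associated`) and one of six categories: the core matrisome
#' holds collagens, proteoglycans and ECM glycoproteins; the associated
#' division holds ECM regulators, ECM-affiliated proteins and secreted
#' factors. The analyses in this package run on the union of the core
#' matrisome and the ECM regulators (see [core_plus_regulators()]).
#'
#' @param path TSV with columns `gene`, `division`, `category` (optionally
#'   gzipped). Consistent duplicate rows collapse; conflicting ones error.
#' @return a `matrisome_catalog`: data.frame with columns `gene_id`,
#'   `division`, `category`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "division", "category")
  if (!all(need %in% names(tab)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  matrisome_catalog(tab$gene, tab$division, tab$category)
}

#' Construct a matrisome catalog in code
#'
#' @param gene_id character gene identifiers.
#' @param division `"core"` or `"associated"` per gene; if `NULL`, inferred
#'   from the category.
#' @param category one of `r paste(MATRISOME_CATEGORIES, collapse = ", ")`.
#' @return a `matrisome_catalog` data.frame.
#' @export
matrisome_catalog <- function(gene_id, division = NULL, category) {
  gene_id <- as.character(gene_id)
  category <- as.character(category)
  bad <- setdiff(unique(category), MATRISOME_CATEGORIES)
  if (length(bad))
    stop("unknown matrisome category: ", paste(bad, collapse = ", "))
  if (is.null(division))
    division <- ifelse(category %in% CORE_CATEGORIES, "core", "associated")
  division <- as.character(division)
  if (any(!division %in% c("core", "associated")))
    stop("division must be 'core' or 'associated'")
  mismatch <- (category %in% CORE_CATEGORIES) != (division == "core")
  if (any(mismatch))
    stop("division inconsistent with category for: ",
         paste(unique(gene_id[mismatch]), collapse = ", "))
  cat_tab <- unique(data.frame(gene_id = gene_id, division = division,
                               category = category, stringsAsFactors = FALSE))
  if (anyDuplicated(cat_tab$gene_id)) {
    dup <- unique(cat_tab$gene_id[duplicated(cat_tab$gene_id)])
    stop("gene(s) mapped to more than one category: ",
         paste(dup, collapse = ", "))
  }
  class(cat_tab) <- c("matrisome_catalog", "data.frame")
  cat_tab
}

#' Analysis gene set: core matrisome plus ECM regulators
#'
#' Returns the gene set every analysis in this package runs on: the core
#' matrisome (collagens, proteoglycans, ECM glycoproteins) together with the
#' ECM regulators; ECM-affiliated proteins and secreted factors are excluded.
#'
#' @param catalog a `matrisome_catalog`.
#' @return character vector of gene ids (possibly empty).
#' @export
core_plus_regulators <- function(catalog) {
  stopifnot(inherits(catalog, "matrisome_catalog"))
  catalog$gene_id[catalog$category %in% c(CORE_CATEGORIES, "ECM_regulators")]
}

#' Look up the matrisome category of genes
#'
#' @param catalog a `matrisome_catalog`.
#' @param gene_id character vector; genes absent from the catalog come back
#'   as `"non_matrisome"`.
#' @return character vector of categories, parallel to `gene_id`.
#' @export
catalog_category <- function(catalog, gene_id) {
  stopifnot(inherits(catalog, "matrisome_catalog"))
  out <- catalog$category[match(gene_id, catalog$gene_id)]
  out[is.na(out)] <- "non_matrisome"
  out
}

#' Write a result table as TSV
#'
#' @param x data.frame.
#' @param path output path; `.gz` suffix gzips.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
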