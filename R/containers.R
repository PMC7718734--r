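#' Line-level genotype container
#'
#' Holds an allele-dosage matrix for a panel of (typically inbred) lines
#' together with per-variant metadata. Dosages are lines x variants; for a
#' fully homozygous panel the declared coding is \code{"0/2"} (homozygous
#' reference 0, homozygous alternate 2) or \code{"0/1"}; outbred data may use
#' \code{"0/1/2"}. Missing calls are \code{NA}.
#'
#' @param dosages numeric matrix, lines in rows (rownames = line ids),
#'   variants in columns (colnames = variant ids).
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} (chrom/pos/ref/alt may be \code{NA}).
#' @param coding declared dosage coding, one of \code{"0/2"}, \code{"0/1"},
#'   \code{"0/1/2"}.
#' @return an object of class \code{"genotype_matrix"}.
#' @export
genotype_matrix <- function(dosages, variants = NULL,
                            coding = c("0/2", "0/1/2", "0/1")) {
  coding <- match.arg(coding)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    stop_ob("genotype dosage matrix must have line ids as rownames")
  ids <- rownames(dosages)
  if (anyDuplicated(ids))
    stop_ob("duplicate line ids in genotypes: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(dosages), chrom = NA_character_,
                           pos = NA_integer_, ref = NA_character_,
                           alt = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(variants) == ncol(dosages))
  max_dose <- switch(coding, "0/2" = 2, "0/1/2" = 2, "0/1" = 1)
  allowed <- switch(coding, "0/2" = c(0, 2), "0/1/2" = c(0, 1, 2),
                    "0/1" = c(0, 1))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% allowed))
    stop_ob("dosage values outside declared coding %s", coding)
  structure(list(dosages = dosages, variants = variants, coding = coding,
                 max_dose = max_dose, dropped_lines = character(0)),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d variants (coding %s)\n",
              nrow(x$dosages), ncol(x$dosages), x$coding))
  cr <- call_rate(x)
  cat(sprintf("  call rate: min %.3f, median %.3f\n",
              min(cr), stats::median(cr)))
  invisible(x)
}

#' Per-variant minor allele frequency
#'
#' Allele frequency is computed from non-missing dosages divided by the
#' coding's maximum dosage; the minor allele frequency is folded into
#' [0, 0.5].
#'
#' @param G a \code{genotype_matrix}.
#' @return named numeric vector of MAFs.
#' @export
maf <- function(G) {
  f <- colMeans(G$dosages, na.rm = TRUE) / G$max_dose
  pmin(f, 1 - f)
}

#' Per-variant call rate
#'
#' @param G a \code{genotype_matrix}.
#' @return named numeric vector: fraction of lines with a non-missing call.
#' @export
call_rate <- function(G) {
  colMeans(!is.na(G$dosages))
}

#' Line-level expression container
#'
#' Abundances are lines x genes on a log2(FPKM) scale; values must be finite.
#'
#' @param abundances numeric matrix, lines in rows (rownames = line ids),
#'   genes in columns.
#' @param genes optional data.frame with columns \code{id} and optionally
#'   \code{chrom}, \code{start}, \code{end}.
#' @return an object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(abundances, genes = NULL) {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (is.null(rownames(abundances)))
    stop_ob("expression matrix must have line ids as rownames")
  if (anyDuplicated(rownames(abundances)))
    stop_ob("duplicate line ids in expression matrix")
  if (is.null(colnames(abundances)))
    colnames(abundances) <- paste0("g", seq_len(ncol(abundances)))
  if (any(!is.finite(abundances)))
    stop_ob("expression abundances contain missing or non-finite values")
  if (is.null(genes))
    genes <- data.frame(id = colnames(abundances), stringsAsFactors = FALSE)
  stopifnot(nrow(genes) == ncol(abundances))
  structure(list(abundances = abundances, genes = genes,
                 dropped_lines = character(0)),
            class = "expression_matrix")
}

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d lines x %d genes\n",
              nrow(x$abundances), ncol(x$abundances)))
  invisible(x)
}

#' Line-mean phenotype container
#'
#' One row per line; trait columns are line means in trait units, missing
#' phenotypes allowed and tracked; covariate columns (categorical or numeric,
#' e.g. infection status or karyotypes) are carried for adjustment.
#'
#' @param data data.frame with a \code{line_id} column.
#' @param traits character vector naming trait columns.
#' @param covariates character vector naming covariate columns.
#' @return an object of class \code{"phenotype_table"}.
#' @export
phenotype_table <- function(data, traits, covariates = character(0)) {
  stopifnot(is.data.frame(data), "line_id" %in% names(data))
  if (anyDuplicated(data$line_id))
    stop_ob("duplicate line ids in phenotype table")
  missing_cols <- setdiff(c(traits, covariates), names(data))
  if (length(missing_cols))
    stop_ob("columns not in table: %s", paste(missing_cols, collapse = ", "))
  for (tr in traits)
    if (!is.numeric(data[[tr]]))
      stop_ob("trait column '%s' is not numeric", tr)
  structure(list(data = data, traits = traits, covariates = covariates,
                 dropped_lines = character(0)),
            class = "phenotype_table")
}

#' @method print phenotype_table
#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d lines, traits: %s\n", nrow(x$data),
              paste(x$traits, collapse = ", ")))
  for (tr in x$traits) {
    n_ok <- sum(!is.na(x$data[[tr]]))
    cat(sprintf("  %s: %d phenotyped lines\n", tr, n_ok))
  }
  invisible(x)
}

#' Extract one trait as a named vector
#'
#' @param pheno a \code{phenotype_table}.
#' @param trait trait name.
#' @param drop_missing drop lines with a missing value.
#' @return named numeric vector keyed by line id.
#' @export
trait_values <- function(pheno, trait, drop_missing = TRUE) {
  stopifnot(inherits(pheno, "phenotype_table"), trait %in% pheno$traits)
  y <- stats::setNames(pheno$data[[trait]], pheno$data$line_id)
  if (drop_missing) y <- y[!is.na(y)]
  y
}

#' Gene annotation container
#'
#' Maps genes to GO terms and to genomic spans (1-based inclusive), with an
#' optional variant-to-gene map filled by \code{\link{map_variants_to_genes}}.
#'
#' @param gene_to_terms named list: gene id -> character vector of GO ids.
#' @param gene_spans data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param variant_to_gene optional \code{variant_gene_map}.
#' @return an object of class \code{"annotation_map"}.
#' @export
annotation_map <- function(gene_to_terms, gene_spans = NULL,
                           variant_to_gene = NULL) {
  stopifnot(is.list(gene_to_terms))
  terms <- unlist(gene_to_terms, use.names = FALSE)
  bad <- terms[!grepl("^GO:[0-9]{7}$", terms)]
  if (length(bad))
    stop_ob("malformed GO ids: %s", paste(utils::head(unique(bad), 5),
                                          collapse = ", "))
  if (!is.null(gene_spans)) {
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_spans)))
    bad_span <- gene_spans$start > gene_spans$end
    if (any(bad_span))
      stop_ob("gene span with start > end: %s",
              paste(gene_spans$gene[bad_span], collapse = ", "))
  }
  structure(list(gene_to_terms = gene_to_terms, gene_spans = gene_spans,
                 variant_to_gene = variant_to_gene),
            class = "annotation_map")
}

#' @method print annotation_map
#' @export
print.annotation_map <- function(x, ...) {
  n_terms <- length(unique(unlist(x$gene_to_terms, use.names = FALSE)))
  cat(sprintf("annotation_map: %d genes, %d GO terms", length(x$gene_to_terms),
              n_terms))
  if (!is.null(x$gene_spans))
    cat(sprintf(", %d gene spans", nrow(x$gene_spans)))
  if (!is.null(x$variant_to_gene))
    cat(sprintf(", %d mapped variants", length(x$variant_to_gene$map)))
  cat("\n")
  invisible(x)
}

#' Line ids stored in a pipeline object
#'
#' @param x a genotype, expression, or phenotype container.
#' @return character vector of line ids.
#' @export
line_ids <- function(x) {
  if (inherits(x, "genotype_matrix")) return(rownames(x$dosages))
  if (inherits(x, "expression_matrix")) return(rownames(x$abundances))
  if (inherits(x, "phenotype_table")) return(x$data$line_id)
  if (inherits(x, "omni_kernel")) return(rownames(x$values))
  stop_ob("no line ids for class %s", paste(class(x), collapse = "/"))
}

#' Align data layers on their common lines
#'
#' Centralized line-id intersection: every supplied layer is subset to the
#' sorted intersection of ids, and each returned object records which of its
#' ids were dropped (field \code{dropped_lines}).
#'
#' @param ... named genotype/expression/phenotype objects.
#' @return named list of aligned objects, with attribute \code{"line_ids"}.
#' @export
align_lines <- function(...) {
  objs <- list(...)
  stopifnot(length(objs) >= 1, !is.null(names(objs)), all(nzchar(names(objs))))
  ids <- sort(Reduce(intersect, lapply(objs, line_ids)))
  if (!length(ids)) stop_ob("no lines in common across layers")
  out <- lapply(objs, function(x) {
    dropped <- setdiff(line_ids(x), ids)
    if (inherits(x, "genotype_matrix")) {
      x$dosages <- x$dosages[ids, , drop = FALSE]
    } else if (inherits(x, "expression_matrix")) {
      x$abundances <- x$abundances[ids, , drop = FALSE]
    } else if (inherits(x, "phenotype_table")) {
      x$data <- x$data[match(ids, x$data$line_id), , drop = FALSE]
    }
    x$dropped_lines <- dropped
    x
  })
  attr(out, "line_ids") <- ids
  out
}
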