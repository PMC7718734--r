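#' Read line genotypes from VCF or a dosage TSV
#'
#' For an inbred panel, diploid VCF genotypes are collapsed to line dosages:
#' homozygous reference -> 0, homozygous alternate -> 2, and residual
#' heterozygous calls are treated as no-calls by default (\code{het =
#' "missing"}) or as dosage 1 (\code{het = "one"}). Multiallelic records are
#' rejected with their coordinate unless \code{decompose = TRUE}, in which
#' case each alternate allele becomes its own biallelic pseudo-variant.
#'
#' @param path path to a VCF (v4.x, plain text) or a TSV with line ids in the
#'   first column and variant ids in the header.
#' @param format \code{"vcf"} or \code{"dosage_tsv"}.
#' @param het handling of heterozygous VCF calls.
#' @param decompose decompose multiallelic VCF records into biallelic ones.
#' @return a \code{\link{genotype_matrix}}; line order as in the file.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv"),
                           het = c("missing", "one"), decompose = FALSE) {
  format <- match.arg(format)
  het <- match.arg(het)
  if (!file.exists(path)) stop_ob("file not found: %s", path)
  if (format == "vcf") read_genotypes_vcf(path, het, decompose)
  else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path, het, decompose) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    stop_ob("duplicate line ids in VCF header: %s",
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  multi <- grepl(",", fix$ALT)
  if (any(multi) && !decompose)
    stop_ob("multiallelic record at %s:%s; enable decompose or normalize upstream",
            fix$CHROM[which(multi)[1]], fix$POS[which(multi)[1]])
  # per record, one column per alternate allele counting that allele
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    g <- gt[i, ]
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    for (a in seq_along(alts)) {
      dose <- vapply(al, function(x) {
        if (length(x) == 0 || anyNA(x) || any(x == ".")) return(NA_real_)
        sum(x == as.character(a))
      }, numeric(1))
      if (het == "missing") dose[dose == 1] <- NA_real_
      id <- fix$ID[i]
      if (is.na(id) || id == ".")
        id <- paste0(fix$CHROM[i], ":", fix$POS[i])
      if (length(alts) > 1) id <- paste0(id, "_", alts[a])
      cols[[length(cols) + 1L]] <- dose
      meta[[length(meta) + 1L]] <- data.frame(
        id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a], stringsAsFactors = FALSE)
    }
  }
  dosages <- do.call(cbind, cols)
  variants <- do.call(rbind, meta)
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  coding <- if (het == "missing") "0/2" else "0/1/2"
  genotype_matrix(dosages, variants, coding = coding)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           na.strings = "NA", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m))
    stop_ob("non-numeric dosage values in %s", path)
  vals <- unique(m[!is.na(m)])
  coding <- if (all(vals %in% c(0, 2))) "0/2"
    else if (all(vals %in% c(0, 1))) "0/1" else "0/1/2"
  # variant ids of the form chrom:pos or chrom_pos carry their coordinate
  ids <- colnames(m)
  parts <- regmatches(ids, regexec("^([^:_]+)[:_]([0-9]+)", ids))
  chrom <- vapply(parts, function(p) if (length(p) == 3) p[2] else NA_character_,
                  character(1))
  pos <- vapply(parts, function(p) if (length(p) == 3) as.integer(p[3])
                else NA_integer_, integer(1))
  variants <- data.frame(id = ids, chrom = chrom, pos = pos,
                         ref = NA_character_, alt = NA_character_,
                         stringsAsFactors = FALSE)
  genotype_matrix(m, variants, coding = coding)
}

#' Read an expression, phenotype, or covariate TSV
#'
#' Expects tab-separated text with line ids in the first column and feature
#' or trait names in the header ('.' decimal, "NA" missing token).
#'
#' @param path file path.
#' @param kind \code{"expression"} (all values must be finite; non-numeric
#'   cells are rejected with their coordinates), \code{"phenotype"} (missing
#'   values allowed and tracked), or \code{"covariates"}.
#' @param traits for \code{kind = "phenotype"}: which columns are traits
#'   (default: all numeric columns); the rest become covariates.
#' @return an \code{\link{expression_matrix}}, \code{\link{phenotype_table}},
#'   or data.frame of covariates keyed by \code{line_id}.
#' @export
read_matrix_table <- function(path, kind = c("expression", "phenotype",
                                             "covariates"), traits = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_ob("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = "NA", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != length(header))
    stop_ob("header has %d fields but rows have %d in %s",
            length(header), ncol(tab), path)
  ids <- as.character(tab[[1]])
  body <- tab[, -1, drop = FALSE]
  if (kind == "expression") {
    for (j in seq_along(body)) {
      col <- body[[j]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
        bad <- bad %||% which(is.na(col))[1]
        stop_ob("non-numeric cell in expression table at row %d (line %s), column '%s'",
                bad, ids[bad], names(body)[j])
      }
      if (anyNA(col))
        stop_ob("missing value in expression table at row %d, column '%s'",
                which(is.na(col))[1], names(body)[j])
    }
    m <- as.matrix(body)
    rownames(m) <- ids
    return(expression_matrix(m))
  }
  df <- data.frame(line_id = ids, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (kind == "covariates") return(df)
  if (is.null(traits))
    traits <- names(body)[vapply(body, is.numeric, logical(1))]
  covars <- setdiff(names(body), traits)
  phenotype_table(df, traits = traits, covariates = covars)
}

#' Read gene-to-GO and gene-span annotation
#'
#' The gene-to-GO file is either a two-column TSV (gene, GO id) or a GAF
#' subset (comment lines starting with '!'; gene symbol in column 3, GO id
#' in column 5). Spans come from a GFF3 (gene features; 1-based inclusive)
#' or a four-column TSV (gene, chrom, start, end). Genes present in the span
#' file but absent from the GO file are retained with an empty term set.
#'
#' @param gene2go_path path to the gene-to-GO file.
#' @param gene_span_path optional path to a GFF3 or span TSV.
#' @return an \code{\link{annotation_map}}.
#' @export
read_annotation <- function(gene2go_path, gene_span_path = NULL) {
  if (!file.exists(gene2go_path)) stop_ob("file not found: %s", gene2go_path)
  lines <- readLines(gene2go_path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  gaf <- length(fields) > 0 && stats::median(nf) >= 5
  pairs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (gaf) c(f[3], f[5]) else c(f[1], f[2])
  })
  genes <- vapply(pairs, `[`, character(1), 1)
  gos <- vapply(pairs, `[`, character(1), 2)
  bad <- which(is.na(gos) | !grepl("^GO:[0-9]{7}$", gos))
  if (length(bad))
    stop_ob("malformed GO id '%s' at line %d of %s",
            gos[bad[1]], lineno[bad[1]], gene2go_path)
  gene_to_terms <- lapply(split(gos, genes), unique)

  gene_spans <- NULL
  if (!is.null(gene_span_path)) {
    if (!file.exists(gene_span_path))
      stop_ob("file not found: %s", gene_span_path)
    first <- readLines(gene_span_path, n = 1)
    if (startsWith(first, "##gff") || grepl("\tgene\t", paste(
          readLines(gene_span_path, n = 50), collapse = "\n"))) {
      g <- ape::read.gff(gene_span_path)
      g <- g[g$type == "gene", , drop = FALSE]
      id <- sub(";.*$", "", sub("^.*?ID=", "", g$attributes))
      gene_spans <- data.frame(gene = id, chrom = as.character(g$seqid),
                               start = g$start, end = g$end,
                               stringsAsFactors = FALSE)
    } else {
      tab <- utils::read.table(gene_span_path, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)
      if (ncol(tab) < 4) stop_ob("span TSV needs 4 columns (gene chrom start end)")
      gene_spans <- data.frame(gene = as.character(tab[[1]]),
                               chrom = as.character(tab[[2]]),
                               start = as.integer(tab[[3]]),
                               end = as.integer(tab[[4]]),
                               stringsAsFactors = FALSE)
    }
    # span-only genes keep an empty term set
    extra <- setdiff(gene_spans$gene, names(gene_to_terms))
    if (length(extra)) {
      empty <- stats::setNames(rep(list(character(0)), length(extra)), extra)
      gene_to_terms <- c(gene_to_terms, empty)
    }
  }
  annotation_map(gene_to_terms, gene_spans)
}

#' Write pipeline results to TSV or JSON
#'
#' Numeric fields are serialized at full precision (17 significant digits
#' for TSV, unrounded JSON) so a write/read round trip reproduces them
#' exactly. \code{cv_metrics} objects become one TSV row per
#' (replicate, fold); lists of GO scan summaries are written sorted by
#' accuracy.
#'
#' @param results a data.frame, list, \code{cv_metrics}, or GO scan summary
#'   data.frame.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_ob("unwritable path: %s", path)
  if (inherits(results, "cv_metrics")) results <- results$per_fold
  if (format == "json") {
    if (is.data.frame(results) && "mean_r" %in% names(results))
      results <- results[order(-results$mean_r), , drop = FALSE]
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    return(invisible(path))
  }
  if (!is.data.frame(results)) results <- as.data.frame(results)
  out <- results
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
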