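#' Write a cohort to disk (VCF + phenotype and annotation TSVs)
#'
#' Emits three plain-text files: `<prefix>.vcf`, a minimal VCF v4.2 with a
#' GT-only FORMAT field (`0/0`, `0/1`, `1/1`, `./.`);
#' `<prefix>.pheno.tsv` with columns `sample_id`, `label`, `age`,
#' `pack_years`; and `<prefix>.anno.tsv` with the variant annotation.
#' [read_cohort()] on the same prefix reproduces the cohort exactly.
#'
#' @param x a [cohort()].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(x, prefix) {
  stopifnot(inherits(x, "cohort"))
  v <- x$variants
  if (!identical(as.character(v$variant_id), colnames(x$genotypes)))
    stop("annotation and genotype variant panels do not match")
  vcf_path <- paste0(prefix, ".vcf")
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[x$genotypes + 1L],
                   nrow = nrow(x$genotypes))
  gt_chr[is.na(gt_chr)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(as.character(v$chrom))),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", sep = "\t")
  # genotype columns are variant-major in the matrix; transpose to rows
  body <- paste(body, apply(gt_chr, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  pheno_path <- paste0(prefix, ".pheno.tsv")
  utils::write.table(
    data.frame(sample_id = x$sample_ids, label = x$labels,
               age = x$age, pack_years = x$pack_years),
    pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)

  anno_path <- paste0(prefix, ".anno.tsv")
  utils::write.table(v, anno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, pheno = pheno_path, anno = anno_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' The VCF is parsed with `VariantAnnotation::readVcf()`; only the GT field
#' is used. Records must be biallelic (multi-allelic sites have to be split
#' upstream; they are rejected rather than guessed at), and genotypes other
#' than `0/0`, `0/1`, `1/0`, `1/1` and `./.` are an error.
#'
#' @param prefix path prefix used by [write_cohort()], or a named list/vector
#'   with elements `vcf`, `pheno`, `anno` pointing at the three files.
#' @return a [cohort()].
#' @export
read_cohort <- function(prefix) {
  if (length(prefix) == 1L && is.character(prefix))
    paths <- c(vcf = paste0(prefix, ".vcf"),
               pheno = paste0(prefix, ".pheno.tsv"),
               anno = paste0(prefix, ".anno.tsv"))
  else paths <- unlist(prefix)
  vcf <- VariantAnnotation::readVcf(paths[["vcf"]])
  alt_list <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt_list) != 1L))
    stop("multi-allelic record(s) found; split into biallelic records first")
  gt <- VariantAnnotation::geno(vcf)$GT    # variants x samples
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA)
  unknown <- setdiff(unique(as.vector(gt)), names(codes))
  if (length(unknown))
    stop("unsupported genotype code(s): ", paste(unknown, collapse = ", "))
  g <- matrix(codes[gt], nrow = ncol(gt), byrow = TRUE,
              dimnames = list(colnames(gt), rownames(gt)))

  pheno <- utils::read.table(paths[["pheno"]], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!identical(pheno$sample_id, rownames(g)))
    stop("phenotype table sample IDs do not match the VCF sample columns")
  anno <- utils::read.table(paths[["anno"]], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  anno$chrom <- as.character(anno$chrom)
  if (!identical(anno$variant_id, colnames(g)))
    stop("annotation table variant panel does not match the VCF records")
  if (anyDuplicated(anno$variant_id))
    stop("duplicated variant identifier(s) in the panel")
  key <- paste(anno$chrom, anno$pos, anno$ref, anno$alt, sep = ":")
  if (anyDuplicated(key))
    stop("variant identifier collision: identical chrom:pos:ref:alt for ",
         "distinct records")
  cohort(g, pheno$label, anno, age = pheno$age, pack_years = pheno$pack_years)
}

#' Read gene-set collections in GMT format
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}
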