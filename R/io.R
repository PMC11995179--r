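#' Write an SV catalog as VCF 4.2
#'
#' Symbolic-allele records with INFO keys SVTYPE, END, SVLEN (negative for
#' deletions, positive otherwise, 0 for translocations), CHR2/POS2 for
#' translocations and SOURCES for provenance. POS is the 1-based start of
#' the affected interval (the internal representation is 0-based
#' half-open, so POS = start + 1); for insertions POS is the base before
#' the inserted sequence.
#'
#' @param catalog SV data.frame (`id`, `chrom`, `start`, `end`, `svtype`,
#'   `length`, optional `chr2`, `pos2`, `sources`/`source`).
#' @param path output file.
#' @param contigs optional data.frame `chrom`, `length` for ##contig lines.
#' @export
write_sv_vcf <- function(catalog, path, contigs = NULL) {
  src <- if (!is.null(catalog$sources)) catalog$sources
         else if (!is.null(catalog$source)) catalog$source
         else "unknown"
  svlen <- ifelse(catalog$svtype == "DEL", -catalog$length,
                  ifelse(catalog$svtype == "TRA", 0, catalog$length))
  info <- paste0("SVTYPE=", catalog$svtype,
                 ";END=", ifelse(catalog$svtype %in% c("DEL", "INV"),
                                 catalog$end, catalog$start + 1),
                 ";SVLEN=", svlen,
                 ifelse(!is.na(catalog$chr2) & catalog$svtype == "TRA",
                        paste0(";CHR2=", catalog$chr2,
                               ";POS2=", catalog$pos2), ""),
                 ";SOURCES=", src)
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", contigs$chrom,
              as.integer(contigs$length)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=TRA,Description=\"Translocation\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Partner chromosome\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Partner position\">",
    "##INFO=<ID=SOURCES,Number=1,Type=String,Description=\"Callset provenance\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(catalog$chrom, format(catalog$start + 1, scientific = FALSE,
                                      trim = TRUE),
                catalog$id, "N", paste0("<", catalog$svtype, ">"),
                ".", "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an SV catalog from VCF
#'
#' Inverse of [write_sv_vcf()]: converts POS/END back to 0-based
#' half-open coordinates and takes absolute SVLEN as the length.
#'
#' @param path VCF file.
#' @return SV data.frame.
#' @export
read_sv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  end1 <- as.numeric(vcfR::extract.info(vcf, "END"))
  svlen <- as.numeric(vcfR::extract.info(vcf, "SVLEN"))
  chr2 <- vcfR::extract.info(vcf, "CHR2")
  pos2 <- as.numeric(vcfR::extract.info(vcf, "POS2"))
  sources <- vcfR::extract.info(vcf, "SOURCES")
  pos <- as.numeric(fix$POS)
  start <- pos - 1
  end <- ifelse(svtype %in% c("DEL", "INV"), end1, start)
  df <- data.frame(id = fix$ID, chrom = fix$CHROM, start = start, end = end,
                   svtype = svtype, length = abs(svlen),
                   chr2 = chr2, pos2 = pos2, source = sources,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  df
}

#' Write / read a genotype matrix as VCF with GT fields
#'
#' Dosage 0/1/2 becomes 0/0, 0/1, 1/1; missing becomes ./..
#'
#' @param genotypes list with `dosage` (samples x loci) and `loci`
#'   (`id`, `chrom`, `start`, optional `svtype`).
#' @param path VCF path.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  X <- genotypes$dosage
  loci <- genotypes$loci
  gt <- matrix(c("0/0", "0/1", "1/1")[X + 1], nrow = nrow(X))
  gt[is.na(X)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(X)), collapse = "\t"))
  info <- if (!is.null(loci$svtype)) paste0("SVTYPE=", loci$svtype) else "."
  body <- paste(loci$chrom, format(loci$start + 1, scientific = FALSE,
                                   trim = TRUE),
                loci$id, "N", "<SV>", ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotype_vcf
#' @return `read_genotype_vcf`: a `genotypes` list (`dosage`, `loci`).
#' @export
read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), fix$ID))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- t(matrix(lut[gt], nrow = nrow(gt)))
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  loci <- data.frame(id = fix$ID, chrom = fix$CHROM,
                     start = as.numeric(fix$POS) - 1,
                     svtype = svtype, stringsAsFactors = FALSE)
  list(dosage = dos, loci = loci)
}

#' Tab-separated helpers for the small pipeline tables
#'
#' Population maps (`sample`, `population`), phenotypes (`sample`,
#' `value`) and count matrices round-trip through plain TSV.
#'
#' @param x object to write; `path` file path.
#' @name tsv_io
#' @export
write_popmap <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_popmap <- function(path) utils::read.delim(path,
                                                stringsAsFactors = FALSE)

#' @rdname tsv_io
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}
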