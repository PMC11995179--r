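#' Simulate gene models and TE intervals
#'
#' Builds a toy reference annotation: non-overlapping multi-exon gene
#' models with UTRs at the transcript ends, plus transposable-element
#' intervals labelled LTR or non-LTR. All coordinates are held internally
#' as 0-based half-open intervals; [write_annotation()] emits standard
#' 1-based GFF3 and 0-based BED.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `"annotation_set"`: a list of data.frames
#'   `chromosomes` (chrom, length), `genes`, `exons`, `cds`, `utr5`,
#'   `utr3` (gene_id, chrom, start, end, strand) and `te`
#'   (te_id, chrom, start, end, class).
#' @examples
#' ann <- simulate_annotation(sim_config(seed = 1, n_genes = 20, n_te = 30))
#' head(ann$genes)
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  withr_seed(child_seed(config, "annotation"), {
    chroms <- data.frame(
      chrom = sprintf("chr%d", seq_len(config$n_chromosomes)),
      length = config$chrom_length,
      stringsAsFactors = FALSE)

    per_chrom <- largest_remainder(
      config$n_genes, rep(1 / nrow(chroms), nrow(chroms)))

    genes <- exons <- cds <- utr5 <- utr3 <- list()
    gid <- 0L
    min_gap <- 2500   # room for 2-kb flanks and intergenic placement
    for (ci in seq_len(nrow(chroms))) {
      g <- per_chrom[ci]
      if (g == 0L) next
      structs <- lapply(seq_len(g), function(i) gene_structure())
      lens <- vapply(structs, function(s) s$length, numeric(1))
      if (any(lens > chroms$length[ci]))
        stop("gene length exceeds chromosome length; increase chrom_length")
      need <- sum(lens) + (g + 1) * min_gap
      if (need > chroms$length[ci])
        stop("chromosome too short for ", g, " genes plus ", min_gap,
             " bp gaps; increase chrom_length or reduce n_genes")
      slack <- chroms$length[ci] - need
      w <- stats::runif(g + 1)
      extra <- floor(slack * w / sum(w))
      cursor <- 0
      for (i in seq_len(g)) {
        cursor <- cursor + min_gap + extra[i]
        gid <- gid + 1L
        id <- sprintf("gene%05d", gid)
        s <- structs[[i]]
        strand <- sample(c("+", "-"), 1L)
        gs <- cursor
        genes[[gid]] <- data.frame(gene_id = id, chrom = chroms$chrom[ci],
                                   start = gs, end = gs + s$length,
                                   strand = strand, stringsAsFactors = FALSE)
        ex <- data.frame(gene_id = id, chrom = chroms$chrom[ci],
                         start = gs + s$exon_start, end = gs + s$exon_end,
                         strand = strand, stringsAsFactors = FALSE)
        exons[[gid]] <- ex
        # UTRs sit at the transcript ends: 5' on the strand's first exon
        u5_len <- s$utr5_len; u3_len <- s$utr3_len
        if (strand == "+") {
          u5 <- data.frame(gene_id = id, chrom = chroms$chrom[ci],
                           start = ex$start[1], end = ex$start[1] + u5_len,
                           strand = strand, stringsAsFactors = FALSE)
          n_ex <- nrow(ex)
          u3 <- data.frame(gene_id = id, chrom = chroms$chrom[ci],
                           start = ex$end[n_ex] - u3_len, end = ex$end[n_ex],
                           strand = strand, stringsAsFactors = FALSE)
        } else {
          n_ex <- nrow(ex)
          u5 <- data.frame(gene_id = id, chrom = chroms$chrom[ci],
                           start = ex$end[n_ex] - u5_len, end = ex$end[n_ex],
                           strand = strand, stringsAsFactors = FALSE)
          u3 <- data.frame(gene_id = id, chrom = chroms$chrom[ci],
                           start = ex$start[1], end = ex$start[1] + u3_len,
                           strand = strand, stringsAsFactors = FALSE)
        }
        utr5[[gid]] <- u5
        utr3[[gid]] <- u3
        cds[[gid]] <- subtract_intervals(ex, rbind(u5, u3))
        cursor <- cursor + s$length
      }
    }
    te_len <- pmin(round(stats::rlnorm(config$n_te, log(800), 0.9)) + 100,
                   50000)
    te_chrom <- sample(chroms$chrom, config$n_te, replace = TRUE)
    te_start <- floor(stats::runif(config$n_te) *
                        (config$chrom_length - te_len))
    te <- data.frame(
      te_id = sprintf("te%05d", seq_len(config$n_te)),
      chrom = te_chrom, start = te_start, end = te_start + te_len,
      class = sample(c("LTR", "non-LTR"), config$n_te, replace = TRUE,
                     prob = c(0.35, 0.65)),
      stringsAsFactors = FALSE)
    te <- te[order(te$chrom, te$start), ]
    rownames(te) <- NULL

    ann <- list(chromosomes = chroms,
                genes = do.call(rbind, genes),
                exons = do.call(rbind, exons),
                cds = do.call(rbind, cds),
                utr5 = do.call(rbind, utr5),
                utr3 = do.call(rbind, utr3),
                te = te)
    ann <- lapply(ann, function(d) { rownames(d) <- NULL; d })
    class(ann) <- "annotation_set"
    ann
  })
}

# Random exon/intron layout for one gene, in gene-local 0-based coordinates.
gene_structure <- function() {
  n_exon <- sample(1:5, 1L)
  exon_len <- sample(300:1200, n_exon, replace = TRUE)
  utr5_len <- sample(50:150, 1L)
  utr3_len <- sample(50:150, 1L)
  exon_len[1] <- max(exon_len[1], utr5_len + utr3_len + 100)
  exon_len[n_exon] <- max(exon_len[n_exon], utr5_len + utr3_len + 100)
  intron_len <- if (n_exon > 1) sample(300:2500, n_exon - 1, replace = TRUE)
                else integer(0)
  starts <- cumsum(c(0, exon_len[-n_exon] + intron_len))
  list(exon_start = starts, exon_end = starts + exon_len,
       length = starts[n_exon] + exon_len[n_exon],
       utr5_len = utr5_len, utr3_len = utr3_len)
}

# Set difference of half-open interval data.frames, per gene.
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0) return(a)
  ga <- GenomicRanges::GRanges(a$chrom,
                               IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom,
                               IRanges::IRanges(b$start + 1, b$end))
  d <- GenomicRanges::setdiff(ga, gb)
  if (length(d) == 0)
    return(a[0, , drop = FALSE])
  data.frame(gene_id = a$gene_id[1], chrom = as.character(GenomicRanges::seqnames(d)),
             start = GenomicRanges::start(d) - 1, end = GenomicRanges::end(d),
             strand = a$strand[1], stringsAsFactors = FALSE)
}

#' Write an annotation set to GFF3 + BED
#'
#' Gene models go to GFF3 (1-based inclusive; gene/mRNA/exon/CDS/UTR rows
#' with ID/Parent links), TE intervals to BED (0-based half-open, name
#' column holding the LTR / non-LTR class).
#'
#' @param ann an `annotation_set`.
#' @param gff_path,bed_path output paths.
#' @export
write_annotation <- function(ann, gff_path, bed_path) {
  rows <- list()
  add <- function(df, type, id, parent) {
    if (nrow(df) == 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      chrom = df$chrom, start = df$start, end = df$end, strand = df$strand,
      type = type, ID = id, Parent = parent,
      phase = if (type == "CDS") 0L else NA_integer_,
      stringsAsFactors = FALSE)
  }
  g <- ann$genes
  add(g, "gene", g$gene_id, NA_character_)
  add(g, "mRNA", paste0(g$gene_id, ".t1"), g$gene_id)
  part <- function(df, type, tag) {
    if (nrow(df) == 0) return()
    add(df, type,
        paste0(df$gene_id, ".", tag, ".", stats::ave(df$start, df$gene_id,
                                                     FUN = seq_along)),
        paste0(df$gene_id, ".t1"))
  }
  part(ann$exons, "exon", "exon")
  part(ann$cds, "CDS", "cds")
  part(ann$utr5, "five_prime_UTR", "utr5")
  part(ann$utr3, "three_prime_UTR", "utr3")
  all <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    all$chrom, IRanges::IRanges(all$start + 1, all$end), strand = all$strand,
    type = all$type, ID = all$ID, Parent = all$Parent, phase = all$phase)
  sl <- stats::setNames(ann$chromosomes$length, ann$chromosomes$chrom)
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, gff_path, format = "gff3")

  te <- GenomicRanges::GRanges(ann$te$chrom,
                               IRanges::IRanges(ann$te$start + 1, ann$te$end),
                               name = ann$te$class)
  rtracklayer::export(te, bed_path, format = "bed")
  invisible(list(gff = gff_path, bed = bed_path))
}

#' Read an annotation set from GFF3 + BED
#'
#' Inverse of [write_annotation()] up to row order and chromosome-length
#' metadata.
#'
#' @param gff_path,bed_path paths written by [write_annotation()].
#' @return An `annotation_set`.
#' @export
read_annotation <- function(gff_path, bed_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   ID = as.character(gr$ID),
                   Parent = vapply(as.list(gr$Parent), function(p)
                     if (length(p)) p[[1]] else NA_character_, character(1)),
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = genes$ID, chrom = genes$chrom,
                      start = genes$start, end = genes$end,
                      strand = genes$strand, stringsAsFactors = FALSE)
  pick <- function(type) {
    d <- df[df$type == type, ]
    d <- d[order(d$chrom, d$start), ]
    data.frame(gene_id = sub("\\.t1$", "", d$Parent), chrom = d$chrom,
               start = d$start, end = d$end, strand = d$strand,
               stringsAsFactors = FALSE)
  }
  te_gr <- rtracklayer::import(bed_path, format = "bed")
  te <- data.frame(te_id = sprintf("te%05d", seq_along(te_gr)),
                   chrom = as.character(GenomicRanges::seqnames(te_gr)),
                   start = GenomicRanges::start(te_gr) - 1,
                   end = GenomicRanges::end(te_gr),
                   class = te_gr$name, stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(gr)
  chroms <- data.frame(chrom = names(sl), length = as.numeric(sl),
                       stringsAsFactors = FALSE)
  ann <- list(chromosomes = chroms,
              genes = genes[order(genes$chrom, genes$start), ],
              exons = pick("exon"), cds = pick("CDS"),
              utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"),
              te = te)
  ann <- lapply(ann, function(d) { rownames(d) <- NULL; d })
  class(ann) <- "annotation_set"
  ann
}
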