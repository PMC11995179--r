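# Internal intervals are 0-based half-open; GRanges are built 1-based
# inclusive. Width-0 records (INS breakpoints) become width-1 point ranges.
df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start + 1, pmax(df$end, df$start + 1)))
}

#' Assign each SV a genic-region label
#'
#' Every base pair an SV overlaps (the breakpoint, for insertions and
#' translocations) is tested against gene features, and a single label is
#' resolved by precedence:
#' splice_region > exon > utr5 > utr3 > intron > upstream2kb >
#' downstream2kb > intergenic. "exon" means coding exon (CDS), so that
#' UTR overlaps are still visible; splice regions extend
#' `splice_intron` bp into the intron and `splice_exon` bp into the exon
#' at every internal exon junction. Up/downstream flanks are
#' strand-aware.
#'
#' @param catalog SV data.frame (`id`, `chrom`, `start`, `end`, `svtype`).
#' @param annotation an `annotation_set`.
#' @param flank flank width (bp) for the up/downstream labels.
#' @param splice_intron,splice_exon splice-region extent around junctions.
#' @return data.frame `sv_id`, `svtype`, `length`, `region`,
#'   `nearest_gene`, `distance` (bp; 0 when overlapping a gene body).
#' @export
annotate_region <- function(catalog, annotation, flank = 2000,
                            splice_intron = 8, splice_exon = 3) {
  if (nrow(catalog) == 0) stop("empty catalog")
  sv <- catalog
  point <- sv$svtype %in% c("INS", "TRA")
  ev <- data.frame(chrom = sv$chrom, start = sv$start,
                   end = ifelse(point, sv$start + 1, sv$end))
  gr_sv <- df_to_granges(ev)

  feats <- region_features(annotation, flank, splice_intron, splice_exon)
  region <- rep("intergenic", nrow(sv))
  assigned <- logical(nrow(sv))
  for (lab in c("splice_region", "exon", "utr5", "utr3", "intron",
                "upstream2kb", "downstream2kb")) {
    f <- feats[[lab]]
    if (is.null(f) || length(f) == 0) next
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_sv, f)))
    take <- setdiff(hit, which(assigned))
    region[take] <- lab
    assigned[take] <- TRUE
  }

  gr_gene <- df_to_granges(annotation$genes)
  nearest <- GenomicRanges::distanceToNearest(gr_sv, gr_gene)
  nearest_gene <- rep(NA_character_, nrow(sv))
  distance <- rep(NA_real_, nrow(sv))
  qh <- S4Vectors::queryHits(nearest)
  nearest_gene[qh] <- annotation$genes$gene_id[S4Vectors::subjectHits(nearest)]
  distance[qh] <- S4Vectors::mcols(nearest)$distance
  data.frame(sv_id = sv$id, svtype = sv$svtype, length = sv$length,
             region = region, nearest_gene = nearest_gene,
             distance = distance, stringsAsFactors = FALSE)
}

# Feature GRanges per region label (all 1-based inclusive).
region_features <- function(annotation, flank, splice_intron, splice_exon) {
  genes <- annotation$genes
  exons <- annotation$exons
  if (is.null(exons) || nrow(exons) == 0) {
    warning("gene models lack exons; treating each gene as a single exon")
    exons <- genes
  }
  # internal junctions: per gene, exon ends except the last, exon starts
  # except the first (coordinate-sorted)
  sp <- list()
  for (g in split(exons, exons$gene_id)) {
    g <- g[order(g$start), ]
    if (nrow(g) < 2) next
    ends <- g$end[-nrow(g)]       # right edge of exon, junction to intron
    starts <- g$start[-1]         # left edge of exon after an intron
    sp[[length(sp) + 1]] <- data.frame(
      chrom = g$chrom[1],
      start = c(ends - splice_exon, starts - splice_intron),
      end = c(ends + splice_intron, starts + splice_exon))
  }
  splice <- if (length(sp)) df_to_granges(do.call(rbind, sp))
            else GenomicRanges::GRanges()

  gr_gene <- df_to_granges(genes)
  gr_exon <- df_to_granges(exons)
  intron <- GenomicRanges::setdiff(gr_gene, gr_exon)

  plus <- genes$strand == "+"
  up <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, pmax(0, genes$start - flank), genes$end),
    end = ifelse(plus, genes$start, genes$end + flank))
  down <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$end, pmax(0, genes$start - flank)),
    end = ifelse(plus, genes$end + flank, genes$start))

  cds <- if (!is.null(annotation$cds) && nrow(annotation$cds)) annotation$cds
         else exons
  list(splice_region = splice,
       exon = df_to_granges(cds),
       utr5 = if (!is.null(annotation$utr5) && nrow(annotation$utr5))
         df_to_granges(annotation$utr5) else GenomicRanges::GRanges(),
       utr3 = if (!is.null(annotation$utr3) && nrow(annotation$utr3))
         df_to_granges(annotation$utr3) else GenomicRanges::GRanges(),
       intron = intron,
       upstream2kb = df_to_granges(up),
       downstream2kb = df_to_granges(down))
}

#' Label PAVs by transposable-element origin
#'
#' A deletion is a TE-PAV when at least `min_overlap` of its deleted
#' interval is covered by TE annotation; its class (LTR / non-LTR) is the
#' majority-overlap TE class. Insertions carry novel sequence, so their
#' TE origin can only be judged from an annotation of the inserted
#' sequence itself (`ins_te`); without one they are reported untestable.
#' Inversions and translocations are not PAVs and are excluded.
#'
#' @param catalog SV data.frame.
#' @param te TE data.frame (`chrom`, `start`, `end`, `class`; 0-based
#'   half-open) as in an `annotation_set`.
#' @param min_overlap minimum covered fraction of the SV length.
#' @param ins_te optional data.frame (`sv_id`, `class`, `fraction`)
#'   annotating inserted sequences.
#' @return list `records` (per-PAV data.frame `sv_id`, `svtype`,
#'   `te_fraction`, `status` in te/non-te/untestable, `te_class`) and
#'   `summary` (TE-PAV percent among testable PAVs; per-type class
#'   percentages).
#' @export
annotate_te_origin <- function(catalog, te, min_overlap = 0.5,
                               ins_te = NULL) {
  pav <- catalog[catalog$svtype %in% c("DEL", "INS"), , drop = FALSE]
  if (nrow(pav) == 0) stop("no PAV (DEL/INS) records in catalog")
  rec <- data.frame(sv_id = pav$id, svtype = pav$svtype,
                    te_fraction = NA_real_, status = "untestable",
                    te_class = NA_character_, stringsAsFactors = FALSE)
  del <- which(pav$svtype == "DEL")
  if (length(del)) {
    gr_del <- df_to_granges(pav[del, ])
    cov <- matrix(0, nrow = length(del), ncol = 2,
                  dimnames = list(NULL, c("LTR", "non-LTR")))
    for (cl in c("LTR", "non-LTR")) {
      sub <- te[te$class == cl, , drop = FALSE]
      if (nrow(sub) == 0) next
      gr_te <- GenomicRanges::reduce(df_to_granges(sub))
      hits <- GenomicRanges::findOverlaps(gr_del, gr_te)
      if (!length(hits)) next
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        gr_del[S4Vectors::queryHits(hits)],
        gr_te[S4Vectors::subjectHits(hits)]))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      cov[as.integer(names(agg)), cl] <- agg
    }
    frac <- pmin(1, rowSums(cov) / pav$length[del])
    rec$te_fraction[del] <- frac
    rec$status[del] <- ifelse(frac >= min_overlap, "te", "non-te")
    is_te <- frac >= min_overlap
    rec$te_class[del][is_te] <-
      colnames(cov)[max.col(cov[is_te, , drop = FALSE], ties.method = "first")]
  }
  ins <- which(pav$svtype == "INS")
  if (length(ins) && !is.null(ins_te)) {
    mi <- match(pav$id[ins], ins_te$sv_id)
    known <- !is.na(mi)
    rec$te_fraction[ins[known]] <- ins_te$fraction[mi[known]]
    rec$status[ins[known]] <- ifelse(
      ins_te$fraction[mi[known]] >= min_overlap, "te", "non-te")
    rec$te_class[ins[known]] <- ifelse(
      ins_te$fraction[mi[known]] >= min_overlap,
      ins_te$class[mi[known]], NA_character_)
  }
  testable <- rec$status != "untestable"
  summ <- list(
    n_pav = nrow(rec), n_testable = sum(testable),
    te_pav_percent = if (any(testable))
      100 * sum(rec$status == "te") / sum(testable) else NA_real_,
    class_percent_by_type = lapply(split(rec[testable & rec$status == "te", ],
                                         rec$svtype[testable & rec$status == "te"]),
      function(d) if (nrow(d)) 100 * table(d$te_class) / nrow(d) else NULL))
  list(records = rec, summary = summ)
}

#' Distance of each SV to its nearest gene, TE vs non-TE contrast
#'
#' Distance is 0 when the SV overlaps a gene body, otherwise base pairs
#' to the closest gene boundary. When TE-origin labels are supplied the
#' TE-PAV and non-TE-PAV distance distributions are compared with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param catalog SV data.frame.
#' @param annotation an `annotation_set`.
#' @param te_labels optional `records` data.frame from
#'   [annotate_te_origin()].
#' @return list `distances` (sv_id, distance), `test` (NULL, or list with
#'   medians, W and p).
#' @export
nearest_gene_distance <- function(catalog, annotation, te_labels = NULL) {
  point <- catalog$svtype %in% c("INS", "TRA")
  ev <- data.frame(chrom = catalog$chrom, start = catalog$start,
                   end = ifelse(point, catalog$start + 1, catalog$end))
  gr_sv <- df_to_granges(ev)
  gr_gene <- df_to_granges(annotation$genes)
  nearest <- GenomicRanges::distanceToNearest(gr_sv, gr_gene)
  distance <- rep(NA_real_, nrow(catalog))
  distance[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
  res <- data.frame(sv_id = catalog$id, distance = distance,
                    stringsAsFactors = FALSE)
  test <- NULL
  if (!is.null(te_labels)) {
    d <- merge(res, te_labels[, c("sv_id", "status")], by = "sv_id")
    d <- d[d$status %in% c("te", "non-te") & !is.na(d$distance), ]
    if (length(unique(d$status)) == 2 && all(table(d$status) >= 2)) {
      wt <- stats::wilcox.test(distance ~ status, data = d,
                               alternative = "two.sided", exact = FALSE)
      med <- tapply(d$distance, d$status, stats::median)
      test <- list(median_te = unname(med["te"]),
                   median_non_te = unname(med["non-te"]),
                   W = unname(wt$statistic), p = wt$p.value)
    }
  }
  list(distances = res, test = test)
}
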