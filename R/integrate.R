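#' Filter a differential-expression table to DEGs
#'
#' Keeps genes with |log2fc| strictly above `lfc_threshold` and adjusted p
#' strictly below `padj_threshold`, and reports up/down counts. Idempotent:
#' filtering a filtered table changes nothing.
#'
#' @param de_table data.frame with `gene`, `log2fc`, `padj`.
#' @param lfc_threshold,padj_threshold strict thresholds.
#' @return list `degs` (filtered table with a `direction` column),
#'   `n_up`, `n_down`, `n_total`.
#' @export
filter_degs <- function(de_table, lfc_threshold = 0.59,
                        padj_threshold = 0.05) {
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(de_table)))
    stop("de_table must have columns ", paste(need, collapse = ", "))
  keep <- !is.na(de_table$log2fc) & !is.na(de_table$padj) &
    abs(de_table$log2fc) > lfc_threshold & de_table$padj < padj_threshold
  degs <- de_table[keep, , drop = FALSE]
  degs$direction <- ifelse(degs$log2fc > 0, "up", "down")
  rownames(degs) <- NULL
  list(degs = degs, n_up = sum(degs$direction == "up"),
       n_down = sum(degs$direction == "down"), n_total = nrow(degs))
}

#' Simple two-group differential-expression test for synthetic counts
#'
#' A deliberately plain stand-in for a full DE model, adequate for the
#' bundled negative-binomial simulations: median-of-ratios normalization
#' (size factor = median across genes of count / geometric mean), a
#' per-gene two-sided Wilcoxon rank-sum test on normalized counts, BH
#' adjustment, and a log2 fold-change of group means with a 0.5
#' pseudocount.
#'
#' @param counts genes x samples integer matrix.
#' @param groups factor of length ncol(counts) with two levels; fold
#'   change is level2 / level1.
#' @return data.frame `gene`, `base_mean`, `log2fc`, `p`, `padj`.
#' @export
stand_in_de_test <- function(counts, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  sf <- median_of_ratios(counts)
  norm <- sweep(counts, 2, sf, "/")
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  # exact rank-sum when group sizes permit (power matters at RNA-seq
  # replicate counts); falls back to the normal approximation on ties
  p <- apply(norm, 1, function(x)
    suppressWarnings(
      stats::wilcox.test(x[g2], x[g1], correct = TRUE)$p.value))
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  data.frame(gene = rownames(counts), base_mean = rowMeans(norm),
             log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
             p = p, padj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

median_of_ratios <- function(counts) {
  logs <- log(counts)
  ok <- is.finite(rowSums(logs))
  if (!any(ok)) stop("no gene has all-positive counts; cannot normalize")
  geo <- exp(rowMeans(logs[ok, , drop = FALSE]))
  apply(counts[ok, , drop = FALSE], 2, function(col) stats::median(col / geo))
}

#' Candidate SVs: stratified loci near differentially expressed genes
#'
#' An SV qualifies when it is in the selected (top-fraction) set and its
#' interval intersects a DEG's gene interval expanded by `window` bp on
#' both sides (half-open semantics, strand ignored).
#'
#' @param selected_loci data.frame `id`, `chrom`, `start`, `end` of
#'   selected SVs.
#' @param degs DEG table (from [filter_degs()]`$degs` or any data.frame
#'   with a `gene` column).
#' @param annotation an `annotation_set` (gene coordinates).
#' @param window bp added on each side of the gene.
#' @return data.frame `sv_id`, `gene_id`, `distance` (bp between SV and
#'   unexpanded gene; 0 if overlapping).
#' @export
candidate_svs <- function(selected_loci, degs, annotation, window = 5000) {
  genes <- annotation$genes
  deg_genes <- genes[genes$gene_id %in% degs$gene, , drop = FALSE]
  if (nrow(selected_loci) == 0 || nrow(deg_genes) == 0)
    return(data.frame(sv_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  ov <- overlap_genes(selected_loci, deg_genes, window = window)
  if (nrow(ov) == 0)
    return(data.frame(sv_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  gr_l <- df_to_granges(selected_loci[match(ov$locus, selected_loci$id), ])
  gr_g <- df_to_granges(deg_genes[match(ov$gene_id, deg_genes$gene_id), ])
  dist <- GenomicRanges::distance(gr_l, gr_g)
  data.frame(sv_id = ov$locus, gene_id = ov$gene_id,
             distance = as.numeric(dist), stringsAsFactors = FALSE)
}

#' Overlap candidate SVs with differential chromatin peaks
#'
#' Half-open interval intersection; touching intervals (SV end equal to
#' peak start) do not overlap.
#'
#' @param candidates data.frame `id` (or `sv_id`), `chrom`, `start`, `end`.
#' @param peaks data.frame `chrom`, `start`, `end` (0-based half-open).
#' @return the candidates with `peak_support` (logical) and `peak_overlap`
#'   (bp of the largest overlap, 0 if none).
#' @export
sv_peak_overlap <- function(candidates, peaks) {
  out <- candidates
  out$peak_support <- FALSE
  out$peak_overlap <- 0
  if (nrow(candidates) == 0 || is.null(peaks) || nrow(peaks) == 0)
    return(out)
  gr_c <- df_to_granges(candidates)
  gr_p <- df_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_p)
  if (length(hits)) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      gr_c[S4Vectors::queryHits(hits)], gr_p[S4Vectors::subjectHits(hits)]))
    best <- tapply(w, S4Vectors::queryHits(hits), max)
    idx <- as.integer(names(best))
    out$peak_support[idx] <- TRUE
    out$peak_overlap[idx] <- as.numeric(best)
  }
  out
}

#' Expression dosage-effect test: genes with vs without SVs in
#' functional regions
#'
#' For each tissue (column group), compares the expression of genes whose
#' region label marks an SV in a functional element (2-kb flanks, intron,
#' exon, splice region, UTRs) against genes without such SVs, with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param expression genes x tissues numeric matrix (e.g. FPKM).
#' @param region_annotation output of [annotate_region()]; genes named in
#'   `nearest_gene` with a functional `region` label form the with-SV set.
#' @param functional_regions region labels counted as functional.
#' @return data.frame per tissue: group sizes, medians, W, `p`,
#'   `direction` ("down" when the with-SV median is lower). Tissues where
#'   either group has < 2 genes are skipped with a warning.
#' @export
dosage_expression_test <- function(expression, region_annotation,
    functional_regions = c("upstream2kb", "downstream2kb", "intron",
                           "exon", "splice_region", "utr5", "utr3")) {
  hit <- region_annotation$region %in% functional_regions
  sv_genes <- unique(region_annotation$nearest_gene[hit])
  with_sv <- rownames(expression) %in% sv_genes
  rows <- list()
  for (tissue in colnames(expression)) {
    x <- expression[with_sv, tissue]
    y <- expression[!with_sv, tissue]
    if (length(x) < 2 || length(y) < 2) {
      warning("tissue ", tissue, " skipped: a group has < 2 genes")
      next
    }
    wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
    rows[[tissue]] <- data.frame(
      tissue = tissue, n_with_sv = length(x), n_without = length(y),
      median_with_sv = stats::median(x), median_without = stats::median(y),
      W = unname(wt$statistic), p = wt$p.value,
      direction = if (stats::median(x) < stats::median(y)) "down" else "up",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

#' Compare carrier frequencies of a variant between two populations
#'
#' Carrier frequency is the fraction of samples carrying at least one
#' alternate allele (dominant coding, the default), only homozygotes
#' (`"recessive"`), or the allele frequency itself (`"allelic"`). The two
#' populations are contrasted with a two-sided Fisher exact test on the
#' carrier / non-carrier (or allele-count) 2x2 table.
#'
#' @param dosages named vector of dosages (0/1/2/NA), names = samples.
#' @param popmap data.frame `sample`, `population`.
#' @param pops length-2 character: (target, reference) population names.
#' @param coding `"carrier"`, `"recessive"` or `"allelic"`.
#' @return list per population `frequency` (percent), `counts`
#'   (2x2 table), `p` (Fisher exact, two-sided).
#' @export
genotype_frequency_compare <- function(dosages, popmap,
                                       pops, coding = c("carrier",
                                                        "recessive",
                                                        "allelic")) {
  coding <- match.arg(coding)
  if (length(pops) != 2) stop("pops must name two populations")
  pop <- popmap$population[match(names(dosages), popmap$sample)]
  tab <- matrix(0, 2, 2, dimnames = list(pops, c("carrier", "non_carrier")))
  for (i in 1:2) {
    d <- dosages[pop == pops[i]]
    d <- d[!is.na(d)]
    if (length(d) == 0) stop("no genotyped samples in population ", pops[i])
    hits <- switch(coding,
                   carrier = sum(d >= 1),
                   recessive = sum(d == 2),
                   allelic = sum(d))
    total <- if (coding == "allelic") 2 * length(d) else length(d)
    tab[i, ] <- c(hits, total - hits)
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(frequency_percent = stats::setNames(
         100 * tab[, 1] / rowSums(tab), pops),
       counts = tab, p = ft$p.value, coding = coding)
}
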