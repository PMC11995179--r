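#' Per-population allele frequencies from a dosage matrix
#'
#' Alternate-allele frequency p = (sum of non-missing dosages) /
#' (2 x non-missing samples) per population and locus. Loci whose overall
#' missing rate exceeds `max_missing`, or with zero non-missing samples
#' in any population, are excluded and listed in the `dropped` element.
#'
#' @param genotypes list with `dosage` (samples x loci, values 0/1/2/NA)
#'   and `loci` (data.frame with `id`), as produced by
#'   [simulate_population_genotypes()].
#' @param popmap data.frame `sample`, `population`.
#' @param max_missing per-locus missing-rate cap.
#' @return list `freq` (loci x populations matrix), `n_eff` (non-missing
#'   sample counts, same shape), `loci` (retained locus table),
#'   `dropped` (data.frame `id`, `reason`).
#' @export
allele_frequencies <- function(genotypes, popmap, max_missing = 0.5) {
  X <- genotypes$dosage
  if (is.null(rownames(X))) stop("dosage matrix must have sample rownames")
  if (!all(rownames(X) %in% popmap$sample))
    stop("every genotyped sample must appear in the population map")
  pop <- popmap$population[match(rownames(X), popmap$sample)]
  pops <- unique(pop)
  if (any(table(pop) < 2)) stop("each population needs n >= 2 samples")

  freq <- n_eff <- matrix(NA_real_, nrow = ncol(X), ncol = length(pops),
                          dimnames = list(colnames(X), pops))
  for (pn in pops) {
    sub <- X[pop == pn, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    n_eff[, pn] <- n_ok
    freq[, pn] <- ifelse(n_ok > 0, colSums(sub, na.rm = TRUE) / (2 * n_ok), NA)
  }
  miss <- colMeans(is.na(X))
  bad_missing <- miss > max_missing
  bad_empty <- apply(n_eff, 1, function(r) any(r == 0))
  keep <- !(bad_missing | bad_empty)
  dropped <- data.frame(
    id = colnames(X)[!keep],
    reason = ifelse(bad_missing[!keep], "missing_rate", "empty_population"),
    stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(nrow(dropped), " locus/loci dropped: ",
            paste(utils::head(dropped$id, 5), collapse = ", "),
            if (nrow(dropped) > 5) ", ..." else "")
  loci <- genotypes$loci
  if (!is.null(loci)) loci <- loci[match(colnames(X)[keep], loci$id), ]
  list(freq = freq[keep, , drop = FALSE],
       n_eff = n_eff[keep, , drop = FALSE],
       loci = loci, dropped = dropped)
}

#' Per-locus pairwise FST
#'
#' Default is a frequency-only estimator,
#' FST = (p1 - p2)^2 / (p1 + p2 - 2 p1 p2), defined as 0 where the
#' denominator vanishes (both populations fixed); it lies in [0, 1] by
#' construction. A Weir–Cockerham estimator with sample-size correction is
#' available for sensitivity analysis; its values are clipped to [0, 1].
#'
#' @param freq loci x populations frequency matrix (or the list returned
#'   by [allele_frequencies()]).
#' @param n_eff matching matrix of per-population sample counts (needed
#'   for `estimator = "wc"`).
#' @param estimator `"hudson"` (frequency-only) or `"wc"`.
#' @return list `fst` (loci x pairs matrix, columns "popA|popB"),
#'   `pairs` (2-column character matrix).
#' @export
pairwise_fst <- function(freq, n_eff = NULL, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  if (is.list(freq) && !is.matrix(freq)) {
    if (is.null(n_eff)) n_eff <- freq$n_eff
    freq <- freq$freq
  }
  pops <- colnames(freq)
  if (length(pops) < 2) stop("need at least two populations")
  combos <- utils::combn(pops, 2)
  fst <- matrix(NA_real_, nrow = nrow(freq), ncol = ncol(combos),
                dimnames = list(rownames(freq),
                                paste(combos[1, ], combos[2, ], sep = "|")))
  for (j in seq_len(ncol(combos))) {
    p1 <- freq[, combos[1, j]]; p2 <- freq[, combos[2, j]]
    if (estimator == "hudson") {
      den <- p1 + p2 - 2 * p1 * p2
      fst[, j] <- ifelse(den > 0, (p1 - p2)^2 / den, 0)
    } else {
      if (is.null(n_eff)) stop("Weir-Cockerham needs sample sizes (n_eff)")
      n1 <- n_eff[, combos[1, j]]; n2 <- n_eff[, combos[2, j]]
      nbar <- (n1 + n2) / 2
      nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
      a <- nbar / nc * (s2 - 1 / (2 * nbar - 1) *
                          (pbar * (1 - pbar) - s2 / 2))
      b <- nbar / (2 * nbar - 1) * (pbar * (1 - pbar) - s2 / 2)
      est <- ifelse(a + b > 0, a / (a + b), 0)
      fst[, j] <- pmin(1, pmax(0, est))
    }
  }
  list(fst = fst, pairs = combos)
}

#' The di statistic: summed standardized FST against a target population
#'
#' For locus l, di(l) = sum over population pairs (target, j) of
#' (FST_l - mean_pair) / sd_pair, where the mean and sd are taken across
#' all loci for that pair. High di marks loci unusually differentiated
#' between the target population and everything else. Pairs with zero sd
#' contribute nothing. With a single pair, di is simply standardized FST.
#'
#' @param fst result of [pairwise_fst()] (or its `fst` matrix).
#' @param target target population name.
#' @param sd_denom `"n-1"` (sample sd, default) or `"n"`.
#' @return numeric vector of di scores, named by locus.
#' @export
di_score <- function(fst, target, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  if (is.list(fst) && !is.matrix(fst)) fst <- fst$fst
  if (nrow(fst) < 2) stop("need >= 2 loci to standardize FST")
  pops_in <- strsplit(colnames(fst), "|", fixed = TRUE)
  use <- vapply(pops_in, function(p) target %in% p, logical(1))
  if (!any(use)) stop("target population '", target, "' not in any pair")
  di <- rep(0, nrow(fst))
  for (j in which(use)) {
    x <- fst[, j]
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (sd_denom == "n") {
      n_ok <- sum(!is.na(x))
      s <- s * sqrt((n_ok - 1) / n_ok)
    }
    if (is.na(s) || s == 0) next
    di <- di + ifelse(is.na(x), 0, (x - mu) / s)
  }
  stats::setNames(di, rownames(fst))
}

#' Select the top fraction of scored loci
#'
#' Threshold is the k-th largest score with k = ceiling(q * n)
#' (nearest-rank); every locus scoring at or above the threshold is
#' selected, so ties at the cut are included and at least ceiling(q * n)
#' loci are always returned.
#'
#' @param scores named numeric vector (e.g. di scores).
#' @param q fraction to select.
#' @return list `selected` (names), `threshold`, `q`, `n_selected`.
#' @export
select_top_fraction <- function(scores, q = 0.05) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  n <- length(scores)
  if (n * q < 1) stop("too few loci for q = ", q)
  k <- ceiling(q * n)
  threshold <- sort(scores, decreasing = TRUE)[k]
  sel <- names(scores)[scores >= threshold]
  list(selected = sel, threshold = threshold, q = q, n_selected = length(sel))
}

#' Overlap selected loci with gene models
#'
#' An SV locus overlaps a gene when their half-open intervals intersect
#' after expanding the gene by `window` bp on both sides.
#'
#' @param loci data.frame `id`, `chrom`, `start`, `end` (0-based
#'   half-open; point loci may have end == start).
#' @param annotation an `annotation_set` (or a `genes` data.frame).
#' @param window expansion (bp) applied to each gene.
#' @return data.frame `locus`, `gene_id` (one row per overlapping pair;
#'   zero rows when nothing overlaps).
#' @export
overlap_genes <- function(loci, annotation, window = 0) {
  genes <- if (inherits(annotation, "annotation_set")) annotation$genes
           else annotation
  if (nrow(loci) == 0)
    return(data.frame(locus = character(0), gene_id = character(0)))
  gr_l <- df_to_granges(loci)
  gexp <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$start - window),
                     end = genes$end + window)
  gr_g <- df_to_granges(gexp)
  hits <- GenomicRanges::findOverlaps(gr_l, gr_g)
  data.frame(locus = loci$id[S4Vectors::queryHits(hits)],
             gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Run the full stratification scan
#'
#' Convenience wrapper: frequencies, pairwise FST, di against the target
#' population, top-fraction selection, and (optionally) gene overlap of
#' the selected loci.
#'
#' @inheritParams allele_frequencies
#' @inheritParams di_score
#' @inheritParams select_top_fraction
#' @param annotation optional `annotation_set` for gene overlap.
#' @param estimator FST estimator, see [pairwise_fst()].
#' @return list with `table` (per-locus chrom/pos/type, frequencies, FSTs,
#'   di, selected flag), `threshold`, `selected`, `genes` (overlap table
#'   or NULL).
#' @export
di_scan <- function(genotypes, popmap, target, q = 0.05,
                    estimator = "hudson", annotation = NULL,
                    max_missing = 0.5) {
  af <- allele_frequencies(genotypes, popmap, max_missing)
  fst <- pairwise_fst(af, estimator = estimator)
  di <- di_score(fst, target)
  sel <- select_top_fraction(di, q)
  tab <- data.frame(af$loci, af$freq, fst$fst, di = di,
                    selected = names(di) %in% sel$selected,
                    check.names = FALSE, stringsAsFactors = FALSE)
  genes <- NULL
  if (!is.null(annotation)) {
    loci_sel <- af$loci[af$loci$id %in% sel$selected, , drop = FALSE]
    if (is.null(loci_sel$end)) loci_sel$end <- loci_sel$start
    genes <- overlap_genes(loci_sel, annotation)
  }
  list(table = tab, threshold = sel$threshold, selected = sel$selected,
       genes = genes)
}
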