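#' Simulate negative-binomial expression counts with planted DEGs
#'
#' Two groups (control / stress) of `n_expr_reps` samples each. A
#' `deg_fraction` of genes carries a multiplicative effect of
#' `2^deg_log2fc` (sign random) in the stress group. When a table of
#' selected SVs is supplied, genes lying within `window` bp of a selected
#' SV are planted as DEGs first, so downstream SV–DEG integration has
#' recoverable signal; remaining DEG slots are filled at random.
#'
#' @param config a [sim_config()] object.
#' @param annotation an `annotation_set` (gene models provide gene ids and
#'   coordinates).
#' @param selected_svs optional data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) of SVs that should sit near planted DEGs.
#' @param window distance (bp) within which a gene counts as "near" a
#'   selected SV.
#' @return list `counts` (genes x samples integer matrix), `groups`
#'   (factor control/stress), `truth` (data.frame `gene`, `log2fc` of
#'   planted effects; zero rows when `deg_fraction = 0`).
#' @export
simulate_expression <- function(config, annotation, selected_svs = NULL,
                                window = 5000) {
  validate_sim_config(config)
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  genes <- annotation$genes
  withr_seed(child_seed(config, "expression"), {
    n_gene <- nrow(genes)
    n_rep <- config$n_expr_reps
    groups <- factor(rep(c("control", "stress"), each = n_rep),
                     levels = c("control", "stress"))
    samples <- paste0(rep(c("ctl", "str"), each = n_rep),
                      rep(seq_len(n_rep), 2))
    mu <- stats::rlnorm(n_gene, meanlog = log(300), sdlog = 1.0) + 10

    n_deg <- round(config$deg_fraction * n_gene)
    near <- character(0)
    if (!is.null(selected_svs) && nrow(selected_svs) > 0) {
      gr_g <- GenomicRanges::GRanges(genes$chrom,
        IRanges::IRanges(pmax(1, genes$start + 1 - window),
                         genes$end + window))
      gr_s <- GenomicRanges::GRanges(selected_svs$chrom,
        IRanges::IRanges(selected_svs$start + 1,
                         pmax(selected_svs$end, selected_svs$start + 1)))
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_g, gr_s)))
      near <- genes$gene_id[hit]
    }
    deg <- head(c(sample(near), sample(setdiff(genes$gene_id, near))), n_deg)
    lfc <- stats::setNames(rep(0, n_gene), genes$gene_id)
    if (n_deg > 0)
      lfc[deg] <- config$deg_log2fc * sample(c(-1, 1), n_deg, replace = TRUE)

    size <- 1 / config$nb_dispersion
    counts <- matrix(0L, nrow = n_gene, ncol = 2 * n_rep,
                     dimnames = list(genes$gene_id, samples))
    mu_mat <- outer(mu, rep(1, 2 * n_rep))
    mu_mat[, groups == "stress"] <- mu_mat[, groups == "stress"] *
      2^lfc[genes$gene_id]
    counts[] <- stats::rnbinom(length(mu_mat), mu = mu_mat, size = size)
    truth <- data.frame(gene = deg, log2fc = unname(lfc[deg]),
                        stringsAsFactors = FALSE)
    list(counts = counts, groups = groups, samples = samples, truth = truth)
  })
}
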