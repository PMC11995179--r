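#' Simulate population SV genotypes with planted divergence
#'
#' For each biallelic locus, draws a baseline alternate-allele frequency
#' from Beta(0.8, 0.8) (a U-shaped folded spectrum typical of SVs) shared
#' by all populations. A `divergent_fraction` of loci instead gets the
#' target population's frequency forced at least `divergent_min_dp` apart
#' from the frequency shared by the remaining populations. Genotypes are
#' independent Hardy–Weinberg draws; dosages are 0/1/2 with optional
#' missingness.
#'
#' @param config a [sim_config()] object (populations, target population,
#'   divergence settings and missingness are read from it).
#' @param sv_catalog data.frame of biallelic loci with columns `id`,
#'   `chrom`, `start` and (optionally) `svtype`. TRA records are used as-is;
#'   callers typically pass DEL/INS/INV loci.
#' @return list with `genotypes` (list `dosage`: samples x loci integer
#'   matrix with NA for missing; `loci`: the locus table), `popmap`
#'   (data.frame `sample`, `population`) and `truth` (`divergent_loci`
#'   ids and the planted per-population frequency table).
#' @export
simulate_population_genotypes <- function(config, sv_catalog) {
  validate_sim_config(config)
  if (!all(c("id", "chrom", "start") %in% names(sv_catalog)))
    stop("sv_catalog needs id, chrom, start columns")
  pops <- config$populations
  withr_seed(child_seed(config, "genotypes"), {
    m <- nrow(sv_catalog)
    pop_names <- names(pops)
    target <- config$target_population
    p <- matrix(NA_real_, nrow = m, ncol = length(pops),
                dimnames = list(NULL, pop_names))
    base <- stats::rbeta(m, 0.8, 0.8)
    for (pn in pop_names) p[, pn] <- base

    n_div <- round(config$divergent_fraction * m)
    div_idx <- sort(sample.int(m, n_div))
    if (n_div > 0) {
      d <- stats::runif(n_div, config$divergent_min_dp,
                        min(0.96, config$divergent_min_dp + 0.3))
      lo <- stats::runif(n_div, 0.02, 0.98 - d)
      hi <- lo + d
      target_high <- stats::runif(n_div) < 0.5
      p_target <- ifelse(target_high, hi, lo)
      p_other <- ifelse(target_high, lo, hi)
      for (pn in pop_names)
        p[div_idx, pn] <- if (pn == target) p_target else p_other
    }

    samples <- unlist(lapply(pop_names, function(pn)
      sprintf("%s_%03d", pn, seq_len(pops[[pn]]))))
    popmap <- data.frame(sample = samples,
                         population = rep(pop_names, pops),
                         stringsAsFactors = FALSE)
    dosage <- matrix(NA_integer_, nrow = length(samples), ncol = m,
                     dimnames = list(samples, sv_catalog$id))
    for (pn in pop_names) {
      rows <- which(popmap$population == pn)
      dosage[rows, ] <- matrix(
        stats::rbinom(length(rows) * m, 2L, rep(p[, pn], each = length(rows))),
        nrow = length(rows))
    }
    if (config$missingness > 0) {
      miss <- stats::runif(length(dosage)) < config$missingness
      dosage[miss] <- NA_integer_
    }
    planted <- data.frame(id = sv_catalog$id, p, check.names = FALSE,
                          stringsAsFactors = FALSE)
    list(genotypes = list(dosage = dosage, loci = sv_catalog),
         popmap = popmap,
         truth = list(divergent_loci = sv_catalog$id[div_idx],
                      planted_freq = planted))
  })
}

#' Simulate a combined SNP + SV marker panel for one population
#'
#' Emulates the genotyped marker set of a mapping population (for example
#' an F2 cross): `n_snp` SNP markers and `n_sv` SV markers interleaved
#' along the toy chromosomes, allele frequencies uniform on [0.1, 0.9],
#' Hardy–Weinberg dosages.
#'
#' @param config a [sim_config()] object.
#' @param n_samples number of individuals.
#' @param n_snp,n_sv marker counts per class.
#' @return list `dosage` (samples x markers), `map` (marker, chrom, pos,
#'   class).
#' @export
simulate_marker_panel <- function(config, n_samples = 540L,
                                  n_snp = 1000L, n_sv = 150L) {
  validate_sim_config(config)
  withr_seed(child_seed(config, "genotypes") + 7L, {
    m <- n_snp + n_sv
    chrom <- sprintf("chr%d", sample.int(config$n_chromosomes, m,
                                         replace = TRUE))
    pos <- floor(stats::runif(m, 1, config$chrom_length))
    cls <- sample(rep(c("SNP", "SV"), c(n_snp, n_sv)))
    map <- data.frame(
      marker = ifelse(cls == "SNP",
                      sprintf("snp%06d", cumsum(cls == "SNP")),
                      sprintf("svm%06d", cumsum(cls == "SV"))),
      chrom = chrom, pos = pos, class = cls, stringsAsFactors = FALSE)
    map <- map[order(map$chrom, map$pos), ]
    rownames(map) <- NULL
    p <- stats::runif(m, 0.1, 0.9)
    dosage <- matrix(stats::rbinom(n_samples * m, 2L, rep(p, each = n_samples)),
                     nrow = n_samples,
                     dimnames = list(sprintf("ind_%04d", seq_len(n_samples)),
                                     map$marker))
    list(dosage = dosage, map = map)
  })
}

#' Simulate additive phenotypes at a target heritability
#'
#' Picks `n_qtl` causal loci (optionally restricted to one marker class,
#' e.g. SV-only QTLs whose signal is invisible to a SNP panel), assigns
#' standard-normal additive effects, and adds an environmental residual
#' orthogonalised against the genetic values and rescaled so the realized
#' genetic-variance fraction equals `h2` exactly (up to floating point).
#'
#' @param config a [sim_config()] object (`h2`, `n_qtl`).
#' @param genotypes either the `genotypes` element returned by
#'   [simulate_population_genotypes()] or a panel from
#'   [simulate_marker_panel()]; anything with a `dosage` matrix.
#' @param qtl_class optional marker class ("SNP"/"SV") to restrict QTLs to;
#'   requires a `map` with a `class` column.
#' @return list `phenotypes` (data.frame `sample`, `value`), `truth`
#'   (data.frame `locus`, `beta`; plus the realized heritability).
#' @export
simulate_phenotypes <- function(config, genotypes, qtl_class = NULL) {
  validate_sim_config(config)
  X <- genotypes$dosage
  if (is.null(X)) stop("genotypes must carry a dosage matrix")
  withr_seed(child_seed(config, "phenotypes"), {
    candidates <- colnames(X)
    if (!is.null(qtl_class)) {
      map <- genotypes$map
      if (is.null(map$class)) stop("qtl_class given but panel has no map")
      candidates <- map$marker[map$class == qtl_class]
    }
    n_qtl <- min(config$n_qtl, length(candidates))
    qtl <- sample(candidates, n_qtl)
    beta <- stats::rnorm(n_qtl)
    Xq <- X[, qtl, drop = FALSE]
    Xq[is.na(Xq)] <- matrix(rep(colMeans(Xq, na.rm = TRUE),
                                each = nrow(Xq)), nrow = nrow(Xq))[is.na(Xq)]
    g <- as.vector(Xq %*% beta)
    h2 <- config$h2
    if (h2 >= 1 || stats::var(g) == 0) {
      y <- g
      if (h2 < 1) y <- stats::rnorm(nrow(X))   # no genetic variance at all
    } else if (h2 <= 0) {
      y <- stats::rnorm(nrow(X))
      g <- g * 0
    } else {
      e <- stats::rnorm(nrow(X))
      e <- stats::residuals(stats::lm(e ~ g))          # exact orthogonality
      e <- e / stats::sd(e) * sqrt(stats::var(g) * (1 - h2) / h2)
      y <- g + e
    }
    realized <- if (stats::var(y) > 0) stats::var(g) / stats::var(y) else NA
    list(phenotypes = data.frame(sample = rownames(X), value = y,
                                 stringsAsFactors = FALSE),
         truth = list(qtl = data.frame(locus = qtl, beta = beta,
                                       stringsAsFactors = FALSE),
                      genetic_values = g,
                      realized_h2 = realized))
  })
}
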