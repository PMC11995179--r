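#' Simulation configuration
#'
#' Builds the single configuration object consumed by every `simulate_*()`
#' generator. Defaults emulate the design of a multi-breed pig pan-genome
#' study: 14 assemblies, gene families split into core / dispensable /
#' private classes, four structural-variant (SV) types dominated by
#' deletions and insertions, and a three-population genotype panel
#' (cold-region, hot-region, commercial) with a small fraction of loci
#' carrying planted allele-frequency divergence.
#'
#' One global `seed` feeds per-stage child seeds derived by fixed offsets,
#' so a stage's output is reproducible even when the configuration of an
#' unrelated stage changes.
#'
#' @param seed integer seed driving all randomness.
#' @param n_genomes number of genomes in the presence/absence matrix.
#' @param n_families number of gene families.
#' @param class_props named numeric of length 3 (`core`, `dispensable`,
#'   `private`); must sum to 1.
#' @param n_chromosomes,chrom_length chromosome count and length (bp) of the
#'   toy reference.
#' @param n_genes,n_te number of gene models and TE intervals to simulate.
#' @param n_sv number of true structural variants underlying the two callsets.
#' @param sv_type_props named numeric of length 4 (`DEL`, `INS`, `INV`,
#'   `TRA`); must sum to 1.
#' @param shared_fraction fraction of true SVs present in both callsets.
#' @param jitter_bp maximum absolute breakpoint jitter (bp) applied to the
#'   second callset's records; additionally capped at 30% of the SV length so
#'   jittered pairs stay within the default merge tolerances.
#' @param populations named integer vector, population name -> sample count.
#' @param target_population population contrasted against the others in the
#'   stratification scan; divergence is planted between it and the rest.
#' @param divergent_fraction fraction of SV loci with planted divergence
#'   (|delta p| >= `divergent_min_dp`).
#' @param divergent_min_dp minimum planted allele-frequency difference.
#' @param missingness per-genotype missing rate in the genotype matrix.
#' @param h2 narrow-sense heritability of the simulated phenotype.
#' @param n_qtl number of additive QTLs.
#' @param n_expr_reps samples per expression group (control / stress).
#' @param deg_fraction fraction of genes planted as differentially expressed.
#' @param deg_log2fc absolute planted log2 fold-change.
#' @param nb_dispersion negative-binomial dispersion (1/size) of counts.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1, n_families = 100)
#' cfg$class_props
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 14L,
                       n_families = 2000L,
                       class_props = c(core = 0.3894, dispensable = 0.6009,
                                       private = 0.0097),
                       n_chromosomes = 3L,
                       chrom_length = 5e6,
                       n_genes = 200L,
                       n_te = 400L,
                       n_sv = 1000L,
                       sv_type_props = c(DEL = 0.53, INS = 0.435,
                                         INV = 0.017, TRA = 0.018),
                       shared_fraction = 0.3,
                       jitter_bp = 20L,
                       populations = c(cold = 72L, hot = 112L,
                                       commercial = 62L),
                       target_population = NULL,
                       divergent_fraction = 0.05,
                       divergent_min_dp = 0.6,
                       missingness = 0,
                       h2 = 0.5,
                       n_qtl = 20L,
                       n_expr_reps = 10L,
                       deg_fraction = 0.05,
                       deg_log2fc = 2,
                       nb_dispersion = 0.1) {
  cfg <- list(
    seed = as.integer(seed),
    n_genomes = as.integer(n_genomes),
    n_families = as.integer(n_families),
    class_props = class_props,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes),
    n_te = as.integer(n_te),
    n_sv = as.integer(n_sv),
    sv_type_props = sv_type_props,
    shared_fraction = shared_fraction,
    jitter_bp = as.integer(jitter_bp),
    populations = populations,
    target_population = if (is.null(target_population)) names(populations)[1]
                        else target_population,
    divergent_fraction = divergent_fraction,
    divergent_min_dp = divergent_min_dp,
    missingness = missingness,
    h2 = h2,
    n_qtl = as.integer(n_qtl),
    n_expr_reps = as.integer(n_expr_reps),
    deg_fraction = deg_fraction,
    deg_log2fc = deg_log2fc,
    nb_dispersion = nb_dispersion
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.finite(cfg$seed))
  props_ok <- function(p, k) {
    length(p) == k && all(p >= 0) && all(p <= 1) && abs(sum(p) - 1) < 1e-9
  }
  if (!props_ok(cfg$class_props, 3L))
    stop("class_props must be 3 proportions in [0,1] summing to 1")
  if (!props_ok(cfg$sv_type_props, 4L))
    stop("sv_type_props must be 4 proportions in [0,1] summing to 1")
  if (!setequal(names(cfg$class_props), c("core", "dispensable", "private")))
    stop("class_props must be named core, dispensable, private")
  if (!setequal(names(cfg$sv_type_props), c("DEL", "INS", "INV", "TRA")))
    stop("sv_type_props must be named DEL, INS, INV, TRA")
  counts <- c(cfg$n_genomes, cfg$n_families, cfg$n_chromosomes,
              cfg$chrom_length, cfg$n_genes, cfg$n_te, cfg$n_sv,
              cfg$n_expr_reps)
  if (any(counts <= 0)) stop("counts must be positive")
  if (cfg$n_genomes < 3L)
    stop("n_genomes must be >= 3: with fewer genomes the core/dispensable/",
         "private classes are undefined")
  if (is.null(names(cfg$populations)) || any(!nzchar(names(cfg$populations))))
    stop("populations must be a named vector")
  if (any(cfg$populations < 2L))
    stop("each population needs n >= 2 samples")
  if (!(cfg$target_population %in% names(cfg$populations)))
    stop("target_population must be one of the population names")
  for (f in c("shared_fraction", "divergent_fraction", "missingness", "h2",
              "deg_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0,1]")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$n_qtl < 0) stop("n_qtl must be non-negative")
  invisible(cfg)
}

# Per-stage child seeds: fixed offsets off the global seed so each stage is
# reproducible on its own. Kept well below .Machine$integer.max.
child_seed <- function(cfg, stage) {
  offsets <- c(pangenome = 101L, annotation = 211L, sv = 307L,
               genotypes = 401L, phenotypes = 503L, expression = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (cfg$seed %% 2000000000L) + offsets[[stage]]
}

#' Largest-remainder apportionment of a total into integer counts
#'
#' Used to turn class proportions into family counts that sum exactly to
#' the total (exact closure, no drift from independent rounding).
#'
#' @param total integer total to apportion.
#' @param props proportions summing to 1.
#' @return integer vector of counts summing to `total`.
#' @keywords internal
largest_remainder <- function(total, props) {
  raw <- total * props
  base <- floor(raw)
  rem <- raw - base
  short <- total - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}
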