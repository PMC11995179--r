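test_that("sim_config validates proportions, counts and populations", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(class_props = c(core = 0.5, dispensable = 0.4,
                                          private = 0.2)), "summing to 1")
  expect_error(sim_config(n_genomes = 2), "n_genomes")
  expect_error(sim_config(populations = c(a = 1L, b = 50L)), "n >= 2")
  expect_error(sim_config(h2 = 1.5), "h2")
  expect_error(sim_config(nb_dispersion = 0), "positive")
})

test_that("pangenome generator hits exact class counts and truth", {
  cfg <- sim_config(seed = 5, n_families = 10000)
  sim <- simulate_pangenome(cfg)
  expect_equal(dim(sim$presence), c(14, 10000))
  # largest-remainder closure at the study proportions
  tab <- table(sim$truth$class)
  expect_equal(unname(tab[c("core", "dispensable", "private")]),
               c(3894, 6009, 97), ignore_attr = TRUE)
  occ <- colSums(sim$presence)
  expect_true(all(occ[sim$truth$class == "core"] == 14))
  expect_true(all(occ[sim$truth$class == "private"] == 1))
  expect_true(all(occ[sim$truth$class == "dispensable"] >= 2 &
                    occ[sim$truth$class == "dispensable"] <= 13))
})

test_that("degenerate all-core mix gives an all-ones matrix", {
  cfg <- sim_config(seed = 2, n_families = 10,
                    class_props = c(core = 1, dispensable = 0, private = 0))
  sim <- simulate_pangenome(cfg)
  expect_true(all(sim$presence == 1))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77, n_families = 200, n_genes = 30, n_te = 40,
                    n_sv = 150)
  expect_identical(simulate_pangenome(cfg), simulate_pangenome(cfg))
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  ann <- simulate_annotation(cfg)
  expect_identical(simulate_sv_callsets(cfg, ann),
                   simulate_sv_callsets(cfg, ann))
  expect_identical(simulate_expression(cfg, ann),
                   simulate_expression(cfg, ann))
})

test_that("annotation generator produces well-formed gene models", {
  cfg <- sim_config(seed = 9, n_genes = 40, n_te = 100)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 40)
  expect_equal(nrow(ann$te), 100)
  expect_true(all(ann$te$class %in% c("LTR", "non-LTR")))
  # every gene has >= 1 exon, all intervals inside bounds, no gene overlap
  expect_true(all(ann$genes$gene_id %in% ann$exons$gene_id))
  for (d in list(ann$genes, ann$exons, ann$cds, ann$utr5, ann$utr3, ann$te))
    expect_true(all(d$start >= 0 & d$end <= cfg$chrom_length &
                      d$start < d$end))
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start), ]
  same <- g$chrom[-1] == g$chrom[-nrow(g)]
  expect_true(all(g$start[-1][same] >= g$end[-nrow(g)][same]))
  # exons stay within their gene and UTRs at transcript ends
  ex <- merge(ann$exons, ann$genes, by = "gene_id",
              suffixes = c("", ".g"))
  expect_true(all(ex$start >= ex$start.g & ex$end <= ex$end.g))
})

test_that("annotation round-trips through GFF3 + BED", {
  cfg <- sim_config(seed = 13, n_genes = 25, n_te = 30)
  ann <- simulate_annotation(cfg)
  gff <- tempfile(fileext = ".gff3"); bed <- tempfile(fileext = ".bed")
  write_annotation(ann, gff, bed)
  ann2 <- read_annotation(gff, bed)
  srt <- function(d) {
    d <- d[order(d$chrom, d$start, d$end), ]
    rownames(d) <- NULL
    d
  }
  for (k in c("genes", "exons", "cds", "utr5", "utr3"))
    expect_equal(srt(ann2[[k]]), srt(ann[[k]]), ignore_attr = TRUE)
  expect_equal(srt(ann2$te)[c("chrom", "start", "end", "class")],
               srt(ann$te)[c("chrom", "start", "end", "class")],
               ignore_attr = TRUE)
})

test_that("annotation rejects genes that cannot fit the chromosome", {
  expect_error(simulate_annotation(
    sim_config(seed = 1, n_genes = 500, n_chromosomes = 1,
               chrom_length = 20000)), "chromosome too short|exceeds")
})

test_that("SV callsets share exactly the configured fraction", {
  cfg0 <- sim_config(seed = 21, n_sv = 300, shared_fraction = 0,
                     n_genes = 10)
  ann <- simulate_annotation(cfg0)
  sv0 <- simulate_sv_callsets(cfg0, ann)
  expect_equal(nrow(sv0$truth$pairs), 0)

  cfg1 <- sim_config(seed = 21, n_sv = 300, shared_fraction = 1,
                     jitter_bp = 0, n_genes = 10)
  sv1 <- simulate_sv_callsets(cfg1, ann)
  expect_equal(nrow(sv1$callset_a), 300)
  expect_equal(nrow(sv1$callset_b), 300)
  # jitter 0: each A record has an identical B partner
  a <- sv1$callset_a[order(sv1$callset_a$chrom, sv1$callset_a$start), ]
  b <- sv1$callset_b[order(sv1$callset_b$chrom, sv1$callset_b$start), ]
  expect_equal(a[c("chrom", "start", "end", "svtype", "length")],
               b[c("chrom", "start", "end", "svtype", "length")],
               ignore_attr = TRUE)
})

test_that("generated DEL+INS sizes have their mode in 101-500 bp", {
  cfg <- sim_config(seed = 31, n_sv = 2000, chrom_length = 1e7)
  ann <- simulate_annotation(cfg)
  sv <- simulate_sv_callsets(cfg, ann)
  cat_a <- sv$callset_a[sv$callset_a$svtype %in% c("DEL", "INS"), ]
  spec <- size_spectrum(cat_a)
  expect_equal(spec$modal_bin, "101-500")
  expect_gt(spec$fraction_lt_5kb, 0.85)
})

test_that("population genotypes reproduce planted frequencies", {
  cfg <- sim_config(seed = 41, n_sv = 400, divergent_fraction = 0.1)
  loci <- data.frame(id = sprintf("sv%04d", 1:400), chrom = "chr1",
                     start = seq(1000, by = 3000, length.out = 400),
                     svtype = "DEL")
  gt <- simulate_population_genotypes(cfg, loci)
  expect_equal(nrow(gt$popmap), 72 + 112 + 62)
  expect_equal(length(gt$truth$divergent_loci), 40)
  # sampled frequencies within 3 binomial SEs of the planted values
  af <- allele_frequencies(gt$genotypes, gt$popmap)
  for (pn in c("cold", "hot", "commercial")) {
    p <- gt$truth$planted_freq[[pn]]
    n <- 2 * sum(gt$popmap$population == pn)
    se <- sqrt(pmax(p * (1 - p), 1e-6) / n)
    expect_gt(mean(abs(af$freq[, pn] - p) <= 3 * se + 1e-9), 0.95)
  }
  # divergent loci really are far apart between target and the others
  div <- gt$truth$planted_freq[gt$truth$planted_freq$id %in%
                                 gt$truth$divergent_loci, ]
  expect_true(all(abs(div$cold - div$hot) >= 0.6 - 1e-9))

  cfg0 <- sim_config(seed = 41, divergent_fraction = 0)
  gt0 <- simulate_population_genotypes(cfg0, loci)
  expect_length(gt0$truth$divergent_loci, 0)
  expect_false(anyNA(gt0$genotypes$dosage))   # missingness = 0
})

test_that("phenotypes realize the requested heritability", {
  cfg <- sim_config(seed = 51, h2 = 0.5, n_qtl = 20)
  panel <- simulate_marker_panel(cfg, n_samples = 540, n_snp = 100,
                                 n_sv = 100)
  ph <- simulate_phenotypes(cfg, panel)
  expect_equal(ph$truth$realized_h2, 0.5, tolerance = 0.02)
  # regression of y on true genetic values recovers slope ~ 1
  fit <- lm(ph$phenotypes$value ~ ph$truth$genetic_values)
  expect_equal(unname(coef(fit)[2]), 1,
               tolerance = 3 * summary(fit)$coefficients[2, 2] + 0.05)

  # h2 = 0: phenotype independent of genotype (null correlation band)
  ph0 <- simulate_phenotypes(sim_config(seed = 51, h2 = 0), panel)
  r <- abs(cor(panel$dosage, ph0$phenotypes$value))
  expect_lt(mean(r > 3 / sqrt(540)), 0.05)

  # h2 = 1, single QTL: deterministic function of that locus dosage
  ph1 <- simulate_phenotypes(sim_config(seed = 51, h2 = 1, n_qtl = 1), panel)
  q <- ph1$truth$qtl$locus
  expect_equal(ph1$phenotypes$value,
               unname(panel$dosage[, q] * ph1$truth$qtl$beta))
})

test_that("expression generator plants recoverable fold changes", {
  cfg <- sim_config(seed = 61, n_genes = 80, deg_fraction = 0.1,
                    deg_log2fc = 2, nb_dispersion = 0.01,
                    n_expr_reps = 50)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  expect_equal(nrow(ex$truth), 8)
  m_ctl <- rowMeans(ex$counts[, ex$groups == "control"])
  m_str <- rowMeans(ex$counts[, ex$groups == "stress"])
  ratio <- (m_str[ex$truth$gene]) / (m_ctl[ex$truth$gene])
  expect_equal(unname(log2(ratio)), ex$truth$log2fc, tolerance = 0.1)

  ex0 <- simulate_expression(sim_config(seed = 61, n_genes = 80,
                                        deg_fraction = 0), ann)
  expect_equal(nrow(ex0$truth), 0)
})
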