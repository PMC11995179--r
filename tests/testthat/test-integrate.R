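test_that("DEG filter applies strict thresholds and is idempotent", {
  de <- data.frame(gene = paste0("g", 1:4),
                   log2fc = c(0.60, 0.59, -2.0, -1.0),
                   padj = c(0.01, 0.01, 0.05, 0.001))
  fd <- filter_degs(de)
  expect_equal(fd$degs$gene, c("g1", "g4"))      # 0.59 and padj=0.05 dropped
  expect_equal(fd$n_up, 1)
  expect_equal(fd$n_down, 1)
  expect_equal(fd$n_total, fd$n_up + fd$n_down)
  again <- filter_degs(fd$degs)
  expect_equal(again$degs$gene, fd$degs$gene)
})

test_that("stand-in DE test is calibrated and recovers planted effects", {
  cfg <- sim_config(seed = 81, n_genes = 100, deg_fraction = 0,
                    nb_dispersion = 0.05)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  de0 <- stand_in_de_test(ex$counts, ex$groups)
  expect_lt(mean(de0$padj < 0.05), 0.02)       # near-null on identical groups
  # BH monotonicity: padj non-decreasing in raw-p rank
  o <- order(de0$p)
  expect_true(all(diff(de0$padj[o]) >= -1e-12))

  cfg4 <- sim_config(seed = 82, n_genes = 100, deg_fraction = 0.1,
                     deg_log2fc = 2, nb_dispersion = 0.05, n_expr_reps = 12)
  ex4 <- simulate_expression(cfg4, ann)
  de4 <- stand_in_de_test(ex4$counts, ex4$groups)
  fd <- filter_degs(de4)
  recall <- mean(ex4$truth$gene %in% fd$degs$gene)
  expect_gt(recall, 0.9)
  # signed log2fc of a planted up-gene is close to the planted value
  up <- ex4$truth$gene[ex4$truth$log2fc > 0]
  expect_equal(mean(de4$log2fc[match(up, de4$gene)]), 2, tolerance = 0.3)
  expect_error(stand_in_de_test(ex4$counts, rep("a", ncol(ex4$counts))),
               "two levels")
})

test_that("candidate SVs require selection AND a DEG within the window", {
  ann <- toy_annotation()    # gene g1 = [10000, 14000)
  degs <- data.frame(gene = "g1")
  sel <- function(start, end)
    data.frame(id = "sv1", chrom = "chr1", start = start, end = end)
  # 4999 bp upstream of the gene start: candidate
  got <- candidate_svs(sel(5000, 5001), degs, ann)
  expect_equal(nrow(got), 1)
  expect_equal(got$distance, 4999)
  # 5001 bp away: not a candidate
  expect_equal(nrow(candidate_svs(sel(4998, 4999), degs, ann)), 0)
  # inside the gene but not selected (empty selection): nothing
  expect_equal(nrow(candidate_svs(sel(12000, 12100)[0, ], degs, ann)), 0)
  # non-DEG gene does not attract candidates
  expect_equal(nrow(candidate_svs(sel(12000, 12100),
                                  data.frame(gene = "other"), ann)), 0)
  # window = 0 reduces to strict overlap (half-open: touching is not enough)
  expect_equal(nrow(candidate_svs(sel(9999, 10001), degs, ann, window = 0)),
               1)
  expect_equal(nrow(candidate_svs(sel(9998, 10000), degs, ann, window = 0)),
               0)
})

test_that("peak overlap uses half-open semantics and reports overlap bp", {
  cand <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                     start = c(1000, 3000, 5000), end = c(1226, 3100, 5050))
  peaks <- data.frame(chrom = "chr1", start = c(900, 3100),
                      end = c(1500, 3200))
  res <- sv_peak_overlap(cand, peaks)
  expect_equal(res$peak_support, c(TRUE, FALSE, FALSE))  # b touches only
  expect_equal(res$peak_overlap[1], 226)                 # DEL inside peak
  empty <- sv_peak_overlap(cand, peaks[0, ])
  expect_false(any(empty$peak_support))
})

test_that("dosage-effect contrast detects expression downshift", {
  set.seed(5)
  expr <- matrix(rlnorm(200 * 2, log(10), 0.3), ncol = 2,
                 dimnames = list(paste0("g", 1:200),
                                 c("muscle", "liver")))
  with_sv <- paste0("g", 1:50)
  expr[with_sv, ] <- expr[with_sv, ] * 0.5
  ra <- data.frame(sv_id = paste0("s", 1:50), region = "intron",
                   nearest_gene = with_sv)
  res <- dosage_expression_test(expr, ra)
  expect_equal(res$direction, c("down", "down"))
  expect_true(all(res$p < 1e-4))
  # identical distributions: p near 1
  expr2 <- matrix(rep(rlnorm(100, log(10), 0.3), 2), ncol = 2,
                  dimnames = list(paste0("g", 1:100), c("t1", "t2")))
  ra2 <- data.frame(sv_id = "s", region = "intron",
                    nearest_gene = paste0("g", seq(2, 100, 2)))
  res2 <- dosage_expression_test(expr2[, 1, drop = FALSE], ra2)
  expect_gt(res2$p, 0.2)
  # intergenic SVs do not define the with-SV group
  ra3 <- data.frame(sv_id = "s", region = "intergenic",
                    nearest_gene = "g1")
  expect_warning(dosage_expression_test(expr2[, 1, drop = FALSE], ra3),
                 "skipped")
})

test_that("genotype-frequency contrast reproduces carrier arithmetic", {
  popmap <- data.frame(
    sample = c(sprintf("h%03d", 1:112), sprintf("c%03d", 1:62)),
    population = rep(c("hot", "commercial"), c(112, 62)))
  dos <- setNames(c(rep(1, 102), rep(0, 10), rep(1, 2), rep(0, 60)),
                  popmap$sample)
  res <- genotype_frequency_compare(dos, popmap, c("hot", "commercial"))
  expect_equal(round(unname(res$frequency_percent["hot"]), 2), 91.07)
  expect_equal(round(unname(res$frequency_percent["commercial"]), 2), 3.23)
  expect_lt(res$p, 1e-15)
  # extreme split matches the Fisher tail
  dos2 <- setNames(c(rep(2, 112), rep(0, 62)), popmap$sample)
  expect_lt(genotype_frequency_compare(dos2, popmap,
                                       c("hot", "commercial"))$p, 1e-15)
  # identical frequencies: p = 1
  dos3 <- setNames(c(rep(c(0, 1), 56), rep(c(0, 1), 31)), popmap$sample)
  expect_equal(genotype_frequency_compare(dos3, popmap,
                                          c("hot", "commercial"))$p, 1)
})

test_that("end-to-end: candidates recover planted DEGs next to planted
          divergent SVs", {
  for (seed in c(7, 8)) {
    cfg <- sim_config(seed = seed, n_genes = 200, n_sv = 1200,
                      deg_fraction = 0.1, divergent_fraction = 0.05,
                      chrom_length = 8e6)
    ann <- simulate_annotation(cfg)
    sv <- simulate_sv_callsets(cfg, ann)
    mg <- merge_callsets(sv$callset_a, sv$callset_b)
    cat_pav <- mg$catalog[mg$catalog$svtype != "TRA", ]
    gt <- simulate_population_genotypes(cfg, cat_pav)
    scan <- di_scan(gt$genotypes, gt$popmap, target = "cold", q = 0.05)
    sel <- cat_pav[cat_pav$id %in% scan$selected, ]
    ex <- simulate_expression(cfg, ann, selected_svs = sel)
    de <- stand_in_de_test(ex$counts, ex$groups)
    degs <- filter_degs(de)$degs
    cand <- candidate_svs(sel, degs, ann, window = 5000)
    # truth: (selected SV, planted DEG) pairs within the 5-kb window
    truth <- candidate_svs(sel, data.frame(gene = ex$truth$gene), ann,
                           window = 5000)
    # the generator must plant measurable adjacency for this design
    expect_gte(nrow(truth), 5)
    key <- function(d) paste(d$sv_id, d$gene_id)
    recall <- mean(key(truth) %in% key(cand))
    precision <- mean(key(cand) %in% key(truth))
    expect_gte(recall, 0.9)
    expect_gte(precision, 0.9)
  }
})
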