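test_that("merge collapses matching records by the type-specific rules", {
  a <- make_callset("chr1", c(1000, 5000, 9000), c(2000, 5000, 9300),
                    c("DEL", "INS", "INV"), "A", source = "alignment")
  a$length[a$svtype == "INS"] <- 120
  b <- a
  b$id <- sub("A", "B", b$id)
  b$source <- "reads"
  mg <- merge_callsets(a, b)
  expect_equal(nrow(mg$catalog), 3)
  expect_true(all(mg$catalog$sources == "alignment,reads"))

  # reciprocal overlap 900/1000 = 0.9 >= 0.5: merged
  a2 <- make_callset("chr1", 1000, 2000, "DEL", "A")
  b2 <- make_callset("chr1", 1100, 2100, "DEL", "B")
  expect_equal(nrow(merge_callsets(a2, b2)$catalog), 1)
  # reciprocal overlap 400/1000 < 0.5: kept apart
  b3 <- make_callset("chr1", 1600, 2600, "DEL", "B")
  expect_equal(nrow(merge_callsets(a2, b3)$catalog), 2)

  # DEL vs INS at the same locus never merge
  b4 <- make_callset("chr1", 1000, 1000, "INS", "B", length = 1000)
  expect_equal(nrow(merge_callsets(a2, b4)$catalog), 2)

  # INS: breakpoints within 100 bp AND size ratio >= 0.7
  a5 <- make_callset("chr1", 1000, 1000, "INS", "A", length = 100)
  b5 <- make_callset("chr1", 1090, 1090, "INS", "B", length = 80)
  expect_equal(nrow(merge_callsets(a5, b5)$catalog), 1)
  b6 <- make_callset("chr1", 1090, 1090, "INS", "B", length = 60)  # ratio 0.6
  expect_equal(nrow(merge_callsets(a5, b6)$catalog), 2)

  # collapsed records keep the first callset's coordinates
  mg2 <- merge_callsets(a2, b2)
  expect_equal(mg2$catalog$start, 1000)
  expect_equal(mg2$catalog$end, 2000)
})

test_that("merge validates input order, types and length floor", {
  a <- make_callset("chr1", c(5000, 1000), c(6000, 2000), c("DEL", "DEL"),
                    "A")
  unsorted <- a[nrow(a):1, ]
  expect_error(merge_callsets(unsorted, a), "sorted")
  bad <- make_callset("chr1", 100, 200, "DUP", "A")
  expect_error(merge_callsets(bad, a), "svtype")
  tiny <- make_callset("chr1", c(100, 1000), c(130, 2000), c("DEL", "DEL"),
                       "A")   # 30 bp record dropped on ingest
  mg <- merge_callsets(tiny, make_callset("chr1", 1000, 2000, "DEL", "B"))
  expect_equal(nrow(mg$catalog), 1)
})

test_that("merge satisfies conservation and symmetry invariants", {
  cfg <- sim_config(seed = 19, n_sv = 500)
  ann <- simulate_annotation(cfg)
  sv <- simulate_sv_callsets(cfg, ann)
  mg <- merge_callsets(sv$callset_a, sv$callset_b)
  expect_equal(nrow(mg$catalog),
               nrow(sv$callset_a) + nrow(sv$callset_b) -
                 nrow(mg$matched_pairs))
  expect_false(any(duplicated(stats::na.omit(mg$catalog$a_id))))
  expect_false(any(duplicated(stats::na.omit(mg$catalog$b_id))))
  swapped <- merge_callsets(sv$callset_b, sv$callset_a)
  expect_equal(nrow(swapped$catalog), nrow(mg$catalog))
  expect_equal(nrow(swapped$matched_pairs), nrow(mg$matched_pairs))
})

test_that("merge recovers the generator's identity truth exactly", {
  cfg <- sim_config(seed = 23, n_sv = 600, shared_fraction = 0.5)
  ann <- simulate_annotation(cfg)
  sv <- simulate_sv_callsets(cfg, ann)
  mg <- merge_callsets(sv$callset_a, sv$callset_b)
  got <- mg$matched_pairs[order(mg$matched_pairs$a_id), ]
  want <- sv$truth$pairs[order(sv$truth$pairs$a_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("merge equals the brute-force all-pairs matcher", {
  cfg <- sim_config(seed = 29, n_sv = 200, shared_fraction = 0.4)
  ann <- simulate_annotation(cfg)
  sv <- simulate_sv_callsets(cfg, ann)
  mg <- merge_callsets(sv$callset_a, sv$callset_b)
  oracle <- brute_force_merge(sv$callset_a, sv$callset_b)
  key <- function(d) sort(paste(d$a_id, d$b_id))
  expect_equal(key(mg$matched_pairs), key(oracle))
})

test_that("PAV composition reproduces the printed-count arithmetic", {
  pav <- classify_pav(c(DEL = 103083, INS = 84631, INV = 3161, TRA = 3359))
  expect_equal(round(pav$pav_percent, 2), 96.64)
  expect_equal(sum(pav$counts), 194234)

  only_inv <- data.frame(svtype = rep("INV", 5))
  expect_equal(classify_pav(only_inv)$pav_fraction, 0)
  expect_error(classify_pav(data.frame(svtype = character(0))), "empty")
})

test_that("size spectrum bins with inclusive upper edges", {
  s <- size_spectrum(c(60, 300, 300, 6000))
  expect_equal(s$bins$count, c(1, 2, 0, 0, 1))
  expect_equal(s$fraction_lt_5kb, 0.75)
  expect_equal(size_spectrum(rep(200, 10))$bins$fraction[2], 1)
  edge <- size_spectrum(c(500, 501))
  expect_equal(edge$bins$count[2:3], c(1, 1))
  expect_equal(sum(size_spectrum(c(60, 5001))$bins$fraction), 1)
  expect_error(size_spectrum(c(10, 60)), "50 bp")
})

test_that("region annotation follows the precedence and strand rules", {
  ann <- toy_annotation(strand = "+")   # exons [10000,11000) [13000,14000)
  sv <- make_callset("chr1",
                     c(10900, 11500, 8400, 10500),
                     c(11100, 11600, 8500, 10550),
                     c("DEL", "DEL", "DEL", "DEL"), "S")
  res <- annotate_region(sv, ann)
  # spanning the exon/intron junction -> splice_region wins
  expect_equal(res$region[match("S_001", res$sv_id)], "splice_region")
  # fully inside the intron, away from junctions
  expect_equal(res$region[match("S_002", res$sv_id)], "intron")
  # 1.5 kb 5' of a + strand TSS -> upstream2kb
  expect_equal(res$region[match("S_003", res$sv_id)], "upstream2kb")
  # inside the coding exon
  expect_equal(res$region[match("S_004", res$sv_id)], "exon")

  # same upstream position, - strand gene -> downstream2kb
  ann_m <- toy_annotation(strand = "-")
  res_m <- annotate_region(make_callset("chr1", 8400, 8500, "DEL", "S"),
                           ann_m)
  expect_equal(res_m$region, "downstream2kb")

  # far away -> intergenic, and UTR hits resolve below coding exon
  far <- annotate_region(make_callset("chr1", 50000, 50100, "DEL", "S"), ann)
  expect_equal(far$region, "intergenic")
  utr_hit <- annotate_region(make_callset("chr1", 10010, 10050, "DEL", "S"),
                             ann)
  expect_equal(utr_hit$region, "utr5")
})

test_that("TE origin labels follow the coverage-fraction rule", {
  te <- data.frame(te_id = c("t1", "t2"), chrom = "chr1",
                   start = c(1000, 5000), end = c(3000, 5500),
                   class = c("LTR", "non-LTR"), stringsAsFactors = FALSE)
  sv <- make_callset("chr1", c(1200, 4900, 8000, 2900), c(1700, 5300, 8200, 3900),
                     c("DEL", "DEL", "INV", "DEL"), "S")
  res <- annotate_te_origin(sv, te)
  rec <- res$records
  expect_false("INV" %in% rec$svtype)            # PAV gate
  r1 <- rec[rec$sv_id == "S_001", ]              # fully inside LTR element
  expect_equal(r1$status, "te"); expect_equal(r1$te_class, "LTR")
  r2 <- rec[rec$sv_id == "S_002", ]              # 300/400 = 0.75 non-LTR
  expect_equal(r2$status, "te"); expect_equal(r2$te_class, "non-LTR")
  r4 <- rec[rec$sv_id == "S_004", ]              # 100/1000 = 0.1 < 0.5
  expect_equal(r4$status, "non-te")
  # INS untestable without inserted-sequence annotation
  ins <- make_callset("chr1", 9000, 9000, "INS", "I", length = 200)
  res_i <- annotate_te_origin(ins, te)
  expect_equal(res_i$records$status, "untestable")
  res_i2 <- annotate_te_origin(ins, te, ins_te = data.frame(
    sv_id = "I_001", class = "LTR", fraction = 0.9))
  expect_equal(res_i2$records$status, "te")
  expect_equal(res_i2$records$te_class, "LTR")
})

test_that("nearest-gene distances use half-open boundary arithmetic", {
  ann <- toy_annotation()   # gene [10000, 14000)
  sv <- make_callset("chr1", c(10500, 5000, 14100), c(10600, 5100, 14200),
                     rep("DEL", 3), "S")
  res <- nearest_gene_distance(sv, ann)
  d <- res$distances$distance[match(c("S_002", "S_001", "S_003"),
                                    res$distances$sv_id)]
  expect_equal(d, c(4900, 0, 100))
  # explicit worked case: SV [5000,5100) vs gene [6000,9000) -> 900
  ann2 <- toy_annotation(gene_start = 6000, exon_len = 1000,
                         intron_len = 1000)
  res2 <- nearest_gene_distance(make_callset("chr1", 5000, 5100, "DEL", "S"),
                                ann2)
  expect_equal(res2$distances$distance, 900)
  # identical distance sets: rank-sum test near 1
  te_labels <- data.frame(sv_id = c("S_001", "S_002", "S_003"),
                          status = c("te", "non-te", "te"))
  sv3 <- make_callset("chr1", c(20000, 20000, 30000, 30000),
                      c(20100, 20100, 30100, 30100), rep("DEL", 4), "S")
  lab3 <- data.frame(sv_id = sv3$id, status = c("te", "non-te",
                                                "te", "non-te"))
  res3 <- nearest_gene_distance(sv3, ann, te_labels = lab3)
  expect_gt(res3$test$p, 0.9)
})

test_that("SV catalogs round-trip through VCF via an independent parser", {
  cfg <- sim_config(seed = 37, n_sv = 120)
  ann <- simulate_annotation(cfg)
  sv <- simulate_sv_callsets(cfg, ann)
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(sv$callset_a, path, contigs = ann$chromosomes)
  back <- read_sv_vcf(path)
  cols <- c("id", "chrom", "start", "end", "svtype", "length")
  expect_equal(back[cols], sv$callset_a[cols], ignore_attr = TRUE)
  tra <- back[back$svtype == "TRA", ]
  orig_tra <- sv$callset_a[sv$callset_a$svtype == "TRA", ]
  expect_equal(as.character(tra$chr2), as.character(orig_tra$chr2))
  expect_equal(as.numeric(tra$pos2), as.numeric(orig_tra$pos2))
})
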