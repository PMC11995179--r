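# Independent oracles used across the suite.

# All-pairs brute-force SV matcher: enumerates every A x B pair, applies the
# type-specific matching rule directly, then resolves conflicts best-first.
brute_force_merge <- function(a, b, recip_overlap = 0.5, ins_dist = 100,
                              ins_size_ratio = 0.7, tra_dist = 1000) {
  cand <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$svtype[i] != b$svtype[j] || a$chrom[i] != b$chrom[j]) next
    type <- a$svtype[i]
    if (type %in% c("DEL", "INV")) {
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov <= 0) next
      ro <- ov / max(a$length[i], b$length[j])
      if (ro < recip_overlap) next
      cand[[length(cand) + 1]] <- data.frame(
        i = i, j = j, score = ro,
        dist = abs(a$start[i] - b$start[j]) + abs(a$end[i] - b$end[j]))
    } else if (type == "INS") {
      d <- abs(a$start[i] - b$start[j])
      ratio <- min(a$length[i], b$length[j]) / max(a$length[i], b$length[j])
      if (d > ins_dist || ratio < ins_size_ratio) next
      cand[[length(cand) + 1]] <- data.frame(i = i, j = j, score = ratio,
                                             dist = d)
    } else {
      if (is.na(a$chr2[i]) != is.na(b$chr2[j])) next
      if (!is.na(a$chr2[i]) && a$chr2[i] != b$chr2[j]) next
      d1 <- abs(a$start[i] - b$start[j])
      d2 <- if (is.na(a$pos2[i])) 0 else abs(a$pos2[i] - b$pos2[j])
      if (d1 > tra_dist || d2 > tra_dist) next
      cand[[length(cand) + 1]] <- data.frame(i = i, j = j, score = 0,
                                             dist = d1 + d2)
    }
  }
  if (!length(cand)) return(data.frame(a_id = character(0),
                                       b_id = character(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$dist, cand$i, cand$j), ]
  used_i <- used_j <- c()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$i[k] %in% used_i) && !(cand$j[k] %in% used_j)) {
      keep[k] <- TRUE
      used_i <- c(used_i, cand$i[k]); used_j <- c(used_j, cand$j[k])
    }
  }
  cand <- cand[keep, ]
  data.frame(a_id = a$id[cand$i], b_id = b$id[cand$j],
             stringsAsFactors = FALSE)
}

# All permutations of 1..n by iterative insertion (different construction
# from the package's recursive enumerator).
enum_perms <- function(n) {
  perms <- list(1L)
  for (m in 2:n) {
    nxt <- list()
    for (p in perms) for (pos in 0:(m - 1))
      nxt[[length(nxt) + 1]] <- append(p, m, after = pos)
    perms <- nxt
  }
  perms
}

# Exhaustive pan/core accumulation means via set operations.
brute_force_curves <- function(presence) {
  n <- nrow(presence)
  fams <- lapply(seq_len(n), function(i) which(presence[i, ] > 0))
  perms <- enum_perms(n)
  pan <- core <- matrix(0, length(perms), n)
  for (i in seq_along(perms)) {
    p <- perms[[i]]
    for (k in seq_len(n)) {
      sets <- fams[p[seq_len(k)]]
      pan[i, k] <- length(Reduce(union, sets))
      core[i, k] <- length(Reduce(intersect, sets))
    }
  }
  list(pan_mean = colMeans(pan), core_mean = colMeans(core))
}

# A tiny deterministic SV callset builder.
make_callset <- function(chrom, start, end, svtype, id_prefix = "X",
                         length = NULL, chr2 = NA, pos2 = NA,
                         source = "test") {
  if (is.null(length))
    length <- ifelse(svtype %in% c("DEL", "INV"), end - start, 100)
  d <- data.frame(id = sprintf("%s_%03d", id_prefix, seq_along(start)),
                  chrom = chrom, start = start, end = end, svtype = svtype,
                  length = length, chr2 = chr2, pos2 = pos2, source = source,
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$start), ]
  rownames(d) <- NULL
  d
}

# Minimal single-gene annotation set for interval tests: one gene with two
# exons, strand-aware UTRs, on a 100-kb chromosome.
toy_annotation <- function(strand = "+", gene_start = 10000,
                           exon_len = 1000, intron_len = 2000,
                           utr = 100, chrom_len = 100000) {
  e1 <- c(gene_start, gene_start + exon_len)
  e2 <- c(e1[2] + intron_len, e1[2] + intron_len + exon_len)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = e1[1],
                      end = e2[2], strand = strand,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
                      strand = strand, stringsAsFactors = FALSE)
  if (strand == "+") {
    utr5 <- data.frame(gene_id = "g1", chrom = "chr1", start = e1[1],
                       end = e1[1] + utr, strand = strand)
    utr3 <- data.frame(gene_id = "g1", chrom = "chr1", start = e2[2] - utr,
                       end = e2[2], strand = strand)
  } else {
    utr5 <- data.frame(gene_id = "g1", chrom = "chr1", start = e2[2] - utr,
                       end = e2[2], strand = strand)
    utr3 <- data.frame(gene_id = "g1", chrom = "chr1", start = e1[1],
                       end = e1[1] + utr, strand = strand)
  }
  # one UTR sits at each transcript end regardless of strand
  cds <- data.frame(gene_id = "g1", chrom = "chr1",
                    start = c(e1[1] + utr, e2[1]),
                    end = c(e1[2], e2[2] - utr),
                    strand = strand, stringsAsFactors = FALSE)
  structure(list(
    chromosomes = data.frame(chrom = "chr1", length = chrom_len),
    genes = genes, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
    te = data.frame(te_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    class = character(0))),
    class = "annotation_set")
}
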