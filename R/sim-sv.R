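#' Simulate two overlapping SV callsets
#'
#' Draws a set of true structural variants (DEL/INS/INV/TRA, sizes from a
#' binned mixture whose mode is the 101–500 bp range, placed non-adjacently
#' along the toy chromosomes) and emits two callsets emulating distinct
#' detection sources: callset A ("alignment") keeps the true coordinates,
#' callset B ("reads") carries breakpoint jitter of up to `jitter_bp`
#' (additionally capped at 30% of the variant length) and, for insertions,
#' a multiplicative size jitter in [0.85, 1.15]. A configurable fraction of
#' true variants appears in both callsets; the identity of those pairs is
#' recorded as ground truth for the merge step.
#'
#' @param config a [sim_config()] object.
#' @param annotation an `annotation_set` from [simulate_annotation()]
#'   (provides the chromosome table).
#' @return list with `callset_a`, `callset_b` (SV data.frames, 0-based
#'   half-open coordinates, sorted by chromosome and start), and `truth`:
#'   `variants` (the true variant table with callset membership) and
#'   `pairs` (data.frame `a_id`, `b_id` of records that are the same
#'   variant).
#' @export
simulate_sv_callsets <- function(config, annotation) {
  validate_sim_config(config)
  chroms <- annotation$chromosomes
  withr_seed(child_seed(config, "sv"), {
    n <- config$n_sv
    svtype <- sample(names(config$sv_type_props), n, replace = TRUE,
                     prob = config$sv_type_props)
    len <- sv_length_mixture(n)
    len[svtype == "TRA"] <- 0L

    # footprint on the reference: DEL/INV span their length, INS/TRA a point
    span <- ifelse(svtype %in% c("DEL", "INV"), len, 1L)
    per_chrom <- largest_remainder(n, rep(1 / nrow(chroms), nrow(chroms)))
    idx <- split(seq_len(n), rep(seq_len(nrow(chroms)), per_chrom))
    chrom <- character(n); start <- numeric(n)
    min_gap <- 2001   # > merge tolerances, so distinct variants never match
    for (ci in seq_along(idx)) {
      ii <- idx[[ci]]
      need <- sum(span[ii]) + (length(ii) + 1) * min_gap
      if (need > chroms$length[ci])
        stop("chromosome too short for ", length(ii), " SVs with ", min_gap,
             " bp spacing; increase chrom_length or reduce n_sv")
      slack <- chroms$length[ci] - need
      w <- stats::runif(length(ii) + 1)
      extra <- floor(slack * w / sum(w))
      cursor <- 0
      for (k in seq_along(ii)) {
        cursor <- cursor + min_gap + extra[k]
        chrom[ii[k]] <- chroms$chrom[ci]
        start[ii[k]] <- cursor
        cursor <- cursor + span[ii[k]]
      }
    }
    end <- ifelse(svtype %in% c("DEL", "INV"), start + len, start)
    chr2 <- pos2 <- rep(NA, n)
    is_tra <- svtype == "TRA"
    if (any(is_tra)) {
      chr2[is_tra] <- sample(chroms$chrom, sum(is_tra), replace = TRUE)
      pos2[is_tra] <- floor(stats::runif(sum(is_tra), 1, chroms$length[1] - 1))
    }
    membership <- sample(c("both", "A", "B"), n, replace = TRUE,
                         prob = c(config$shared_fraction,
                                  (1 - config$shared_fraction) * 0.75,
                                  (1 - config$shared_fraction) * 0.25))
    variants <- data.frame(sv_id = sprintf("sv%06d", seq_len(n)),
                           chrom = chrom, start = start, end = end,
                           svtype = svtype, length = len,
                           chr2 = chr2, pos2 = pos2,
                           membership = membership,
                           stringsAsFactors = FALSE)

    in_a <- membership %in% c("both", "A")
    in_b <- membership %in% c("both", "B")
    callset_a <- variants[in_a, c("chrom", "start", "end", "svtype",
                                  "length", "chr2", "pos2")]
    callset_a$id <- sprintf("A_%06d", seq_len(nrow(callset_a)))
    callset_a$source <- "alignment"

    bv <- variants[in_b, ]
    j <- config$jitter_bp
    jit <- function(limit) {
      limit <- pmax(0, floor(limit))
      vapply(limit, function(l) if (l == 0) 0 else
        sample(seq(-l, l), 1L), numeric(1))
    }
    b_start <- bv$start; b_end <- bv$end; b_len <- bv$length
    del_inv <- bv$svtype %in% c("DEL", "INV")
    shift <- jit(pmin(j, 0.3 * pmax(bv$length, 1)))
    b_start[del_inv] <- pmax(0, bv$start[del_inv] + shift[del_inv])
    b_end[del_inv] <- b_start[del_inv] + bv$length[del_inv]
    ins <- bv$svtype == "INS"
    if (any(ins)) {
      b_start[ins] <- pmax(0, bv$start[ins] + jit(rep(min(j, 100), sum(ins))))
      b_end[ins] <- b_start[ins]
      if (j > 0)
        b_len[ins] <- pmax(50, round(bv$length[ins] *
                                       stats::runif(sum(ins), 0.85, 1.15)))
    }
    tra <- bv$svtype == "TRA"
    if (any(tra)) {
      b_start[tra] <- pmax(0, bv$start[tra] + jit(rep(min(j, 500), sum(tra))))
      b_end[tra] <- b_start[tra]
      bv$pos2[tra] <- pmax(1, bv$pos2[tra] + jit(rep(min(j, 500), sum(tra))))
    }
    callset_b <- data.frame(chrom = bv$chrom, start = b_start, end = b_end,
                            svtype = bv$svtype, length = b_len,
                            chr2 = bv$chr2, pos2 = bv$pos2,
                            stringsAsFactors = FALSE)
    callset_b$id <- sprintf("B_%06d", seq_len(nrow(callset_b)))
    callset_b$source <- "reads"

    pairs <- data.frame(
      a_id = callset_a$id[match(variants$sv_id[membership == "both"],
                                variants$sv_id[in_a])],
      b_id = callset_b$id[match(variants$sv_id[membership == "both"],
                                variants$sv_id[in_b])],
      stringsAsFactors = FALSE)

    ord <- function(d) { d <- d[order(d$chrom, d$start), ]; rownames(d) <- NULL; d }
    cols <- c("id", "chrom", "start", "end", "svtype", "length",
              "chr2", "pos2", "source")
    list(callset_a = ord(callset_a)[, cols],
         callset_b = ord(callset_b)[, cols],
         truth = list(variants = variants, pairs = pairs))
  })
}

# Binned size mixture: uniform within each bin, bin weights chosen so the
# 101-500 bp bin is the mode and ~91% of variants fall below 5 kb.
sv_length_mixture <- function(n) {
  bins <- rbind(c(50, 100), c(101, 500), c(501, 1000),
                c(1001, 5000), c(5001, 20000))
  w <- c(0.20, 0.53, 0.10, 0.08, 0.09)
  b <- sample(nrow(bins), n, replace = TRUE, prob = w)
  floor(stats::runif(n, bins[b, 1], bins[b, 2] + 1))
}
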