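#' Merge two SV callsets into a nonredundant catalog
#'
#' Records from the two callsets are collapsed when they describe the same
#' variant: same SV type, and
#' \itemize{
#'   \item DEL/INV: reciprocal overlap >= `recip_overlap`;
#'   \item INS: breakpoints within `ins_dist` bp and size ratio
#'     (min/max) >= `ins_size_ratio`;
#'   \item TRA: both breakpoints within `tra_dist` bp.
#' }
#' Matching is greedy best-first: candidate pairs are ranked by overlap
#' quality (reciprocal overlap for DEL/INV, size ratio for INS), ties
#' broken by smaller breakpoint distance, then input order; each record
#' is used at most once. Collapsed records keep the first callset's
#' coordinates and carry both sources.
#'
#' @param callset_a,callset_b SV data.frames (columns `id`, `chrom`,
#'   `start`, `end`, `svtype`, `length`, `chr2`, `pos2`, `source`;
#'   0-based half-open coordinates) sorted by chromosome then start.
#' @param recip_overlap,ins_dist,ins_size_ratio,tra_dist matching
#'   thresholds (see above).
#' @param min_length records (other than TRA) shorter than this are
#'   dropped on ingest — the conventional lower bound of an SV.
#' @return list with `catalog` (merged data.frame; `sources` is a
#'   comma-joined provenance string, `a_id`/`b_id` trace the constituent
#'   records) and `matched_pairs` (data.frame `a_id`, `b_id`).
#' @export
merge_callsets <- function(callset_a, callset_b,
                           recip_overlap = 0.5, ins_dist = 100,
                           ins_size_ratio = 0.7, tra_dist = 1000,
                           min_length = 50) {
  a <- check_callset(callset_a, min_length, "callset_a")
  b <- check_callset(callset_b, min_length, "callset_b")
  cand <- sv_candidate_pairs(a, b, recip_overlap, ins_dist,
                             ins_size_ratio, tra_dist)
  matched_a <- integer(0); matched_b <- integer(0)
  if (nrow(cand) > 0) {
    cand <- cand[order(-cand$score, cand$dist, cand$ai, cand$bi), ]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ai <- cand$ai[i]; bi <- cand$bi[i]
      if (!used_a[ai] && !used_b[bi]) {
        used_a[ai] <- TRUE; used_b[bi] <- TRUE; keep[i] <- TRUE
      }
    }
    cand <- cand[keep, ]
    matched_a <- cand$ai; matched_b <- cand$bi
  }
  merged <- a
  merged$sources <- a$source
  merged$a_id <- a$id
  merged$b_id <- NA_character_
  if (length(matched_a)) {
    merged$sources[matched_a] <- paste(a$source[matched_a],
                                       b$source[matched_b], sep = ",")
    merged$b_id[matched_a] <- b$id[matched_b]
  }
  rest <- b[setdiff(seq_len(nrow(b)), matched_b), , drop = FALSE]
  if (nrow(rest)) {
    rest$sources <- rest$source
    rest$a_id <- NA_character_
    rest$b_id <- rest$id
    merged <- rbind(merged, rest)
  }
  merged$source <- NULL
  merged <- merged[order(merged$chrom, merged$start), ]
  merged$id <- sprintf("SV%06d", seq_len(nrow(merged)))
  rownames(merged) <- NULL
  pairs <- data.frame(a_id = a$id[matched_a], b_id = b$id[matched_b],
                      stringsAsFactors = FALSE)
  list(catalog = merged, matched_pairs = pairs)
}

check_callset <- function(x, min_length, label) {
  need <- c("id", "chrom", "start", "end", "svtype", "length")
  if (!all(need %in% names(x)))
    stop(label, " must have columns ", paste(need, collapse = ", "))
  if (!all(x$svtype %in% c("DEL", "INS", "INV", "TRA")))
    stop(label, ": unknown svtype (expected DEL/INS/INV/TRA)")
  ord <- order(x$chrom, x$start)
  if (!identical(ord, seq_len(nrow(x))))
    stop(label, " must be sorted by chromosome, then start")
  if (any(x$start > x$end)) stop(label, ": start > end")
  if (is.null(x$source)) x$source <- label
  if (is.null(x$chr2)) x$chr2 <- NA
  if (is.null(x$pos2)) x$pos2 <- NA
  drop <- x$svtype != "TRA" & x$length < min_length
  x[!drop, , drop = FALSE]
}

# Candidate A-B pairs passing the type-specific matching rule, with a
# unified (score, dist) ranking for the greedy pass.
sv_candidate_pairs <- function(a, b, recip_overlap, ins_dist,
                               ins_size_ratio, tra_dist) {
  out <- list()
  for (type in intersect(unique(a$svtype), unique(b$svtype))) {
    ai <- which(a$svtype == type); bi <- which(b$svtype == type)
    if (!length(ai) || !length(bi)) next
    if (type %in% c("DEL", "INV")) {
      gra <- GenomicRanges::GRanges(a$chrom[ai],
               IRanges::IRanges(a$start[ai] + 1, a$end[ai]))
      grb <- GenomicRanges::GRanges(b$chrom[bi],
               IRanges::IRanges(b$start[bi] + 1, b$end[bi]))
      hits <- GenomicRanges::findOverlaps(gra, grb)
      if (!length(hits)) next
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(gra[qi], grb[si]))
      ro <- ov / pmax(a$length[ai][qi], b$length[bi][si])
      pass <- ro >= recip_overlap
      if (!any(pass)) next
      out[[length(out) + 1]] <- data.frame(
        ai = ai[qi][pass], bi = bi[si][pass], score = ro[pass],
        dist = abs(a$start[ai][qi][pass] - b$start[bi][si][pass]) +
               abs(a$end[ai][qi][pass] - b$end[bi][si][pass]))
    } else if (type == "INS") {
      gra <- GenomicRanges::GRanges(a$chrom[ai],
               IRanges::IRanges(a$start[ai] + 1, width = 1))
      grb <- GenomicRanges::GRanges(b$chrom[bi],
               IRanges::IRanges(b$start[bi] + 1, width = 1))
      hits <- GenomicRanges::findOverlaps(gra, grb, maxgap = ins_dist)
      if (!length(hits)) next
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      d <- abs(a$start[ai][qi] - b$start[bi][si])
      ratio <- pmin(a$length[ai][qi], b$length[bi][si]) /
               pmax(a$length[ai][qi], b$length[bi][si])
      pass <- d <= ins_dist & ratio >= ins_size_ratio
      if (!any(pass)) next
      out[[length(out) + 1]] <- data.frame(
        ai = ai[qi][pass], bi = bi[si][pass], score = ratio[pass],
        dist = d[pass])
    } else {   # TRA: both breakpoints within tra_dist
      grid <- expand.grid(q = seq_along(ai), s = seq_along(bi))
      qa <- ai[grid$q]; qb <- bi[grid$s]
      d1 <- abs(a$start[qa] - b$start[qb])
      d2 <- abs(a$pos2[qa] - b$pos2[qb])
      pass <- a$chrom[qa] == b$chrom[qb] &
        (is.na(a$chr2[qa]) & is.na(b$chr2[qb]) |
           !is.na(a$chr2[qa]) & !is.na(b$chr2[qb]) &
           a$chr2[qa] == b$chr2[qb]) &
        d1 <= tra_dist & d2 <= tra_dist
      pass[is.na(pass)] <- FALSE
      if (!any(pass)) next
      out[[length(out) + 1]] <- data.frame(
        ai = qa[pass], bi = qb[pass], score = 0,
        dist = d1[pass] + d2[pass])
    }
  }
  if (!length(out))
    return(data.frame(ai = integer(0), bi = integer(0),
                      score = numeric(0), dist = numeric(0)))
  do.call(rbind, out)
}
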