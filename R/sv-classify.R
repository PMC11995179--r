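#' PAV composition of an SV catalog
#'
#' Deletions and insertions are presence/absence variations (PAVs):
#' sequence present in some genomes and absent in others. Inversions and
#' translocations rearrange without gaining or losing sequence.
#'
#' @param catalog merged SV data.frame with an `svtype` column, or a named
#'   count vector (`DEL`, `INS`, `INV`, `TRA`) when only the per-type
#'   totals are known.
#' @return list `counts` (per svtype), `proportions`, `pav_count`,
#'   `pav_fraction` and `pav_percent`.
#' @examples
#' classify_pav(c(DEL = 103083, INS = 84631, INV = 3161, TRA = 3359))$pav_percent
#' @export
classify_pav <- function(catalog) {
  if (is.numeric(catalog)) {
    counts <- catalog
    if (!all(names(counts) %in% c("DEL", "INS", "INV", "TRA")))
      stop("count vector must be named with SV types")
  } else {
    if (nrow(catalog) == 0) stop("empty catalog: PAV fraction undefined")
    counts <- table(factor(catalog$svtype,
                           levels = c("DEL", "INS", "INV", "TRA")))
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  total <- sum(counts)
  if (total == 0) stop("empty catalog: PAV fraction undefined")
  pav <- sum(counts[names(counts) %in% c("DEL", "INS")])
  list(counts = counts, proportions = counts / total,
       pav_count = pav, pav_fraction = pav / total,
       pav_percent = 100 * pav / total)
}

#' SV size spectrum
#'
#' Bins DEL/INS/INV lengths into 50-100, 101-500, 501-1000, 1001-5000 and
#' >5000 bp (upper edges inclusive); translocations have no length and are
#' excluded. Also reports the fraction of binned variants below 5 kb.
#'
#' @param catalog SV data.frame (`svtype`, `length`) or a numeric vector
#'   of lengths.
#' @return list `bins` (data.frame `bin`, `count`, `fraction`),
#'   `fraction_lt_5kb`, `modal_bin`, `n`.
#' @export
size_spectrum <- function(catalog) {
  len <- if (is.numeric(catalog)) catalog
         else catalog$length[catalog$svtype != "TRA"]
  len <- len[!is.na(len)]
  if (length(len) == 0) stop("no lengths to bin")
  if (any(len < 50)) stop("lengths below 50 bp are not SVs by convention")
  labs <- c("50-100", "101-500", "501-1000", "1001-5000", ">5000")
  bin <- cut(len, breaks = c(49, 100, 500, 1000, 5000, Inf), labels = labs)
  counts <- as.vector(table(bin))
  frac <- counts / length(len)
  list(bins = data.frame(bin = labs, count = counts, fraction = frac,
                         stringsAsFactors = FALSE),
       fraction_lt_5kb = sum(frac[1:4]),
       modal_bin = labs[which.max(counts)],
       n = length(len))
}

#' Share of a catalog contributed by each source
#'
#' @param counts named numeric vector of per-source record counts.
#' @return list `total`, `percent` (named).
#' @examples
#' source_shares(c(alignment = 158858, reads = 35376))$percent
#' @export
source_shares <- function(counts) {
  if (is.null(names(counts)) || sum(counts) <= 0)
    stop("counts must be a named vector with positive total")
  list(total = sum(counts), percent = 100 * counts / sum(counts))
}
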