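#' Classify gene families as core, dispensable or private
#'
#' Occupancy rule over a genomes x families presence/absence matrix:
#' a family present in all n genomes is core, in exactly one genome
#' private, and otherwise (2..n-1 genomes) dispensable.
#'
#' @param presence genomes x families matrix with 0/1 entries.
#' @return list with `classification` (data.frame `family`, `occupancy`,
#'   `class`), `counts` and `proportions` per class.
#' @examples
#' m <- rbind(g1 = c(1, 1, 1), g2 = c(1, 1, 0), g3 = c(1, 0, 0))
#' colnames(m) <- c("f1", "f2", "f3")
#' classify_families(m)$classification$class   # core dispensable private
#' @export
classify_families <- function(presence) {
  check_presence(presence)
  n <- nrow(presence)
  occ <- colSums(presence)
  cls <- ifelse(occ == n, "core", ifelse(occ == 1, "private", "dispensable"))
  classification <- data.frame(family = colnames(presence),
                               occupancy = as.integer(occ), class = cls,
                               stringsAsFactors = FALSE)
  counts <- c(core = sum(cls == "core"),
              dispensable = sum(cls == "dispensable"),
              private = sum(cls == "private"))
  list(classification = classification, counts = counts,
       proportions = counts / ncol(presence))
}

check_presence <- function(presence) {
  if (!is.matrix(presence) || !all(presence %in% c(0, 1)))
    stop("presence must be a 0/1 matrix (genomes x families)")
  if (nrow(presence) < 3)
    stop("need at least 3 genomes for the three-class scheme")
  if (any(colSums(presence) == 0))
    stop("all-zero family column: families must be present somewhere")
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence)))
    stop("genome and family identifiers must be unique")
  invisible(presence)
}

#' Per-genome class composition
#'
#' For each genome, the percentage of the families it contains that are
#' core, dispensable, private. Because dispensable families are absent
#' from some genomes, these per-genome percentages need not match the
#' global class proportions (core families are over-represented in every
#' individual genome).
#'
#' @param presence genomes x families 0/1 matrix.
#' @param classification result of [classify_families()] (computed if
#'   missing).
#' @return data.frame per genome: `n_families` present, `core_pct`,
#'   `dispensable_pct`, `private_pct`.
#' @export
per_genome_composition <- function(presence, classification = NULL) {
  check_presence(presence)
  if (is.null(classification)) classification <- classify_families(presence)
  cls <- classification$classification$class
  if (length(cls) != ncol(presence))
    stop("classification inconsistent with matrix")
  out <- data.frame(genome = rownames(presence),
                    n_families = as.integer(rowSums(presence)),
                    stringsAsFactors = FALSE)
  for (k in c("core", "dispensable", "private")) {
    ink <- presence[, cls == k, drop = FALSE]
    out[[paste0(k, "_pct")]] <- 100 * rowSums(ink) / out$n_families
  }
  out
}

#' Pan- and core-genome accumulation curves
#'
#' For a random ordering of genomes, pan(k) is the number of distinct
#' families in the first k genomes and core(k) the number present in all
#' of the first k. Means and standard deviations are taken over orderings:
#' all n! orderings when n! does not exceed `exhaustive_cap`, otherwise
#' `n_permutations` uniformly sampled orderings.
#'
#' @param presence genomes x families 0/1 matrix.
#' @param n_permutations orderings to sample when enumeration is too big.
#' @param seed RNG seed for the sampled orderings.
#' @param exhaustive_cap enumerate all orderings when n! <= this.
#' @return data.frame `k`, `pan_mean`, `pan_sd`, `core_mean`, `core_sd`,
#'   with attribute `n_orderings`.
#' @export
accumulation_curves <- function(presence, n_permutations = 1000, seed = 1,
                                exhaustive_cap = 40320) {
  check_presence(presence)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  n <- nrow(presence)
  P <- presence > 0
  if (factorial(n) <= exhaustive_cap) {
    orderings <- all_permutations(n)
  } else {
    orderings <- withr_seed(seed, replicate(n_permutations, sample.int(n),
                                            simplify = FALSE))
  }
  pan <- core <- matrix(0, nrow = length(orderings), ncol = n)
  for (i in seq_along(orderings)) {
    ord <- orderings[[i]]
    any_v <- all_v <- P[ord[1], ]
    pan[i, 1] <- sum(any_v); core[i, 1] <- sum(all_v)
    for (k in seq_len(n)[-1]) {
      any_v <- any_v | P[ord[k], ]
      all_v <- all_v & P[ord[k], ]
      pan[i, k] <- sum(any_v); core[i, k] <- sum(all_v)
    }
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  res <- data.frame(k = seq_len(n),
                    pan_mean = colMeans(pan),
                    pan_sd = apply(pan, 2, sd0),
                    core_mean = colMeans(core),
                    core_sd = apply(core, 2, sd0))
  attr(res, "n_orderings") <- length(orderings)
  res
}

# All permutations of 1..n as a list (n small; guarded by exhaustive_cap).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[s])
    }
  }
  out
}

#' Compare a per-family metric across pan-genome classes
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of classes
#' (exact when both groups have <= `exact_max` values and no ties, normal
#' approximation with continuity correction otherwise), BH-adjusted
#' across the pairs.
#'
#' @param values named numeric vector, family -> metric (e.g. expression,
#'   CDS length, Ka/Ks, pi).
#' @param classification result of [classify_families()].
#' @param metric_name label carried into the output.
#' @param exact_max exact-test size cutoff per group.
#' @return data.frame per class pair: group sizes, medians, rank-sum W,
#'   `p`, `padj`.
#' @export
class_metric_compare <- function(values, classification,
                                 metric_name = "metric", exact_max = 25) {
  cl <- classification$classification
  if (is.null(names(values))) stop("values must be named by family")
  cl <- cl[cl$family %in% names(values), ]
  groups <- split(values[cl$family], cl$class)
  small <- vapply(groups, length, 0L) < 2
  if (any(small)) {
    warning("class(es) with < 2 values skipped: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2)
    stop("need >= 2 classes with >= 2 values each")
  combos <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- lapply(combos, function(pair) {
    x <- groups[[pair[1]]]; y <- groups[[pair[2]]]
    exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !any(duplicated(c(x, y)))
    wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                             exact = exact, correct = TRUE)
    data.frame(metric = metric_name,
               class_a = pair[1], class_b = pair[2],
               n_a = length(x), n_b = length(y),
               median_a = stats::median(x), median_b = stats::median(y),
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res
}
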