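#' Single-marker GWAS by least squares
#'
#' Fits y ~ dosage (+ optional covariates) marker by marker. Markers with
#' minor-allele frequency below `maf_min` or missing rate above
#' `max_missing` are excluded (reported in `excluded`); remaining missing
#' dosages are mean-imputed per marker. Covariates are projected out of
#' both phenotype and dosages (Frisch–Waugh), so the per-marker test is an
#' ordinary t-test with the covariate degrees of freedom removed.
#'
#' @param panel list with `dosage` (samples x markers) and `map`
#'   (`marker`, `chrom`, `pos`, `class`).
#' @param phenotypes numeric vector (aligned with dosage rows, or named by
#'   sample) or data.frame `sample`, `value`.
#' @param covariates optional numeric matrix (samples x q).
#' @param maf_min,max_missing marker filters.
#' @return list `result` (per marker: map columns, `beta`, `se`, `t`, `p`,
#'   `padj` BH, `bonferroni` flag at 0.05) and `excluded` (marker,
#'   reason).
#' @export
gwas_scan <- function(panel, phenotypes, covariates = NULL,
                      maf_min = 0.01, max_missing = 0.1) {
  X <- panel$dosage
  y <- align_phenotype(phenotypes, X)
  n <- nrow(X)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (n <= ncol(covariates) + 2) stop("too few samples for covariates")
  }
  miss <- colMeans(is.na(X))
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  bad <- miss > max_missing | maf < maf_min | is.na(maf)
  excluded <- data.frame(
    marker = colnames(X)[bad],
    reason = ifelse(miss[bad] > max_missing, "missing_rate", "maf"),
    stringsAsFactors = FALSE)
  X <- X[, !bad, drop = FALSE]
  if (ncol(X) == 0) stop("no markers pass the filters")
  X <- mean_impute(X)

  q <- 0
  if (!is.null(covariates)) {
    Z <- cbind(1, covariates)
    q <- ncol(covariates)
    P <- Z %*% solve(crossprod(Z), t(Z))
    y <- y - P %*% y
    X <- X - P %*% X
    y <- as.vector(y)
  } else {
    y <- y - mean(y)
    X <- sweep(X, 2, colMeans(X))
  }
  df <- n - 2 - q
  sxx <- colSums(X^2)
  sxy <- as.vector(crossprod(X, y))
  beta <- sxy / sxx
  rss <- sum(y^2) - beta * sxy
  se <- sqrt(rss / df / sxx)
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  map <- panel$map[match(colnames(X), panel$map$marker), ]
  res <- data.frame(map, beta = beta, se = se, t = t_stat, p = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    bonferroni = p < 0.05 / length(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(result = res, excluded = excluded)
}

align_phenotype <- function(phenotypes, X) {
  if (is.data.frame(phenotypes)) {
    y <- phenotypes$value[match(rownames(X), phenotypes$sample)]
  } else if (!is.null(names(phenotypes)) && !is.null(rownames(X))) {
    y <- phenotypes[rownames(X)]
  } else y <- phenotypes
  if (length(y) != nrow(X) || any(is.na(y)))
    stop("phenotype does not align with the dosage matrix")
  if (stats::var(y) == 0) stop("constant phenotype")
  as.numeric(y)
}

mean_impute <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

#' Linkage disequilibrium between SVs and surrounding SNPs
#'
#' For each SV marker, takes the SNPs whose position lies in the half-open
#' window [pos - window, pos + window) on the same chromosome and computes
#' R-squared as the squared Pearson correlation of dosage vectors
#' (pairwise complete cases). Reports per-SV SNP counts and max/mean R²,
#' and the fraction of SVs with any R² above `strong_r2`.
#'
#' @param panel list with `dosage` and `map` (needs a `class` column
#'   distinguishing SNP and SV).
#' @param window half-width (bp).
#' @param strong_r2 threshold defining "strong" linkage.
#' @param return_pairs also return the per-pair R² table.
#' @return list `per_sv` (sv, n_snps, max_r2, mean_r2, any_strong),
#'   `fraction_strong`, `mean_n_snps`, and optionally `pairs`.
#' @export
ld_profile <- function(panel, window = 500000, strong_r2 = 0.6,
                       return_pairs = FALSE) {
  map <- panel$map
  X <- panel$dosage
  svs <- map[map$class == "SV", , drop = FALSE]
  snps <- map[map$class == "SNP", , drop = FALSE]
  if (nrow(svs) == 0 || nrow(snps) == 0) stop("panel needs both classes")
  rows <- vector("list", nrow(svs))
  pairs <- list()
  for (i in seq_len(nrow(svs))) {
    near <- snps$marker[snps$chrom == svs$chrom[i] &
                          snps$pos >= svs$pos[i] - window &
                          snps$pos < svs$pos[i] + window]
    if (length(near) == 0) {
      rows[[i]] <- data.frame(sv = svs$marker[i], n_snps = 0L,
                              max_r2 = NA_real_, mean_r2 = NA_real_,
                              any_strong = FALSE)
      next
    }
    r <- suppressWarnings(stats::cor(X[, svs$marker[i]],
                                     X[, near, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r2 <- as.vector(r)^2
    rows[[i]] <- data.frame(sv = svs$marker[i], n_snps = length(near),
                            max_r2 = suppressWarnings(max(r2, na.rm = TRUE)),
                            mean_r2 = mean(r2, na.rm = TRUE),
                            any_strong = any(r2 > strong_r2, na.rm = TRUE))
    if (return_pairs)
      pairs[[i]] <- data.frame(sv = svs$marker[i], snp = near, r2 = r2,
                               stringsAsFactors = FALSE)
  }
  per_sv <- do.call(rbind, rows)
  rownames(per_sv) <- NULL
  out <- list(per_sv = per_sv,
              fraction_strong = mean(per_sv$any_strong),
              mean_n_snps = mean(per_sv$n_snps))
  if (return_pairs) out$pairs <- do.call(rbind, pairs)
  out
}

#' Allele-substitution effect at a single locus
#'
#' Welch two-sided t-test of the phenotype between reference individuals
#' and alternate-allele carriers (`coding = "carrier"`: dosage 0 vs
#' dosage >= 1; `"genotype"`: homozygous ref vs homozygous alt).
#'
#' @param dosages vector of dosages (0/1/2, NA allowed).
#' @param phenotypes numeric vector, same order/names.
#' @param coding grouping rule.
#' @return list `group_means`, `group_n`, `t`, `df`, `p`.
#' @export
allele_substitution_test <- function(dosages, phenotypes,
                                     coding = c("carrier", "genotype")) {
  coding <- match.arg(coding)
  ok <- !is.na(dosages) & !is.na(phenotypes)
  d <- dosages[ok]; y <- phenotypes[ok]
  grp <- switch(coding,
                carrier = ifelse(d >= 1, "alt", "ref"),
                genotype = ifelse(d == 2, "alt",
                                  ifelse(d == 0, "ref", NA)))
  keep <- !is.na(grp)
  grp <- grp[keep]; y <- y[keep]
  if (sum(grp == "ref") < 2 || sum(grp == "alt") < 2)
    stop("need >= 2 samples in both the reference and alternate group")
  tt <- stats::t.test(y[grp == "ref"], y[grp == "alt"], var.equal = FALSE)
  list(group_means = c(ref = mean(y[grp == "ref"]),
                       alt = mean(y[grp == "alt"])),
       group_n = c(ref = sum(grp == "ref"), alt = sum(grp == "alt")),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Cross-validated genomic selection with one or more marker panels
#'
#' Ridge regression on standardized dosages (the penalized equivalent of
#' GBLUP with a genomic relationship built from the same markers), with
#' the shrinkage parameter chosen by inner cross-validation over a fixed
#' log-spaced grid. A panel given as a *named list* of dosage-matrix
#' blocks (e.g. `list(SNP = ..., SV = ...)` for a combined SNP+SV panel)
#' is fitted as a weighted two-kernel model: each block is standardized
#' and scaled by its marker count, and the relative block weight is
#' chosen on a grid by the same inner CV. This way a combined panel can
#' fall back onto whichever marker class carries the signal, so adding an
#' uninformative class does not systematically cost accuracy. Outer fold
#' assignments are identical across panels, making per-fold accuracy
#' differences paired comparisons. Accuracy is the Pearson correlation of
#' predicted and observed phenotype in held-out folds.
#'
#' @param panels named list; each element a dosage matrix (samples x
#'   markers) or a named list of such blocks sharing rows.
#' @param phenotypes numeric vector / data.frame as in [gwas_scan()].
#' @param k outer folds.
#' @param repeats independent repetitions (new fold assignments each).
#' @param seed RNG seed controlling fold assignments.
#' @param lambda shrinkage grid (on block-normalized predictors).
#' @param weight_grid grid for the first block's weight in two-block
#'   panels.
#' @param inner_folds inner CV folds.
#' @return list `accuracy` (data.frame panel, repeat, fold, r), `summary`
#'   (per panel mean and sd), `deltas` (pairwise mean differences, in
#'   percentage points of correlation).
#' @export
gs_cross_validate <- function(panels, phenotypes, k = 5, repeats = 10,
                              seed = 1,
                              lambda = 10^seq(2, -4, length.out = 25),
                              weight_grid = c(0, 0.25, 0.5, 0.75, 1),
                              inner_folds = 5) {
  if (is.null(names(panels))) stop("panels must be a named list")
  first <- panels[[1]]
  n <- if (is.list(first)) nrow(first[[1]]) else nrow(first)
  if (n < 50) stop("need at least 50 samples for cross-validation")
  blocks_of <- function(p) if (is.list(p)) p else list(p)
  for (p in panels)
    for (b in blocks_of(p))
      if (nrow(b) != n) stop("panels must share samples")
  y <- align_phenotype(phenotypes, blocks_of(first)[[1]])

  # standardize columns and scale the block by sqrt(#markers), so each
  # block contributes a unit-trace genomic relationship
  prep <- function(X) {
    X <- mean_impute(X)
    Xs <- scale(X)
    Xs[, !is.finite(colSums(Xs))] <- 0
    Xs / sqrt(ncol(Xs))
  }
  acc <- list()
  for (r in seq_len(repeats)) {
    fold <- withr_seed(seed + 7919L * r,
                       sample(rep(seq_len(k), length.out = n)))
    inner_all <- withr_seed(seed + 104729L * r,
                            sample(rep(seq_len(inner_folds),
                                       length.out = n)))
    for (pn in names(panels)) {
      blocks <- lapply(blocks_of(panels[[pn]]), prep)
      if (length(blocks) > 2)
        stop("at most two blocks per panel are supported")
      wgrid <- if (length(blocks) == 2) weight_grid else 1
      for (f in seq_len(k)) {
        test <- fold == f
        inner <- inner_all[!test]
        best <- NULL
        for (w in wgrid) {
          Xw <- if (length(blocks) == 2)
            cbind(sqrt(w) * blocks[[1]], sqrt(1 - w) * blocks[[2]])
          else blocks[[1]]
          fit <- glmnet::cv.glmnet(Xw[!test, , drop = FALSE], y[!test],
                                   alpha = 0, lambda = lambda,
                                   foldid = inner, standardize = FALSE)
          if (is.null(best) || min(fit$cvm) < best$cvm)
            best <- list(cvm = min(fit$cvm), fit = fit, Xw = Xw)
        }
        pred <- as.vector(stats::predict(best$fit,
                                         best$Xw[test, , drop = FALSE],
                                         s = "lambda.min"))
        r_fold <- if (stats::sd(pred) > 0) stats::cor(pred, y[test]) else 0
        acc[[length(acc) + 1]] <- data.frame(
          panel = pn, rep = r, fold = f, r = r_fold,
          stringsAsFactors = FALSE)
      }
    }
  }
  acc <- do.call(rbind, acc)
  summ <- do.call(rbind, lapply(split(acc$r, acc$panel), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v))))
  summ <- data.frame(panel = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  combos <- if (length(panels) >= 2)
    utils::combn(names(panels), 2, simplify = FALSE) else list()
  deltas <- do.call(rbind, lapply(combos, function(pr) {
    a <- acc$r[acc$panel == pr[1]]; b <- acc$r[acc$panel == pr[2]]
    data.frame(panel_a = pr[1], panel_b = pr[2],
               delta_pct_points = 100 * (mean(a) - mean(b)),
               stringsAsFactors = FALSE)
  }))
  list(accuracy = acc, summary = summ, deltas = deltas)
}

#' Plot-ready Manhattan table
#'
#' @param gwas_result `result` data.frame from [gwas_scan()] (or the list
#'   itself).
#' @return data.frame `marker`, `chrom`, `pos`, `neglog10p`, `class`,
#'   sorted by genome coordinate.
#' @export
manhattan_table <- function(gwas_result) {
  res <- if (is.data.frame(gwas_result)) gwas_result else gwas_result$result
  out <- data.frame(marker = res$marker, chrom = res$chrom, pos = res$pos,
                    neglog10p = -log10(res$p), class = res$class,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
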