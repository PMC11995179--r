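#' Simulate a gene-family presence/absence matrix
#'
#' Generates a binary genomes x families matrix with an exact
#' core/dispensable/private composition. Class counts are obtained from
#' `class_props` by largest-remainder rounding, so they always sum to
#' `n_families`. Core families are present in every genome, private
#' families in exactly one (chosen uniformly), and dispensable families in
#' k genomes with k drawn uniformly from 2..n_genomes-1.
#'
#' @param config a [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{presence}{integer matrix, `n_genomes` rows (genomes) by
#'       `n_families` columns (families), entries 0/1.}
#'     \item{truth}{data.frame `family`, `class` — the planted class of
#'       every family.}
#'   }
#' @examples
#' sim <- simulate_pangenome(sim_config(seed = 1, n_families = 50))
#' table(sim$truth$class)
#' @export
simulate_pangenome <- function(config) {
  validate_sim_config(config)
  n <- config$n_genomes
  m <- config$n_families
  props <- config$class_props[c("core", "dispensable", "private")]
  counts <- largest_remainder(m, props)
  names(counts) <- names(props)

  withr_seed(child_seed(config, "pangenome"), {
    classes <- rep(names(counts), counts)
    presence <- matrix(0L, nrow = n, ncol = m,
                       dimnames = list(
                         genome = sprintf("genome%02d", seq_len(n)),
                         family = sprintf("fam%06d", seq_len(m))))
    for (j in seq_len(m)) {
      presence[, j] <- switch(classes[j],
        core = rep(1L, n),
        private = {
          v <- integer(n); v[sample.int(n, 1L)] <- 1L; v
        },
        dispensable = {
          k <- sample(2:(n - 1L), 1L)
          v <- integer(n); v[sample.int(n, k)] <- 1L; v
        })
    }
    truth <- data.frame(family = colnames(presence), class = classes,
                        stringsAsFactors = FALSE)
    list(presence = presence, truth = truth)
  })
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a presence matrix as TSV
#'
#' Rows are families, columns genomes (the common orthology-table layout);
#' the reader returns the internal genomes x families orientation.
#'
#' @param presence genomes x families 0/1 matrix.
#' @param path TSV path.
#' @export
write_presence_matrix <- function(presence, path) {
  df <- data.frame(family = colnames(presence), t(presence),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$family
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("genome", "family")
  m
}
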