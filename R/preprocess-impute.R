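#' Iterative random-forest imputation of missing metabolite values
#'
#' Missing entries are initialised at their column means and then refined by
#' iterating over incomplete columns (most complete first): each column is
#' regressed on all others with a random forest and its missing entries are
#' replaced by the forest predictions. Iteration stops when the relative
#' change of the imputed entries falls below `tol` or after `max_iter`
#' rounds. Observed entries are never altered, and forest predictions are
#' averages of observed values, so imputations lie within each column's
#' observed range. Deterministic under a fixed seed.
#'
#' @param metabolites Metabolite tibble or numeric matrix with `NA` for
#'   missing entries; every column must satisfy the upstream <= 20%
#'   missingness filter and have at least one observed value.
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 100).
#' @param max_iter Maximum refinement rounds (default 10).
#' @param tol Relative-change stopping tolerance (default 1e-4).
#' @return Completed object of the same shape as the input.
#' @export
impute_missing <- function(metabolites, seed = 1L, num_trees = 100,
                           max_iter = 10, tol = 1e-4) {
  is_df <- is.data.frame(metabolites)
  m <- if (is_df) metabolite_matrix(metabolites) else metabolites
  miss <- is.na(m)
  if (!any(miss)) return(metabolites)
  if (any(colSums(!miss) == 0)) {
    oo_abort(paste0("column(s) entirely missing, cannot impute: ",
                    paste(colnames(m)[colSums(!miss) == 0], collapse = ", ")))
  }
  set.seed(seed)
  # initialise at column means
  mu <- colMeans(m, na.rm = TRUE)
  filled <- m
  for (j in which(colSums(miss) > 0)) filled[miss[, j], j] <- mu[j]

  target <- which(colSums(miss) > 0)
  target <- target[order(colSums(miss)[target])]
  prev <- filled
  for (iter in seq_len(max_iter)) {
    for (j in target) {
      obs <- !miss[, j]
      df <- as.data.frame(filled[, -j, drop = FALSE])
      df$.y <- filled[, j]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df[obs, , drop = FALSE],
        num.trees = num_trees, seed = seed + iter * 1000L + j,
        num.threads = 1, verbose = FALSE)
      filled[miss[, j], j] <-
        stats::predict(fit, df[miss[, j], , drop = FALSE],
                       num.threads = 1)$predictions
    }
    delta <- sum((filled[miss] - prev[miss])^2)
    denom <- sum(filled[miss]^2)
    if (denom > 0 && delta / denom < tol^2) break
    prev <- filled
  }
  stopifnot(identical(filled[!miss], m[!miss]))
  if (is_df) {
    idcols <- intersect(c("participant_id", "visit"), names(metabolites))
    out <- metabolites
    out[, setdiff(names(out), idcols)] <- tibble::as_tibble(filled)
    out
  } else {
    filled
  }
}
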