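# Coefficient-space principal component analysis across the three exposure
# signatures, and profile-specificity correlation matrices.

#' Stack signature coefficients into a metabolite-by-exposure matrix
#'
#' Rows are the union of metabolites selected in any signature; columns are
#' the exposures; entries are the mean elastic-net coefficients, with zero
#' assigned wherever a metabolite was not selected by a given signature.
#'
#' @param signatures Named list of `oo_signature` objects (names become
#'   columns; defaults to each model's exposure label).
#' @return Tibble with `metabolite` plus one numeric column per signature.
#' @export
coefficient_matrix <- function(signatures) {
  stopifnot(length(signatures) >= 1,
            all(vapply(signatures, inherits, logical(1), "oo_signature")))
  if (is.null(names(signatures)) || any(names(signatures) == "")) {
    names(signatures) <- vapply(signatures, `[[`, character(1), "exposure")
  }
  mets <- sort(unique(unlist(lapply(signatures, `[[`, "selected"))))
  out <- tibble::tibble(metabolite = mets)
  for (nm in names(signatures)) {
    w <- setNames(signatures[[nm]]$weights$coef_mean,
                  signatures[[nm]]$weights$metabolite)
    out[[nm]] <- unname(w[mets])
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  out
}

#' Principal component analysis of signature coefficients
#'
#' Centers and scales each exposure column of the coefficient matrix, then
#' eigendecomposes its correlation structure (metabolites as observations).
#' Loading signs follow the convention that each loading vector's
#' largest-magnitude entry is positive.
#'
#' @param coefficients Output of [coefficient_matrix()] (or any numeric data
#'   frame with an optional `metabolite` column); at least 2 rows, no missing
#'   entries.
#' @return List of class `oo_pca`: `loadings`, `scores`,
#'   `variance_fraction`, and the standardized matrix used.
#' @export
coefficient_pca <- function(coefficients) {
  df <- as.data.frame(coefficients)
  rn <- if ("metabolite" %in% names(df)) df$metabolite else rownames(df)
  x <- as.matrix(df[, setdiff(names(df), "metabolite"), drop = FALSE])
  if (nrow(x) < 2) oo_abort("need at least 2 rows for PCA")
  if (anyNA(x)) oo_abort("missing entries after zero-fill; cannot run PCA")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    oo_abort(paste0("constant column(s) after centering: ",
                    paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  xs <- scale(x)
  rownames(xs) <- rn
  sv <- svd(xs)
  ev <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  for (k in seq_len(ncol(loadings))) { # sign convention
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  dimnames(scores) <- list(rn, paste0("PC", seq_len(ncol(scores))))
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = ev, standardized = xs),
            class = "oo_pca")
}

#' @export
print.oo_pca <- function(x, ...) {
  cat("<oo_pca> variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.oo_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "exposure") |>
    tidyr::pivot_longer(-"exposure", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.oo_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$variance_fraction)),
                 variance_fraction = x$variance_fraction)
}

#' @export
autoplot.oo_pca <- function(object, ...) {
  sc <- tibble::as_tibble(object$scores, rownames = "metabolite")
  ld <- tibble::as_tibble(object$loadings, rownames = "exposure")
  r <- max(abs(sc$PC1), abs(sc$PC2))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(data = ld, colour = "#b2182b",
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * r,
                                       yend = .data$PC2 * r),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = ld, colour = "#b2182b", vjust = -0.5,
                       ggplot2::aes(x = .data$PC1 * r, y = .data$PC2 * r,
                                    label = .data$exposure)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])) +
    ggplot2::theme_minimal()
}

#' Profile-specificity correlation table
#'
#' Pearson correlations between each signature score and each olive-oil
#' intake; with exposure-specific planted signals the diagonal is expected to
#' dominate.
#'
#' @param scores Data frame of signature scores (one column per signature).
#' @param intakes Data frame of intakes (one column per exposure), aligned to
#'   `scores`.
#' @return Tibble: `signature`, `exposure`, `r`.
#' @export
specificity_correlations <- function(scores, intakes) {
  scores <- as.data.frame(scores)
  intakes <- as.data.frame(intakes)
  stopifnot(nrow(scores) == nrow(intakes))
  bad <- c(names(scores)[vapply(scores, sd, numeric(1)) == 0],
           names(intakes)[vapply(intakes, sd, numeric(1)) == 0])
  if (length(bad) > 0) {
    oo_abort(paste0("zero-variance vector(s): ", paste(bad, collapse = ", ")))
  }
  tidyr::expand_grid(signature = names(scores), exposure = names(intakes)) |>
    dplyr::mutate(r = purrr::map2_dbl(.data$signature, .data$exposure,
                                      ~ cor(scores[[.x]], intakes[[.y]])))
}
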