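# Pooled-reference standardization, Blom rank-based inverse normal
# transformation, and residual-method energy adjustment.

#' Pooled plasma reference ("nearest neighbor") standardization
#'
#' For each metabolite, a sample value `v` measured at a given run position
#' becomes `v / r * median(refs)` where `r` is the pooled plasma reference
#' nearest in run order and `refs` are all pooled references for that
#' metabolite. When a sample is equidistant between two references, the
#' earlier run position is used. A nearest reference of zero makes the value
#' unquantifiable: it is set missing and flagged, not an error.
#'
#' @param values Numeric vector of sample values, in run order.
#' @param positions Run positions of the samples.
#' @param ref_values Numeric vector of pooled-reference values.
#' @param ref_positions Run positions of the pooled references.
#' @return Tibble with `value` (standardized, `NA` where unquantifiable),
#'   `ref_position` (the reference used), and `unquantifiable` flag.
#' @export
#' @examples
#' pooled_reference_standardize(12, 2, c(10, 20), c(0, 10))  # 12/10 * 15 = 18
pooled_reference_standardize <- function(values, positions,
                                         ref_values, ref_positions) {
  if (length(ref_values) < 1) oo_abort("at least one pooled reference required")
  stopifnot(length(values) == length(positions),
            length(ref_values) == length(ref_positions))
  med <- median(ref_values)
  ord <- order(ref_positions)
  ref_values <- ref_values[ord]
  ref_positions <- ref_positions[ord]
  nearest <- vapply(positions, function(pos) {
    d <- abs(ref_positions - pos)
    which(d == min(d))[1] # tie -> earlier run position
  }, integer(1))
  r <- ref_values[nearest]
  bad <- r == 0
  out <- values / r * med
  out[bad] <- NA_real_
  tibble::tibble(value = out, ref_position = ref_positions[nearest],
                 unquantifiable = bad)
}

#' Blom rank-based inverse normal transformation
#'
#' Maps the value of rank `r` among `n` to the normal quantile of
#' `(r - 3/8) / (n + 1/4)`. Ties receive the mean of their tied ranks
#' (midranks), so the output is order-isomorphic to the input.
#'
#' @param x Numeric vector or matrix/data frame (applied per column); must
#'   have at least two distinct finite values per column.
#' @return Transformed object of the same shape.
#' @export
#' @examples
#' blom_transform(c(5, 1, 9)) # middle element maps to 0
blom_transform <- function(x) {
  one <- function(v) {
    ok <- is.finite(v)
    if (length(unique(v[ok])) < 2) {
      oo_abort("constant column: Blom transformation undefined")
    }
    n <- sum(ok)
    r <- rank(v[ok], ties.method = "average")
    out <- rep(NA_real_, length(v))
    out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
    out
  }
  if (is.matrix(x)) return(apply(x, 2L, one))
  if (is.data.frame(x)) {
    idcols <- intersect(c("participant_id", "visit"), names(x))
    out <- x
    for (nm in setdiff(names(x), idcols)) out[[nm]] <- one(x[[nm]])
    return(out)
  }
  one(x)
}

#' Residual-method energy adjustment
#'
#' Regresses an intake on total energy by least squares and returns the
#' residuals re-centered at the mean intake, so units (g/day) and center are
#' preserved while the adjusted intake is uncorrelated with energy.
#'
#' @param intake Numeric intake vector (g/day).
#' @param energy Numeric total energy vector (kcal/day), non-constant.
#' @return Adjusted intake vector.
#' @export
#' @examples
#' energy_adjust_residual(c(10, 20, 30), c(2000, 2500, 2000))
energy_adjust_residual <- function(intake, energy) {
  stopifnot(length(intake) == length(energy))
  if (length(intake) < 3) oo_abort("need at least 3 observations")
  if (sd(energy) == 0) oo_abort("energy is constant: residual method undefined")
  fit <- lm(intake ~ energy)
  unname(stats::resid(fit) + mean(intake))
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' @param r Pearson correlation.
#' @param n Sample size (must be >= 4).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4) oo_abort("confidence interval undefined for n < 4")
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}
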