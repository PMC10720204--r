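# Metabolome-wide covariate-adjusted linear screen with Benjamini-Hochberg
# control. The per-metabolite regression metabolite ~ exposure + covariates
# is computed for all metabolites at once through the
# Frisch-Waugh-Lovell decomposition: both the exposure and the metabolite
# matrix are residualised on the covariate design with one QR factorisation,
# after which each coefficient, its standard error and t-statistic equal the
# full least-squares fit exactly.

#' Metabolome-wide covariate-adjusted linear associations
#'
#' Regresses each (imputed, Blom-transformed) metabolite on an olive-oil
#' exposure plus covariates, returning the per-SD exposure coefficient, its
#' standard error, the two-sided p-value, and the Benjamini-Hochberg adjusted
#' q-value. Categorical covariates are expanded to indicator contrasts with
#' the factor's first level as reference.
#'
#' @param metabolites Complete metabolite tibble or numeric matrix
#'   (participants x metabolites).
#' @param exposure Numeric exposure vector (energy-adjusted intake); entered
#'   per SD so coefficients are comparable across exposures.
#' @param covariates Data frame of covariates aligned to participants
#'   (e.g. center, age, sex, smoking, BMI, education, physical activity), or
#'   `NULL` for an intercept-only adjustment.
#' @param exposure_name Label recorded in the result.
#' @return Tibble of class `oo_screen`: one row per metabolite with `beta`,
#'   `se`, `statistic`, `p_value`, `q_value`, `exposure`, `n`.
#' @export
metabolome_wide_lm <- function(metabolites, exposure, covariates = NULL,
                               exposure_name = "total_oo") {
  m <- if (is.data.frame(metabolites)) metabolite_matrix(metabolites) else metabolites
  n <- nrow(m)
  stopifnot(length(exposure) == n)
  if (anyNA(m)) oo_abort("metabolite matrix must be complete (impute first)")
  z <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stopifnot(nrow(covariates) == n)
    model.matrix(~ ., data = as.data.frame(covariates))
  }
  qrz <- qr(z)
  if (qrz$rank < ncol(z)) {
    dropped <- colnames(z)[qrz$pivot[(qrz$rank + 1):ncol(z)]]
    oo_abort(paste0("rank-deficient covariate design; collinear column(s): ",
                    paste(dropped, collapse = ", ")))
  }
  x <- exposure / sd(exposure)
  ex <- qr.resid(qrz, x)
  exx <- sum(ex^2)
  if (exx < 1e-12) oo_abort("exposure is collinear with the covariates")
  em <- qr.resid(qrz, m)
  beta <- as.numeric(crossprod(em, ex)) / exx
  rss <- unname(colSums(em^2)) - beta^2 * exx
  df <- n - qrz$rank - 1L
  se <- sqrt(pmax(rss, 0) / df / exx)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  out <- tibble::tibble(metabolite = colnames(m), beta = beta, se = se,
                        statistic = tstat, p_value = p,
                        q_value = bh_adjust(p),
                        exposure = exposure_name, n = n)
  class(out) <- c("oo_screen", class(out))
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order, capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.05))
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    oo_abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Volcano plot of a metabolome-wide screen
#'
#' Effect size against -log10 p, with the dotted significance line drawn at
#' the largest p-value whose q-value falls below `fdr`.
#'
#' @param screen An `oo_screen` result.
#' @param fdr False-discovery-rate threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(screen, fdr = 0.05) {
  stopifnot(inherits(screen, "oo_screen"))
  sig <- screen$q_value < fdr
  gg <- ggplot2::ggplot(screen, ggplot2::aes(x = .data$beta,
                                             y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$q_value < fdr),
                        alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#1b7837")) +
    ggplot2::labs(x = "association per SD of exposure",
                  y = expression(-log[10](p)),
                  title = unique(screen$exposure)) +
    ggplot2::theme_minimal()
  if (any(sig)) {
    cut <- max(screen$p_value[sig])
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(cut), linetype = "dotted")
  }
  gg
}

#' @export
autoplot.oo_screen <- function(object, ...) plot_volcano(object, ...)
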