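# Multi-metabolite signature derivation: ten disjoint 90/10
# training-validation splits, an inner cross-validated lambda choice per
# split, consistency selection (nonzero in all ten splits), and mean
# cross-split coefficients as the final weights.

#' Derive a multi-metabolite signature by cross-validated elastic net
#'
#' Partitions the discovery sample into ten disjoint train/validation splits
#' (90%/10%). For each split an elastic net is fitted on the training part at
#' the mixing parameter `alpha`, with the penalty `lambda` chosen by an inner
#' k-fold cross-validation (rule `"min"` = minimum CV error, the default, or
#' `"1se"` = largest lambda within one SD of the minimum); the held-out 10%
#' is scored out-of-split. Metabolites with nonzero coefficients in all ten
#' splits form the consistency-selected set; their mean cross-split
#' coefficients (with SDs) are the signature weights.
#'
#' @param metabolites Complete metabolite tibble or matrix (discovery
#'   sample).
#' @param intake Energy-adjusted intake vector (g/day).
#' @param alpha Elastic-net mixing parameter (study presets: 0.4 total olive
#'   oil, 0.2 virgin, 0.3 common).
#' @param exposure_name Label stored in the model.
#' @param n_splits Number of outer splits (default 10).
#' @param inner_k Inner CV folds for the lambda choice (default 10).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param nlambda Lambda path length (default 50).
#' @param seed Seed controlling outer partition and inner folds.
#' @return A list of class `oo_signature`: per-split coefficients,
#'   `selection_count`, the consistency-`selected` metabolites, mean/SD
#'   `weights`, training standardization parameters, intercept, pooled
#'   out-of-split predictions, and the fold assignment.
#' @export
derive_signature <- function(metabolites, intake, alpha,
                             exposure_name = "total_oo", n_splits = 10,
                             inner_k = 10, lambda_rule = c("min", "1se"),
                             nlambda = 50, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  x <- if (is.data.frame(metabolites)) metabolite_matrix(metabolites) else metabolites
  y_raw <- as.numeric(intake)
  n <- nrow(x)
  stopifnot(length(y_raw) == n)
  if (n < n_splits * 2) oo_abort("too few observations for 90/10 splitting")
  # work on unit-variance intake: coefficients become unitless
  # (standardized-metabolite, standardized-intake scale)
  y_scale <- sd(y_raw)
  if (y_scale == 0) oo_abort("intake is constant")
  y <- y_raw / y_scale
  set.seed(seed)
  split_id <- sample(rep(seq_len(n_splits), length.out = n))

  coefs <- matrix(0, ncol(x), n_splits,
                  dimnames = list(colnames(x), paste0("split", seq_len(n_splits))))
  lambdas <- numeric(n_splits)
  oof <- rep(NA_real_, n)
  for (s in seq_len(n_splits)) {
    tr <- split_id != s
    xtr <- x[tr, , drop = FALSE]
    ytr <- y[tr]
    foldid <- sample(rep(seq_len(inner_k), length.out = sum(tr)))
    cv <- cv_enet(xtr, ytr, alpha, foldid, nlambda = nlambda)
    lam <- if (lambda_rule == "min") cv$lambda_min else cv$lambda_1se
    st <- oo_standardize(xtr)
    # warm-start down the path to the chosen lambda (identical solution,
    # far fewer sweeps than a cold single-lambda solve); tight tolerance so
    # the reported coefficients are KKT-certifiable
    lam_path <- cv$lambda[cv$lambda >= lam]
    b <- enet_path_gram(st$x, ytr - mean(ytr), alpha, lam_path,
                        tol_rel = 1e-12)[, length(lam_path)]
    coefs[, s] <- b
    lambdas[s] <- lam
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2L, st$center, "-"),
                 2L, st$scale, "/")
    oof[!tr] <- (as.numeric(xte %*% b) + mean(ytr)) * y_scale
  }

  selection_count <- rowSums(coefs != 0)
  selected <- names(selection_count)[selection_count == n_splits]
  full_st <- oo_standardize(x)
  structure(list(
    exposure = exposure_name, alpha = alpha, lambda_rule = lambda_rule,
    lambdas = lambdas, coefficients = coefs,
    selection_count = selection_count, selected = selected,
    weights = tibble::tibble(
      metabolite = selected,
      coef_mean = rowMeans(coefs[selected, , drop = FALSE]),
      coef_sd = apply(coefs[selected, , drop = FALSE], 1L, sd)),
    center = full_st$center, scale = full_st$scale,
    intercept = mean(y_raw), y_scale = y_scale,
    oof_predictions = oof, intake = y_raw, split_id = split_id, seed = seed),
    class = "oo_signature")
}

#' Apply a signature to new metabolite data
#'
#' Standardizes the selected metabolite columns with the model's stored
#' training parameters (matching columns by name, so column order is
#' irrelevant) and returns the weighted score: the model's predicted intake
#' `intercept + sum_j mean_coef_j * standardized m_j`.
#'
#' @param model An `oo_signature`.
#' @param metabolites New metabolite tibble or matrix; must contain every
#'   selected metabolite.
#' @return Numeric score vector.
#' @export
apply_signature <- function(model, metabolites) {
  stopifnot(inherits(model, "oo_signature"))
  x <- if (is.data.frame(metabolites)) metabolite_matrix(metabolites) else metabolites
  sel <- model$selected
  if (length(sel) == 0) return(rep(model$intercept, nrow(x)))
  missing_cols <- setdiff(sel, colnames(x))
  if (length(missing_cols) > 0) {
    oo_abort(paste0("selected metabolite(s) absent from new data: ",
                    paste(missing_cols, collapse = ", ")))
  }
  xs <- sweep(sweep(x[, sel, drop = FALSE], 2L, model$center[sel], "-"),
              2L, model$scale[sel], "/")
  as.numeric(xs %*% model$weights$coef_mean) * model$y_scale + model$intercept
}

#' Correlation-based validation of a signature
#'
#' In `"discovery"` mode, correlates the pooled out-of-split predictions with
#' the discovery intakes; in `"external"` mode, applies the final averaged
#' model to new data (e.g. the year-1 visit). The 95% confidence interval
#' uses the Fisher z transformation.
#'
#' @param model An `oo_signature`.
#' @param metabolites New metabolite data (external mode only).
#' @param intake Intake vector (external mode only).
#' @param mode `"discovery"` or `"external"`.
#' @return One-row tibble: `r`, `ci_lower`, `ci_upper`, `n`, `data_label`.
#' @export
validate_signature <- function(model, metabolites = NULL, intake = NULL,
                               mode = c("discovery", "external")) {
  mode <- match.arg(mode)
  if (mode == "discovery") {
    score <- model$oof_predictions
    y <- model$intake
    label <- "discovery-baseline"
  } else {
    stopifnot(!is.null(metabolites), !is.null(intake))
    score <- apply_signature(model, metabolites)
    y <- as.numeric(intake)
    label <- "validation-external"
  }
  n <- length(y)
  if (n < 4) oo_abort("confidence interval undefined for n < 4")
  if (sd(score) == 0) {
    oo_abort("signature score is constant; correlation undefined")
  }
  r <- cor(score, y)
  ci <- fisher_ci(r, n)
  tibble::tibble(r = r, ci_lower = ci[1], ci_upper = ci[2], n = n,
                 data_label = label, exposure = model$exposure)
}

#' @export
print.oo_signature <- function(x, ...) {
  cat("<oo_signature>", x$exposure, "| alpha =", x$alpha,
      "|", length(x$selected), "consistency-selected metabolites\n")
  invisible(x)
}

#' @export
tidy.oo_signature <- function(x, ...) {
  tibble::tibble(metabolite = rownames(x$coefficients),
                 selection_count = unname(x$selection_count),
                 coef_mean = rowMeans(x$coefficients),
                 coef_sd = apply(x$coefficients, 1L, sd),
                 selected = rownames(x$coefficients) %in% x$selected,
                 exposure = x$exposure)
}

#' @export
glance.oo_signature <- function(x, ...) {
  disc <- validate_signature(x, mode = "discovery")
  tibble::tibble(exposure = x$exposure, alpha = x$alpha,
                 n_selected = length(x$selected),
                 n_positive = sum(x$weights$coef_mean > 0),
                 n_negative = sum(x$weights$coef_mean < 0),
                 r_discovery = disc$r, ci_lower = disc$ci_lower,
                 ci_upper = disc$ci_upper, n = disc$n)
}

#' @export
autoplot.oo_signature <- function(object, ...) {
  w <- object$weights[order(object$weights$coef_mean), ]
  w$metabolite <- factor(w$metabolite, levels = w$metabolite)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$coef_mean, y = .data$metabolite)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$coef_mean - .data$coef_sd,
                                         xmax = .data$coef_mean + .data$coef_sd),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean coefficient (per-split SD)", y = NULL,
                  title = paste0(object$exposure, ": consistency-selected metabolites")) +
    ggplot2::theme_minimal()
}

#' Serialize / restore a signature model as JSON
#'
#' @param model An `oo_signature`.
#' @param path File path.
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns the restored `oo_signature`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "oo_signature"))
  obj <- unclass(model)
  obj$coefficients <- as.data.frame(obj$coefficients)
  obj$weights <- as.data.frame(obj$weights)
  obj$center <- as.list(obj$center)
  obj$scale <- as.list(obj$scale)
  obj$selection_count <- as.list(obj$selection_count)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- as.matrix(obj$coefficients)
  obj$weights <- tibble::as_tibble(obj$weights)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  obj$selection_count <- unlist(obj$selection_count)
  obj$selected <- as.character(obj$selected %||% character(0))
  structure(obj, class = "oo_signature")
}
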