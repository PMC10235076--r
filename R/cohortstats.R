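#' Read a cohort table
#'
#' One row per coral colony: identifiers, island of origin, genus/species,
#' Symbiodiniaceae and bacterial community profile labels (categorical,
#' taken as given), colony diameter (cm, a proxy of age) and the per-probe
#' TL summary fields (`htl_*` host, `stl_*` symbiont; mean/med/Q1/Q3/IQ in
#' kb).
#'
#' @param path CSV with header `colony_id,island,genus,species,
#'   symbiodiniaceae_profile,bacteria_profile,diameter_cm,htl_mean_kb,...,
#'   stl_iq_kb`.
#' @return A data frame; duplicate colony ids raise an error.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("colony_id", "island", "genus", "diameter_cm", "htl_mean_kb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$colony_id))
    stop("duplicated colony ids in cohort table")
  df
}

#' Ordinary least squares fit over predictor blocks
#'
#' Thin wrapper around [stats::lm()] returning the statistics used
#' downstream: R-squared, adjusted R-squared and AIC under the full
#' Gaussian log-likelihood (so values match standard statistical
#' software; only differences matter for selection). Categorical blocks
#' are dummy-encoded by the model matrix and always enter whole. A perfect
#' fit (RSS of zero) has unbounded likelihood; its AIC is guarded to
#' `-Inf` so it still ranks first. A zero-variance response has R-squared
#' defined as 0.
#'
#' @param response numeric response vector.
#' @param blocks named list of predictor blocks (numeric vectors or
#'   factors/character vectors), each of the response's length.
#' @param label optional descriptor of the model.
#' @return A `model_fit` with `coefficients`, `r2`, `adj_r2`, `aic`, `n`,
#'   `df_residual`, `n_param` (counting intercept, slopes and the error
#'   variance), `p_value` (overall F) and the underlying `lm` object.
#' @export
ols_fit <- function(response, blocks, label = NULL) {
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  dat <- data.frame(.y = response, blocks, check.names = TRUE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  fit <- stats::lm(.y ~ ., data = dat)
  co <- stats::coef(fit)
  if (anyNA(co))
    warning("rank-deficient design: dropping aliased terms ",
            paste(names(co)[is.na(co)], collapse = ", "))
  k_beta <- sum(!is.na(co))
  if (n <= k_beta) stop("more parameters than observations")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((dat$.y - mean(dat$.y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  adj <- if (tss == 0) 0 else 1 - (1 - r2) * (n - 1) / (n - k_beta)
  aic <- if (rss <= tss * 1e-14 || rss == 0) -Inf else stats::AIC(fit)
  fstat <- summary(fit)$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(label = if (is.null(label))
                   paste(names(blocks), collapse = "+") else label,
                 coefficients = co, r2 = r2, adj_r2 = adj, aic = aic,
                 n = n, n_param = k_beta + 1L,
                 df_residual = n - k_beta, p_value = pval, lm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit %s> n=%d, R2=%.4f (adj %.4f), AIC=%.2f\n",
              x$label, x$n, x$r2, x$adj_r2, x$aic))
  invisible(x)
}

#' Telomere-length versus colony-size regression family
#'
#' Fits the three candidate shapes for the TL-size relationship on the
#' natural-log response: `ln(TL) ~ diameter` (linear),
#' `ln(TL) ~ diameter + diameter^2` (quadratic) and
#' `ln(TL) ~ ln(diameter)` (logarithmic). Model ranking by AIC is
#' invariant to the base of the response logarithm. Rows with missing or
#' (for the logarithmic model) non-positive diameters are dropped
#' listwise, with counts recorded.
#'
#' @param cohort cohort data frame (see [read_cohort()]).
#' @param response name of the TL column to model, e.g. `"htl_mean_kb"`.
#' @param genus optional genus filter.
#' @return Named list of three `model_fit`s (`linear`, `quadratic`,
#'   `logarithmic`), each with a `slope` and `slope_p` element added for
#'   the diameter term.
#' @export
fit_tl_size_models <- function(cohort, response = "htl_mean_kb",
                               genus = NULL) {
  if (!is.null(genus)) cohort <- cohort[cohort$genus == genus, , drop = FALSE]
  ok <- is.finite(cohort[[response]]) & cohort[[response]] > 0 &
    is.finite(cohort$diameter_cm)
  cohort <- cohort[ok, , drop = FALSE]
  if (nrow(cohort) < 10L)
    stop("need at least 10 colonies with TL and diameter")
  y <- log(cohort[[response]])
  d <- cohort$diameter_cm
  add_slope <- function(fit, term) {
    sm <- summary(fit$lm)$coefficients
    fit$slope <- unname(sm[term, "Estimate"])
    fit$slope_p <- unname(sm[term, "Pr(>|t|)"])
    fit
  }
  lin <- add_slope(ols_fit(y, list(diameter = d), "linear"), "diameter")
  quad <- add_slope(ols_fit(y, list(diameter = d, diameter2 = d^2),
                            "quadratic"), "diameter")
  pos <- d > 0
  n_dropped_log <- sum(!pos)
  logm <- add_slope(ols_fit(y[pos], list(log_diameter = log(d[pos])),
                            "logarithmic"), "log_diameter")
  logm$n_dropped_nonpositive <- n_dropped_log
  list(linear = lin, quadratic = quad, logarithmic = logm)
}

#' Select the best model by AIC
#'
#' The fit with the lowest AIC wins; exact ties go to the model with
#' fewer parameters. Fits computed on different data subsets are not
#' AIC-comparable and are refused.
#'
#' @param fits list of `model_fit` objects on the same response vector.
#' @return The selected `model_fit`.
#' @export
aic_select <- function(fits) {
  if (length(fits) == 0L) stop("no fits to select from")
  n <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(n)) > 1L)
    stop("fits use different data subsets; AIC values are not comparable")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "n_param")
  best <- which(aic == min(aic))
  fits[[best[which.min(k[best])]]]
}

subset_key <- function(s) paste(sort(s), collapse = "+")

#' R-squared of every predictor-block subset
#'
#' Fits an OLS model for each non-empty subset of the predictor blocks
#' (blocks enter whole: a categorical's dummies are never split) and
#' records its multiple R-squared — the raw material of a commonality
#' analysis.
#'
#' @param response numeric response.
#' @param blocks named list of predictor blocks (at most 10).
#' @return Named numeric vector of R-squared values, names being
#'   `+`-joined sorted block subsets (e.g. `"diameter+island"`).
#' @export
all_subsets_r2 <- function(response, blocks) {
  p <- length(blocks)
  stopifnot(p >= 1L, p <= 10L, !is.null(names(blocks)))
  nm <- names(blocks)
  out <- numeric(0)
  for (mask in seq_len(2^p - 1L)) {
    sel <- nm[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0]
    out[subset_key(sel)] <- ols_fit(response, blocks[sel])$r2
  }
  out
}

#' Commonality analysis of regression R-squared
#'
#' Decomposes the full model's R-squared into one coefficient per
#' non-empty subset of predictor blocks: the unique contribution of each
#' single predictor and the common (shared) contribution of every larger
#' subset. Coefficients `C(S)` are defined by the linear system
#' `R2(M) = sum over S with S intersecting M of C(S)` for every non-empty
#' model `M` — a `(2^p - 1)` square system with a unique solution — which
#' makes the construction verifiable on any number of blocks. They sum
#' exactly to the full-model (non-adjusted) R-squared, and the unique
#' coefficient of X equals `R2(full) - R2(full minus X)`. Negative
#' coefficients are legitimate and indicate suppression.
#'
#' @param r2map named vector from [all_subsets_r2()].
#' @return A `commonality_result`: data frame with `subset`,
#'   `coefficient` and `percent_of_total` (relative to the full-model
#'   R-squared), ordered uniques first, plus the total.
#' @export
commonality <- function(r2map) {
  nm1 <- names(r2map)[!grepl("+", names(r2map), fixed = TRUE)]
  p <- length(nm1)
  subsets <- lapply(seq_len(2^p - 1L), function(mask)
    sort(nm1)[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0])
  keys <- vapply(subsets, subset_key, character(1))
  if (!all(keys %in% names(r2map)))
    stop("r2map is incomplete: missing ",
         paste(setdiff(keys, names(r2map)), collapse = ", "))
  m <- length(keys)
  A <- matrix(0, m, m, dimnames = list(keys, keys))
  for (i in seq_len(m)) for (j in seq_len(m))
    A[i, j] <- as.numeric(length(intersect(subsets[[i]], subsets[[j]])) > 0)
  coefs <- solve(A, r2map[keys])
  resid <- max(abs(A %*% coefs - r2map[keys]))
  if (resid > 1e-8)
    stop("inconsistent r2map: system residual ", format(resid))
  full <- r2map[[subset_key(nm1)]]
  sizes <- lengths(subsets)
  ord <- order(sizes, keys)
  structure(list(
    table = data.frame(
      subset = keys[ord],
      n_blocks = sizes[ord],
      coefficient = unname(coefs[ord]),
      percent_of_total = unname(coefs[ord]) / full * 100),
    total_r2 = full),
    class = "commonality_result")
}

#' @export
print.commonality_result <- function(x, ...) {
  tb <- x$table
  lab <- ifelse(tb$n_blocks == 1L, paste("Unique to", tb$subset),
                paste("Common to", gsub("+", ", ", tb$subset, fixed = TRUE)))
  print(data.frame(contribution = lab,
                   coefficient = round(tb$coefficient, 4),
                   `% total` = round(tb$percent_of_total, 2),
                   check.names = FALSE), row.names = FALSE)
  cat(sprintf("Total (multiple R2): %.4f\n", x$total_r2))
  invisible(x)
}

#' Write a commonality table
#'
#' CSV mirroring the unique/common layout: header
#' `subset,coefficient,percent_of_total`, with a final `Total` row whose
#' coefficient is the full-model multiple R-squared.
#'
#' @param result a `commonality_result`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_commonality <- function(result, path) {
  tb <- result$table[, c("subset", "coefficient", "percent_of_total")]
  tb <- rbind(tb, data.frame(subset = "Total",
                             coefficient = result$total_r2,
                             percent_of_total = 100))
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

#' Pairwise correlation matrix with BH adjustment
#'
#' Spearman rank correlations for TL-parameter and TL-size associations
#' (rank-based, robust to monotone transforms), or Pearson for replicate
#' concordance. Raw p-values of the upper triangle are adjusted with the
#' Benjamini-Hochberg step-up procedure. Constant columns yield `NA`
#' coefficients (undefined, not zero).
#'
#' @param data data frame or matrix of numeric columns.
#' @param method `"spearman"` or `"pearson"`.
#' @return A `correlation_matrix` with symmetric `r`, `p` and
#'   `p_adjusted` matrices (unit diagonal on `r`; `NA` diagonal p).
#' @export
correlation_matrix <- function(data, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  k <- ncol(data)
  if (k < 2L) stop("need at least two columns")
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(data), names(data)))
  diag(r) <- 1
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- data[[i]]; y <- data[[j]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for columns ",
                           names(data)[i], ", ", names(data)[j])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next  # undefined
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                           exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  padj <- p
  padj[up] <- stats::p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(method = method, r = r, p = p, p_adjusted = padj),
            class = "correlation_matrix")
}
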