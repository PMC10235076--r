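test_that("ols_fit matches the closed-form normal-equations solution", {
  set.seed(8)
  n <- 60
  x1 <- rnorm(n)
  f <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  y <- 1 + 2 * x1 + c(a = 0, b = 1.5, c = -1)[f] + rnorm(n)
  fit <- ols_fit(y, list(x1 = x1, grp = f))
  X <- stats::model.matrix(~ x1 + f)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(beta),
               tolerance = 1e-10)
  rss <- sum((y - X %*% beta)^2)
  expect_equal(fit$r2, 1 - rss / sum((y - mean(y))^2), tolerance = 1e-10)
  # Gaussian AIC with intercept + slopes + error variance counted
  k <- ncol(X) + 1
  expect_equal(fit$aic, n * log(rss / n) + n * log(2 * pi) + n + 2 * k,
               tolerance = 1e-8)
})

test_that("ols_fit guards degenerate fits", {
  x <- 1:20
  perfect <- suppressWarnings(ols_fit(3 + 2 * x, list(x = x)))
  expect_equal(perfect$r2, 1)
  expect_identical(perfect$aic, -Inf)
  constant <- suppressWarnings(ols_fit(rep(4, 20), list(x = rnorm(20))))
  expect_equal(constant$r2, 0)
  expect_warning(ols_fit(rnorm(20), list(x = x, x2 = 2 * x)),
                 "rank-deficient")
})

test_that("aic_select takes the lowest AIC, ties to fewer parameters", {
  mk <- function(aic, k, n = 50)
    structure(list(aic = aic, n_param = k, n = n, label = paste0("m", k)),
              class = "model_fit")
  expect_equal(aic_select(list(mk(10, 3), mk(7, 4), mk(12, 2)))$aic, 7)
  expect_equal(aic_select(list(mk(5, 3), mk(5, 2)))$n_param, 2)
  single <- mk(3, 2)
  expect_identical(aic_select(list(single)), single)
  expect_error(aic_select(list(mk(1, 2, n = 50), mk(2, 2, n = 40))),
               "not comparable")
  expect_error(aic_select(list()), "no fits")
})

test_that("the TL-size model family recovers generative shapes", {
  set.seed(101)
  n <- 200
  diam <- runif(n, 10, 80)
  mk_cohort <- function(lntl) data.frame(
    colony_id = paste0("c", 1:n), island = "I1", genus = "Pocillopora",
    diameter_cm = diam, htl_mean_kb = exp(lntl))

  # linear truth with negative slope: slope recovered, log shape rejected.
  # (AIC may prefer the nesting quadratic in ~16% of realizations — that
  # is a property of AIC, not a defect — so selection frequency is
  # checked over replicates below.)
  co <- mk_cohort(2 - 0.01 * diam + rnorm(n, 0, 0.1))
  fits <- fit_tl_size_models(co)
  expect_lt(fits$linear$slope, 0)
  se <- summary(fits$linear$lm)$coefficients["diameter", "Std. Error"]
  expect_lt(abs(fits$linear$slope - (-0.01)), 3 * se)
  expect_lt(fits$linear$aic, fits$logarithmic$aic)
  picks <- vapply(1:50, function(i) {
    coi <- mk_cohort(2 - 0.01 * diam + rnorm(n, 0, 0.1))
    aic_select(fit_tl_size_models(coi))$label
  }, character(1))
  expect_gte(sum(picks == "linear"), 35)   # ~84% expected, 3 sd margin

  # exactly quadratic truth -> quadratic has lowest AIC
  co2 <- mk_cohort(1 + 0.04 * diam - 4e-4 * diam^2 + rnorm(n, 0, 0.05))
  expect_equal(aic_select(fit_tl_size_models(co2))$label, "quadratic")

  expect_error(fit_tl_size_models(co[1:5, ]), "at least 10")
})

test_that("AIC ranking is invariant to the response logarithm base", {
  set.seed(55)
  n <- 120
  diam <- runif(n, 5, 60)
  y_ln <- 1.5 - 0.008 * diam + rnorm(n, 0, 0.2)
  rank_of <- function(y) {
    fits <- list(linear = ols_fit(y, list(d = diam)),
                 quadratic = ols_fit(y, list(d = diam, d2 = diam^2)),
                 logarithmic = ols_fit(y, list(ld = log(diam))))
    names(sort(vapply(fits, `[[`, numeric(1), "aic")))
  }
  expect_identical(rank_of(y_ln), rank_of(y_ln / log(2)))  # log2 response
})

test_that("all_subsets_r2 is consistent on orthogonal and duplicate blocks", {
  set.seed(12)
  n <- 128
  x1 <- rnorm(n); x1 <- x1 - mean(x1)
  z <- rnorm(n)
  x2 <- residuals(lm(z ~ x1))          # exactly orthogonal to x1
  y <- x1 + 0.5 * x2 + rnorm(n)
  r2 <- all_subsets_r2(y, list(x1 = x1, x2 = x2))
  expect_named(r2, c("x1", "x2", "x1+x2"), ignore.order = TRUE)
  expect_equal(r2[["x1"]], ols_fit(y, list(x1 = x1))$r2)
  expect_equal(r2[["x1+x2"]], r2[["x1"]] + r2[["x2"]], tolerance = 1e-8)

  dup <- suppressWarnings(all_subsets_r2(y, list(a = x1, b = x1)))
  expect_equal(dup[["a"]], dup[["a+b"]], tolerance = 1e-10)
  expect_equal(dup[["b"]], dup[["a+b"]], tolerance = 1e-10)
})

test_that("commonality solves the subset system exactly", {
  set.seed(19)
  n <- 150
  x1 <- rnorm(n); x1 <- x1 - mean(x1)
  x2 <- residuals(lm(rnorm(n) ~ x1))
  y <- 2 * x1 + x2 + rnorm(n, 0, 2)

  # single predictor: unique = R2, 100%
  r1 <- all_subsets_r2(y, list(x1 = x1))
  cm1 <- commonality(r1)
  expect_equal(cm1$table$coefficient, unname(r1[["x1"]]))
  expect_equal(cm1$table$percent_of_total, 100)

  # orthogonal predictors: common ~ 0, uniques ~ marginal R2s
  r2 <- all_subsets_r2(y, list(x1 = x1, x2 = x2))
  cm2 <- commonality(r2)
  tb <- cm2$table
  expect_equal(tb$coefficient[tb$subset == "x1+x2"], 0, tolerance = 1e-8)
  expect_equal(tb$coefficient[tb$subset == "x1"], unname(r2[["x1"]]),
               tolerance = 1e-8)
  expect_equal(sum(tb$coefficient), cm2$total_r2, tolerance = 1e-12)

  # duplicated predictor: all shared, nothing unique (3x3 brute force)
  rdup <- suppressWarnings(all_subsets_r2(y, list(a = x1, b = x1)))
  A <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))   # {a},{b},{a,b}
  brute <- solve(A, unname(rdup[c("a", "b", "a+b")]))
  cmd <- commonality(rdup)
  expect_equal(cmd$table$coefficient[match(c("a", "b", "a+b"),
                                           cmd$table$subset)],
               brute, tolerance = 1e-10)
  expect_equal(brute[1], 0, tolerance = 1e-10)
  expect_equal(brute[3], unname(rdup[["a"]]), tolerance = 1e-10)
})

test_that("commonality identities hold on random three-block designs", {
  set.seed(31)
  for (i in 1:10) {
    n <- 90
    blocks <- list(u = rnorm(n),
                   v = factor(sample(letters[1:3], n, replace = TRUE)),
                   w = rnorm(n))
    y <- blocks$u + (blocks$v == "b") + 0.3 * blocks$w + rnorm(n)
    r2 <- all_subsets_r2(y, blocks)
    cm <- commonality(r2)
    full <- r2[["u+v+w"]]
    expect_equal(sum(cm$table$coefficient), unname(full),
                 tolerance = 1e-10)
    expect_equal(sum(cm$table$percent_of_total), 100, tolerance = 1e-6)
    for (b in c("u", "v", "w")) {
      drop_key <- paste(sort(setdiff(c("u", "v", "w"), b)), collapse = "+")
      expect_equal(cm$table$coefficient[cm$table$subset == b],
                   unname(full - r2[[drop_key]]), tolerance = 1e-10)
    }
  }
})

test_that("correlation matrices honor monotone invariance and BH", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 5.5, 7.2)
  cm <- correlation_matrix(data.frame(x = x, ex = exp(x), neg = -x),
                           method = "spearman")
  expect_equal(cm$r["x", "ex"], 1)
  expect_equal(cm$r["x", "neg"], -1)
  expect_true(isSymmetric(cm$r))
  expect_equal(diag(cm$r), c(x = 1, ex = 1, neg = 1))
  off <- upper.tri(cm$p)
  expect_true(all(cm$p_adjusted[off] >= cm$p[off] - 1e-15))

  # BH step-up applied by hand to the matrix's own raw p-values:
  # sort ascending, multiply p_(i) by m/i, enforce monotonicity from the
  # top, undo the sort. Example {.01,.02,.03,.04} -> all .04.
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(77)
  rd <- as.data.frame(matrix(rnorm(30 * 5), 30, 5))
  rd$V2 <- rd$V1 + rnorm(30, 0, 0.4)
  cmr <- correlation_matrix(rd, method = "spearman")
  off <- upper.tri(cmr$p)
  expect_equal(cmr$p_adjusted[off], bh_oracle(cmr$p[off]),
               tolerance = 1e-12)
  # reordering columns permutes the adjusted values identically
  cmp <- correlation_matrix(rd[, c(3, 1, 5, 2, 4)], method = "spearman")
  for (a in names(rd)) for (b in names(rd)) if (a != b)
    expect_equal(cmp$p_adjusted[a, b], cmr$p_adjusted[a, b],
                 tolerance = 1e-12)

  const <- data.frame(a = x, b = rep(1, 7))
  cmc <- correlation_matrix(const, method = "pearson")
  expect_true(is.na(cmc$r["a", "b"]))
  expect_error(correlation_matrix(data.frame(a = 1:2, b = 2:1)),
               "fewer than 3")
})
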