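test_that("standardization centers, scales to unit norm and drops constants", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  y <- c(1, 2, 4)
  expect_message(d <- standardize(x, y), "constant")
  expect_equal(unname(d$x[, "a"]), c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_false("b" %in% colnames(d$x))
  expect_equal(mean(d$y), 0)
  # idempotence on retained columns
  d2 <- standardize(d$x, d$y)
  expect_equal(d2$x, d$x, tolerance = 1e-12)
  expect_error(standardize(cbind(a = c(2, 2, 2)), y), "constant")
})

test_that("one-predictor LARS reaches the OLS solution in a single step", {
  d <- random_design(12, 1, seed = 1)
  p <- lars_path(d)
  expect_equal(p$steps, 1L)
  expect_equal(unname(p$beta[2L, 1L]), sum(d$x[, 1L] * d$y),
               tolerance = 1e-10)
})

test_that("a response orthogonal to every predictor yields a zero-step path", {
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  d <- standardize(x, rnorm(10))
  y_perp <- stats::resid(stats::lm(d$y ~ d$x))
  d$y <- y_perp - mean(y_perp)
  p <- lars_path(d)
  expect_equal(p$steps, 0L)
  expect_true(all(p$beta == 0))
})

test_that("under an orthonormal design the path follows the |x'y| ranking in closed form", {
  # mean-centered orthonormal columns, N = 8, P = 3
  set.seed(6)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(24), 8, 3))))[, 2:4]
  colnames(q) <- c("a", "b", "c")
  targets <- c(0.9, 0.5, 0.2)
  y <- drop(q %*% targets)
  d <- list(x = q, y = y, x_center = colMeans(q),
            x_scale = rep(1, 3), y_center = 0,
            dropped = character(0))
  class(d) <- "lars_design"
  p <- lars_path(d)
  expect_identical(p$active, c("a", "b", "c"))
  # at breakpoint m the common active correlation equals the (m+1)-th |x'y|
  for (m in 1:2) {
    resid_m <- y - q %*% p$beta[m + 1L, ]
    cors <- abs(drop(crossprod(q, resid_m)))
    expect_equal(unname(cors[seq_len(m)]), rep(targets[m + 1L], m),
                 tolerance = 1e-10)
  }
  # closed-form coefficients: soft-threshold at the next entry's correlation
  expect_equal(unname(p$beta[2L, ]), c(0.9 - 0.5, 0, 0), tolerance = 1e-10)
  expect_equal(unname(p$beta[3L, ]), c(0.9 - 0.2, 0.5 - 0.2, 0),
               tolerance = 1e-10)
  expect_equal(unname(p$beta[4L, ]), targets, tolerance = 1e-10)
})

test_that("the full coefficient path matches the reference implementation", {
  d <- random_design(20, 10, seed = 3)
  ref <- sklearn_lars_paths(list(d))[[1L]]
  p <- lars_path(d)
  expect_equal(nrow(p$beta), nrow(ref$coefs))
  expect_lt(max(abs(p$beta - unname(ref$coefs))), 1e-8)
})

test_that("active-set correlations stay equal and dominant along the path", {
  for (seed in 1:5) {
    d <- random_design(15, 8, seed = seed)
    p <- lars_path(d)
    for (m in seq_len(p$steps)) {
      resid_m <- d$y - d$x %*% p$beta[m + 1L, ]
      cors <- abs(drop(crossprod(d$x, resid_m)))
      act <- match(p$active[seq_len(m)], colnames(d$x))
      if (m < p$steps) {
        expect_lt(diff(range(cors[act])), 1e-8)
        expect_lte(max(cors[-act], 0), min(cors[act]) + 1e-8)
      }
    }
    # residual norm is non-increasing along the path
    rss <- vapply(0:p$steps, function(m)
      sum((d$y - d$x %*% p$beta[m + 1L, ])^2), numeric(1L))
    expect_true(all(diff(rss) <= 1e-10))
  }
})

test_that("adjusted R-squared follows its closed form", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(adjusted_r_squared(y, y, 2), 1.0)
  fitted <- y - c(1, 0, 0, 0, 0)   # RSS 1, TSS 10 -> R2 = 0.9
  expect_equal(adjusted_r_squared(y, fitted, 2), 1 - 0.1 * 4 / 2)
  expect_equal(adjusted_r_squared(y, rep(mean(y), 5), 0), 0)
  expect_error(adjusted_r_squared(rep(2, 5), rep(2, 5), 1), "sum of squares")
  expect_error(adjusted_r_squared(y, y, 4), "N >")
})

test_that("Cp with pruning recovers an exact sparse model from a noiseless response", {
  set.seed(10)
  x <- matrix(rnorm(25 * 8), 25, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 2 * x[, 2] - 1.5 * x[, 5]
  d <- standardize(x, y)
  p <- lars_path(d)
  fit <- select_step(p, d, criterion = "cp")
  expect_setequal(fit$selected, c("f2", "f5"))
  expect_gte(fit$adjusted_r_squared, 0.999)
  # original-scale coefficients match the generative ones
  expect_equal(unname(fit$coefficients[c("f2", "f5")]), c(2, -1.5),
               tolerance = 1e-8)
})

test_that("fixed-k selection at k = 0 gives the intercept-only model", {
  d <- random_design(12, 4, seed = 4)
  p <- lars_path(d)
  fit <- select_step(p, d, criterion = "max_steps_k", k = 0)
  expect_length(fit$selected, 0L)
  expect_equal(fit$adjusted_r_squared, 0)
  expect_equal(fit$intercept, d$y_center)
  expect_error(select_step(p, d, criterion = "max_steps_k", k = 99),
               "exceeds")
})

test_that("a pure-noise response selects almost nothing", {
  sizes <- vapply(1:30, function(seed) {
    d <- random_design(25, 60, seed = 100 + seed)
    p <- lars_path(d, max_steps = 23)
    length(select_step(p, d, criterion = "cp")$selected)
  }, numeric(1L))
  expect_lte(median(sizes), 2)
})

test_that("fit_group recovers a planted mixed TF/SF support without noise", {
  cfg <- fixture_config(seed = 31, n_groups = 1, group_sizes = c(20L),
                        n_isoforms = 20L, n_tfs = 10L, n_sfs = 6L,
                        true_support_per_group = 3L, noise_sd = 0)
  d <- fixture_design(cfg)
  g <- d$groups[[1L]]
  group <- structure(list(group_id = 1L, members = g$members),
                     class = "coexpression_group")
  tf_m <- structure(d$tf_strength_true, flavor = "TF",
                    class = c("strength_matrix", "matrix", "array"))
  sf_m <- structure(d$sf_strength_true, flavor = "SF",
                    class = c("strength_matrix", "matrix", "array"))
  fit <- fit_group(group, tf_m, sf_m, d$expression)
  expect_setequal(fit$selected, g$support)
  expect_gte(fit$adjusted_r_squared, 0.999)
  expect_true(fit$kept)
  # factor types follow the matrix of origin
  expect_true(all(fit$factor_type[grep("^TF", fit$selected)] == "TF"))
  expect_true(all(fit$factor_type[grep("^SF", fit$selected)] == "SF"))

  # permutation invariance over isoform row order
  perm_group <- structure(list(group_id = 1L,
                               members = rev(g$members)),
                          class = "coexpression_group")
  fit2 <- fit_group(perm_group, tf_m, sf_m, d$expression)
  expect_setequal(fit2$selected, fit$selected)
  expect_equal(fit2$coefficients[sort(names(fit2$coefficients))],
               fit$coefficients[sort(names(fit$coefficients))],
               tolerance = 1e-8)
})

test_that("an unstructured response is flagged as not kept", {
  cfg <- fixture_config(seed = 32, n_groups = 1, group_sizes = c(15L),
                        n_isoforms = 15L, n_tfs = 8L, n_sfs = 4L,
                        true_support_per_group = 2L)
  d <- fixture_design(cfg)
  g <- d$groups[[1L]]
  expr <- d$expression
  set.seed(77)
  expr$fpkm[g$members, ] <- matrix(runif(length(g$members) *
                                           ncol(expr$fpkm), 6, 12),
                                   length(g$members))
  group <- structure(list(group_id = 1L, members = g$members),
                     class = "coexpression_group")
  tf_m <- structure(d$tf_strength_true, flavor = "TF",
                    class = c("strength_matrix", "matrix", "array"))
  sf_m <- structure(d$sf_strength_true, flavor = "SF",
                    class = c("strength_matrix", "matrix", "array"))
  fit <- fit_group(group, tf_m, sf_m, expr)
  expect_false(fit$kept)
})
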