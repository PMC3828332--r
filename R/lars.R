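#' Standardize a design matrix and response for LARS
#'
#' Predictor columns are centered and scaled to unit Euclidean norm
#' (the LARS convention); constant columns are dropped with a message.
#' The response is centered.  Centering/scaling constants are retained so
#' selected coefficients and the intercept can be reported on the original
#' scale.
#'
#' @param x Numeric matrix (observations x predictors, named columns).
#' @param y Numeric response vector.
#' @return A list of class `lars_design`: `x` (standardized), `y`
#'   (centered), `x_center`, `x_scale`, `y_center`, `dropped` (names of
#'   constant columns).
#' @export
standardize <- function(x, y) {
  x <- as.matrix(x)
  check_that(nrow(x) >= 3L, "need at least 3 observations")
  check_that(nrow(x) == length(y), "x and y dimensions disagree")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  nrm <- sqrt(colSums(xc^2))
  constant <- nrm < 1e-12
  check_that(!all(constant), "all predictor columns are constant")
  if (any(constant))
    message(sprintf("dropping %d constant column(s): %s", sum(constant),
                    paste(colnames(x)[constant], collapse = ", ")))
  xs <- sweep(xc[, !constant, drop = FALSE], 2L, nrm[!constant], "/")
  structure(list(x = xs, y = y - mean(y),
                 x_center = ctr[!constant], x_scale = nrm[!constant],
                 y_center = mean(y), dropped = colnames(x)[constant]),
            class = "lars_design")
}

#' Compute the least-angle regression path
#'
#' Plain LARS (the active set only grows): the first step activates the
#' predictor most correlated with the response; at each step the
#' coefficients advance along the direction equiangular with all active
#' predictors until an inactive predictor attains the same absolute
#' correlation with the residual, which then joins the active set.  At
#' every breakpoint the active predictors share a common absolute
#' correlation with the residual that dominates all inactive ones.
#'
#' @param design A `lars_design` from [standardize()].
#' @param max_steps Maximum number of variables to enter; must not exceed
#'   `min(N - 1, P)`. Defaults to that bound.
#' @return A list of class `lars_path` with `steps` (number of
#'   breakpoints), `active` (factor names in entry order), `beta`
#'   (`(steps + 1) x P` coefficient matrix, first row zero, on the
#'   standardized scale) and `cmax` (maximum absolute correlation at each
#'   breakpoint, starting before the first step).
#' @export
lars_path <- function(design, max_steps = NULL) {
  x <- design$x; y <- design$y
  n <- nrow(x); p <- ncol(x)
  bound <- min(n - 1L, p)
  max_steps <- min(max_steps %||% bound, bound)
  beta <- matrix(0, 1L, p, dimnames = list(NULL, colnames(x)))
  active <- integer(0)
  cvec <- drop(crossprod(x, y))
  cmax <- max(abs(cvec))
  cmax_trace <- cmax
  tol <- 1e-12
  if (cmax < tol)  # response orthogonal to every predictor
    return(structure(list(steps = 0L, active = character(0), beta = beta,
                          cmax = cmax_trace), class = "lars_path"))
  b <- numeric(p)
  for (step in seq_len(max_steps)) {
    inactive <- setdiff(seq_len(p), active)
    j_new <- inactive[which.max(abs(cvec[inactive]))]
    active <- c(active, j_new)
    s <- sign(cvec[active])
    xa <- x[, active, drop = FALSE]
    g <- crossprod(xa)
    ch <- tryCatch(chol(g), error = function(e) NULL)
    if (is.null(ch)) {
      warning(sprintf("rank-deficient active set at step %d; path truncated",
                      step))
      active <- active[-length(active)]
      break
    }
    ginv_s <- backsolve(ch, forwardsolve(t(ch), s))
    aa <- 1 / sqrt(sum(s * ginv_s))
    w <- aa * ginv_s                      # coefficient direction (signed)
    u <- drop(xa %*% w)                   # equiangular vector
    a <- drop(crossprod(x, u))
    cmax <- max(abs(cvec[active]))
    if (length(active) == p || step == max_steps &&
        length(active) == min(n - 1L, p)) {
      gamma <- cmax / aa
    } else {
      others <- setdiff(seq_len(p), active)
      cand <- c((cmax - cvec[others]) / (aa - a[others]),
                (cmax + cvec[others]) / (aa + a[others]))
      cand <- cand[is.finite(cand) & cand > tol]
      gamma <- if (length(cand)) min(cand) else cmax / aa
      gamma <- min(gamma, cmax / aa)
    }
    b[active] <- b[active] + gamma * w
    cvec <- cvec - gamma * a
    beta <- rbind(beta, b)
    cmax_trace <- c(cmax_trace, max(abs(cvec)))
    if (max(abs(cvec)) < tol) break
  }
  rownames(beta) <- NULL
  structure(list(steps = nrow(beta) - 1L,
                 active = colnames(x)[active],
                 beta = beta, cmax = cmax_trace),
            class = "lars_path")
}

#' @export
print.lars_path <- function(x, ...) {
  cat(sprintf("lars_path: %d steps; entry order: %s\n", x$steps,
              paste(x$active, collapse = ", ")))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) (N - 1) / (N - p - 1)` with
#' `R^2 = 1 - RSS / TSS`.
#'
#' @param response Observed response vector.
#' @param fitted Fitted values.
#' @param n_predictors Number of predictors `p` in the model (intercept
#'   not counted); requires `N > p + 1`.
#' @return The adjusted R-squared (a real number, at most 1).
#' @export
adjusted_r_squared <- function(response, fitted, n_predictors) {
  n <- length(response)
  check_that(n > n_predictors + 1L, "need N > n_predictors + 1")
  tss <- sum((response - mean(response))^2)
  check_that(tss > 0, "zero total sum of squares")
  rss <- sum((response - fitted)^2)
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
}

# Stepwise refinement of the LARS-selected active set: alternate backward
# elimination and forward addition on OLS refits of the standardized
# design, minimising the extended BIC
#   n log(RSS/n) + |S| (log n + 2 gamma log P)
# until neither move improves it.  The backward pass discards spurious
# predictors the one-at-a-time path interleaved before the last true
# ones; the forward pass recovers strong predictors the greedy path
# ordering postponed past the chosen breakpoint.  The RSS floor keeps the
# criterion finite on (near-)perfect fits, where removing redundant
# predictors leaves the residual at the floor and the penalty alone
# decides.
refine_selection <- function(x, y, selected, ebic_gamma = 1) {
  n <- nrow(x)
  p <- ncol(x)
  floor_rss <- 1e-12 * max(sum(y^2), 1)
  pen <- log(n) + 2 * ebic_gamma * log(max(p, 2L))
  crit <- function(s) {
    r <- if (length(s)) stats::lm.fit(x[, s, drop = FALSE], y)$residuals else y
    n * log(max(sum(r^2), floor_rss) / n) + length(s) * pen
  }
  cur <- selected
  cur_crit <- crit(cur)
  repeat {
    improved <- FALSE
    while (length(cur)) {
      cand <- vapply(seq_along(cur), function(i) crit(cur[-i]), numeric(1L))
      if (min(cand) < cur_crit - 1e-10) {
        cur_crit <- min(cand)
        cur <- cur[-which.min(cand)]
        improved <- TRUE
      } else break
    }
    repeat {
      outs <- setdiff(colnames(x), cur)
      if (!length(outs) || length(cur) >= n - 2L) break
      cand <- vapply(outs, function(j) crit(c(cur, j)), numeric(1L))
      if (min(cand) < cur_crit - 1e-10) {
        cur_crit <- min(cand)
        cur <- c(cur, outs[which.min(cand)])
        improved <- TRUE
      } else break
    }
    if (!improved) break
  }
  cur
}

#' Choose a model size along a LARS path
#'
#' With `criterion = "cp"` the breakpoint minimising Mallows'
#' `Cp = RSS / sigma2 - N + 2 m` is chosen.  The residual variance
#' `sigma2` is estimated from the model halfway along the path: with more
#' candidate predictors than observations the path's largest model fits
#' the data essentially perfectly, so a variance estimate taken there
#' collapses to zero and Cp would always choose the deepest model.  When
#' even the mid-path model is an essentially perfect fit, the smallest
#' step attaining that residual level is taken.  Because the
#' one-at-a-time path can interleave spurious predictors before the last
#' true ones (and postpone true ones past the breakpoint), the chosen
#' active set is then refined by alternating backward elimination and
#' forward addition on ordinary-least-squares refits under the extended
#' BIC (`prune = TRUE`, the default for `"cp"`), which retains the
#' strong predictors and discards interlopers.  With `criterion =
#' "max_steps_k"` the breakpoint after `k` variables is taken (no
#' pruning by default), mirroring the fixed-k formulation of the
#' algorithm.  Coefficients and the intercept are reported on the
#' original scale; after pruning they come from the refit.
#'
#' @param path A `lars_path`.
#' @param design The `lars_design` the path was computed on.
#' @param criterion `"cp"` or `"max_steps_k"`.
#' @param k Step to take when `criterion = "max_steps_k"`.
#' @param prune Refine the chosen active set by stepwise search (default
#'   `TRUE` for `"cp"`, `FALSE` for `"max_steps_k"`).
#' @param ebic_gamma Extended-BIC penalty weight used during pruning
#'   (default 1).
#' @return A list of class `lars_fit`: `selected` (factor names),
#'   `coefficients` (original scale, named), `intercept`, `step`
#'   (breakpoint before pruning), `adjusted_r_squared`, `criterion`,
#'   `cp` (trace when applicable).
#' @export
select_step <- function(path, design, criterion = c("cp", "max_steps_k"),
                        k = NULL, prune = NULL, ebic_gamma = 1) {
  criterion <- match.arg(criterion)
  prune <- prune %||% (criterion == "cp")
  n <- nrow(design$x)
  p <- ncol(design$x)
  m_max <- path$steps
  rss <- vapply(0:m_max, function(m)
    sum((design$y - design$x %*% path$beta[m + 1L, ])^2), numeric(1L))
  cp <- NULL
  if (criterion == "cp") {
    if (m_max == 0L) {
      step <- 0L
    } else {
      m0 <- min(ceiling(n / 2), m_max)
      sigma2 <- rss[m0 + 1L] / max(n - m0 - 1L, 1L)
      tss <- sum(design$y^2)
      if (!is.finite(sigma2) || sigma2 < 1e-10 * tss / n) {
        # essentially perfect reference fit: smallest model at that level
        step <- min(which(rss <= rss[m0 + 1L] + 1e-8 * tss)) - 1L
      } else {
        cp <- rss / sigma2 - n + 2 * (0:m_max)
        step <- which.min(cp) - 1L
      }
    }
  } else {
    check_that(!is.null(k) && k >= 0L, "criterion max_steps_k requires k")
    check_that(k <= m_max, "k = %d exceeds path length %d", k, m_max)
    step <- as.integer(k)
  }
  sel <- path$active[seq_len(step)]
  if (prune && length(sel)) {
    sel <- refine_selection(design$x, design$y, sel,
                            ebic_gamma = ebic_gamma)
    beta_std <- numeric(ncol(design$x))
    names(beta_std) <- colnames(design$x)
    if (length(sel))
      beta_std[sel] <- stats::lm.fit(design$x[, sel, drop = FALSE],
                                     design$y)$coefficients
  } else {
    beta_std <- path$beta[step + 1L, ]
    sel <- names(beta_std)[beta_std != 0]
  }
  coef_orig <- beta_std[sel] / design$x_scale[sel]
  intercept <- design$y_center -
    sum(coef_orig * design$x_center[sel])
  fitted_centered <- drop(design$x %*% beta_std)
  adj <- if (!length(sel)) 0 else
    adjusted_r_squared(design$y + design$y_center,
                       fitted_centered + design$y_center, length(sel))
  structure(list(selected = sel, coefficients = coef_orig,
                 intercept = intercept, step = step,
                 adjusted_r_squared = adj, criterion = criterion, cp = cp),
            class = "lars_fit")
}

#' @export
print.lars_fit <- function(x, ...) {
  cat(sprintf("lars_fit: %d factor(s) selected (step %d), adjusted R^2 = %.4f\n",
              length(x$selected), x$step, x$adjusted_r_squared))
  if (length(x$selected))
    print(round(x$coefficients, 4))
  invisible(x)
}

# Per-isoform expression response used in the regression.
group_response <- function(group, expr,
                           response = c("condition_mean", "all_mean",
                                        "log2_condition_mean")) {
  response <- match.arg(response)
  idx <- match(group$members, rownames(expr$fpkm))
  check_that(!anyNA(idx), "group member(s) missing from expression table")
  vapply(seq_along(idx), function(k) {
    i <- idx[k]
    up <- expr$info$up_condition[match(group$members[k],
                                       expr$info$isoform_id)]
    v <- switch(response,
                condition_mean = mean(expr$fpkm[i, expr$condition == up]),
                all_mean = mean(expr$fpkm[i, ]),
                log2_condition_mean =
                  log2(mean(expr$fpkm[i, expr$condition == up]) + 1))
    v
  }, numeric(1L))
}

#' Fit the sparse regulatory model for one co-expressed group
#'
#' Assembles the design matrix (TF strength columns followed by SF
#' strength columns, rows = group members), standardizes it, runs the LARS
#' path and chooses a model size.  The response per isoform is by default
#' the mean expression over the samples of its up-regulated condition.
#' Groups whose adjusted R-squared falls below `r2_min` are flagged as not
#' kept (ill-fitting).
#'
#' @param group A `coexpression_group`.
#' @param tf_strength,sf_strength `strength_matrix` objects whose rows
#'   cover the group members (members missing from a matrix contribute
#'   all-zero rows, with a message).
#' @param expr The `expression_table` providing the response.
#' @param response Response summary; see [group_response()].
#' @param criterion,k Model-size choice; see [select_step()].
#' @param max_steps Path length bound passed to [lars_path()]; defaults to
#'   `min(N - 2, P)` so residual-variance estimation and refits keep at
#'   least one residual degree of freedom.
#' @param r2_min Keep threshold on adjusted R-squared (default 0.5).
#' @return A list of class `group_fit`: the `lars_fit` fields plus
#'   `group_id`, `factor_type` (named TF/SF per selected factor), `kept`,
#'   `n`, and `response`.
#' @export
fit_group <- function(group, tf_strength, sf_strength, expr,
                      response = "condition_mean",
                      criterion = "cp", k = NULL, max_steps = NULL,
                      r2_min = 0.5) {
  members <- group$members
  check_that(length(members) >= 3L, "group too small to fit (N < 3)")
  take_rows <- function(m, flavor) {
    miss <- setdiff(members, rownames(m))
    if (length(miss))
      message(sprintf("%d member(s) missing from %s strengths; rows set to 0",
                      length(miss), flavor))
    out <- matrix(0, length(members), ncol(m),
                  dimnames = list(members, colnames(m)))
    hit <- intersect(members, rownames(m))
    out[hit, ] <- m[hit, , drop = FALSE]
    out
  }
  xt <- take_rows(tf_strength, "TF")
  xs <- take_rows(sf_strength, "SF")
  x <- cbind(xt, xs)
  type <- c(rep("TF", ncol(xt)), rep("SF", ncol(xs)))
  names(type) <- colnames(x)
  y <- group_response(group, expr, response)
  design <- standardize(x, y)
  max_steps <- max_steps %||% min(length(members) - 2L, ncol(design$x))
  path <- lars_path(design, max_steps = max_steps)
  fit <- select_step(path, design, criterion = criterion, k = k)
  fit$group_id <- group$group_id
  fit$factor_type <- type[fit$selected]
  fit$kept <- fit$adjusted_r_squared >= r2_min
  fit$n <- length(members)
  fit$response_values <- stats::setNames(y, members)
  fit$path <- path
  class(fit) <- c("group_fit", class(fit))
  fit
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(group_id = fit$group_id, selected = fit$selected,
         factor_type = unname(fit$factor_type),
         coefficients = unname(fit$coefficients),
         intercept = fit$intercept, step = fit$step,
         adjusted_r_squared = fit$adjusted_r_squared,
         criterion = fit$criterion, kept = fit$kept, n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
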