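#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle vectors, with a one-tailed
#' (positive association) permutation p-value: rows and columns of `d2` are
#' relabelled jointly `n_perm` times and
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#'
#' @param d1,d2 Symmetric zero-diagonal matrices with identical labels in
#'   identical order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `mantel_result` (list: r, p, n_perm, n).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  d1 <- check_dissimilarity(d1, "d1")
  d2 <- check_dissimilarity(d2, "d2")
  if (!identical(rownames(d1), rownames(d2))) {
    abort("d1 and d2 must share labels in the same order")
  }
  n <- nrow(d1)
  if (n < 3) abort("need at least 3 observations")
  v1 <- upper_tri_vec(d1)
  r_obs <- cor(v1, upper_tri_vec(d2))
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(v1, upper_tri_vec(d2[p, p])) >= r_obs) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel statistic r: %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(statistic = x$r, p.value = x$p, n_perm = x$n_perm, n = x$n)
}

# trace of H %*% G without forming the product
tr_hg <- function(h, g) sum(h * t(g))

#' Distance-based permutational multivariate ANOVA (PERMANOVA)
#'
#' Sequential (Type-I) sums of squares on the Gower-centered matrix
#' G = -1/2 J (D*D) J: for nested design matrices with intercept,
#' SS_k = tr(H_1..k G) - tr(H_1..k-1 G), R2_k = SS_k / tr(G), and
#' F_k = (SS_k / df_k) / (SS_res / df_res). P-values come from `n_perm`
#' joint row/column permutations of D with the usual +1 correction.
#'
#' @param d Symmetric zero-diagonal dissimilarity matrix over samples.
#' @param covariates Data frame of model terms, one column per term, rows
#'   aligned with `d`'s labels; terms enter in column order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `permanova_fit`; see [tidy.permanova_fit()].
#' @export
permanova <- function(d, covariates, n_perm = 999, seed = 1L) {
  d <- check_dissimilarity(d, "d")
  n <- nrow(d)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) abort("covariate rows must match d")
  terms <- names(covariates)
  g <- gower_center(d)
  total_ss <- sum(diag(g))
  # nested hat matrices
  x <- matrix(1, n, 1)
  hats <- list(x %*% solve(crossprod(x)) %*% t(x))
  dfs <- numeric(length(terms))
  prev_ncol <- 1L
  for (k in seq_along(terms)) {
    mm <- stats::model.matrix(~., data = covariates[, seq_len(k), drop = FALSE])
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      abort(sprintf("collinear covariate: term '%s'", terms[k]))
    }
    hats[[k + 1]] <- mm %*% solve(crossprod(mm)) %*% t(mm)
    dfs[k] <- ncol(mm) - prev_ncol
    prev_ncol <- ncol(mm)
  }
  df_res <- n - 1 - sum(dfs)
  ss_for <- function(gm) {
    tr <- vapply(hats, tr_hg, 0, g = gm)
    ss <- diff(tr)
    ss_res <- sum(diag(gm)) - tr[length(tr)]
    f <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- ss_for(g)
  set.seed(as.integer(seed))
  exceed <- integer(length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    fp <- ss_for(g[p, p])$f
    exceed <- exceed + as.integer(fp >= obs$f)
  }
  structure(list(
    terms = terms, df = dfs, ss = obs$ss, r2 = obs$ss / total_ss,
    f = obs$f, p = (1 + exceed) / (1 + n_perm),
    df_res = df_res, ss_res = obs$ss_res, r2_res = obs$ss_res / total_ss,
    total_ss = total_ss, n_perm = n_perm, n = n
  ), class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations, n = %d)\n", x$n_perm, x$n))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 5)
  invisible(x)
}

#' Tidy a PERMANOVA fit
#'
#' One row per model term plus a `Residual` row: df, SS, R2, pseudo-F and
#' permutation p-value. `glance()` gives model-level R2 and permutation
#' settings.
#'
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  bind_rows(
    tibble(term = x$terms, df = x$df, sum_sq = x$ss, r2 = x$r2,
           statistic = x$f, p.value = x$p),
    tibble(term = "Residual", df = x$df_res, sum_sq = x$ss_res,
           r2 = x$r2_res, statistic = NA_real_, p.value = NA_real_)
  )
}

#' @rdname tidy.permanova_fit
#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble(r2_model = sum(x$r2), r2_residual = x$r2_res,
         total_ss = x$total_ss, n = x$n, n_perm = x$n_perm)
}

#' Partial F-test for one predictor given covariates
#'
#' Least-squares fits of the nested models `response ~ covariates` and
#' `response ~ covariates + predictor`;
#' F = ((RSS0 - RSS1) / q) / (RSS1 / (n - p1)) with p from the F
#' distribution. A perfect fit of the full model reports F = Inf, p = 0.
#'
#' @param data Data frame holding all variables.
#' @param response,predictor Column names (character scalars).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return One-row tibble: statistic, p.value, df1, df2.
#' @export
partial_f_test <- function(data, response, predictor,
                           covariates = character()) {
  data <- as.data.frame(data)
  n <- nrow(data)
  f0 <- stats::reformulate(if (length(covariates)) covariates else "1",
                           response = response)
  f1 <- stats::reformulate(c(covariates, predictor), response = response)
  m0 <- lm(f0, data = data)
  m1 <- lm(f1, data = data)
  p1 <- m1$rank
  if (p1 <= m0$rank) abort("singular design: predictor adds no rank")
  if (n <= p1 + 1) abort("need n > number of parameters + 1")
  rss0 <- sum(stats::residuals(m0)^2)
  rss1 <- sum(stats::residuals(m1)^2)
  q <- p1 - m0$rank
  df2 <- n - p1
  if (rss1 <= .Machine$double.eps * rss0) {
    return(tibble(statistic = Inf, p.value = 0, df1 = q, df2 = df2))
  }
  f <- ((rss0 - rss1) / q) / (rss1 / df2)
  tibble(statistic = f, p.value = pf(f, q, df2, lower.tail = FALSE),
         df1 = q, df2 = df2)
}
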