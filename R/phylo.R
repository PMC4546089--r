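#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node with daughter
#' values x_left, x_right on working branches b_left, b_right, the contrast
#' is `(x_left - x_right) / sqrt(b_left + b_right)`, the ancestral value is
#' the branch-length weighted average, and the parent branch is extended by
#' `b_left * b_right / (b_left + b_right)`. Multifurcations are resolved to
#' zero-length branches first, and zero-length branches are replaced by
#' `eps`; both adjustments are reported in attributes.
#'
#' @param tree An ape `phylo` tree (>= 2 tips).
#' @param trait Named numeric vector of tip values (one per tip).
#' @param eps Replacement for zero-length branches.
#' @return Numeric vector of `n - 1` standardized contrasts, named by ape's
#'   internal node numbers (deterministic node order).
#' @export
pic_contrasts <- function(tree, trait, eps = 1e-8) {
  prep <- prepare_tree(tree, eps)
  tree <- prep$tree
  x <- trait_for_tree(trait, tree)
  n <- length(tree$tip.label)
  if (n < 2L) stop("contrasts need at least 2 tips")
  nnode <- tree$Nnode
  val <- c(unname(x), rep(NA_real_, nnode))
  blen <- numeric(n + nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  contrasts <- stats::setNames(rep(NA_real_, nnode),
                               as.character((n + 1):(n + nnode)))
  # children-first traversal: postorder edge list, parents by first appearance
  po <- stats::reorder(tree, "postorder")
  for (node in unique(po$edge[, 1])) {
    ch <- kids[[as.character(node)]]
    stopifnot(length(ch) == 2L)
    b <- blen[ch]
    v <- val[ch]
    contrasts[as.character(node)] <- (v[1] - v[2]) / sqrt(sum(b))
    val[node] <- (v[1] / b[1] + v[2] / b[2]) / (1 / b[1] + 1 / b[2])
    blen[node] <- blen[node] + b[1] * b[2] / sum(b)
  }
  structure(contrasts, resolved = prep$resolved,
            zero_replaced = prep$zero_replaced)
}

# Resolve multifurcations (zero-length branches) and epsilon-replace
# zero-length branches so the pruning algorithm is defined.
prepare_tree <- function(tree, eps = 1e-8) {
  resolved <- FALSE
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    resolved <- TRUE
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  zero <- tree$edge.length <= 0
  if (any(zero)) tree$edge.length[zero] <- eps
  list(tree = tree, resolved = resolved, zero_replaced = sum(zero))
}

#' Blomberg's K statistic
#'
#' With C the Brownian covariance matrix implied by the branch lengths and
#' `a = (1'C^-1 x) / (1'C^-1 1)` the GLS phylogenetic mean,
#' `K = [(MSE0/MSE)_obs] / [(MSE0/MSE)_exp]` where
#' `MSE0 = (x-a)'(x-a)/(n-1)`, `MSE = (x-a)'C^-1(x-a)/(n-1)` and
#' `(MSE0/MSE)_exp = [tr(C) - n / sum(C^-1)] / (n-1)`. K = 1 is the Brownian
#' expectation; K > 1 means more signal than Brownian motion.
#'
#' @inheritParams pic_contrasts
#' @return The K value (scalar).
#' @export
blomberg_k <- function(tree, trait, eps = 1e-8) {
  prep <- prepare_tree(tree, eps)
  tree <- prep$tree
  x <- trait_for_tree(trait, tree)
  n <- length(x)
  C <- ape::vcv(tree)
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular Brownian covariance (zero-length structure): ",
         conditionMessage(e)))
  one <- rep(1, n)
  a <- as.numeric(one %*% Ci %*% x) / as.numeric(one %*% Ci %*% one)
  d <- x - a
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(d %*% Ci %*% d) / (n - 1)
  if (mse <= 0 || mse0 == 0) {
    stop("trait has no variance on the tree; K undefined")
  }
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation significance of phylogenetic signal
#'
#' The observed statistic is the variance of the phylogenetically
#' independent contrasts; the null distribution shuffles trait values across
#' tips. Lower contrast variance than the null means stronger signal
#' (one-sided): `p = (1 + #[null <= observed]) / (n_perm + 1)`.
#'
#' @inheritParams pic_contrasts
#' @param n_perm Number of permutations (values < 99 give coarse p
#'   resolution and trigger a warning).
#' @param seed Integer seed.
#' @return A list of class `k_result`: `K`, `pic_variance`, `p`, `n_perm`.
#' @export
k_significance <- function(tree, trait, n_perm = 999L, seed = 1L,
                           eps = 1e-8) {
  if (n_perm < 99L) warning("n_perm < 99 gives coarse p-value resolution")
  prep <- prepare_tree(tree, eps)
  tree <- prep$tree
  x <- trait_for_tree(trait, tree)
  n <- length(x)
  # contrasts are a linear map of tip values: precompute it once so the
  # permutation loop is a matrix product
  L <- vapply(seq_len(n), function(i) {
    unit <- stats::setNames(numeric(n), names(x))
    unit[i] <- 1
    unname(pic_contrasts(tree, unit, eps))
  }, numeric(n - 1L))
  obs <- stats::var(as.numeric(L %*% x))
  perms <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) x[sample.int(n)], numeric(n))
  })
  null_var <- apply(L %*% perms, 2L, stats::var)
  p <- (1 + sum(null_var <= obs)) / (n_perm + 1)
  structure(list(K = blomberg_k(tree, trait, eps), pic_variance = obs,
                 p = p, n_perm = n_perm),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg K = %.4f, PIC variance = %.4g, p = %.4g (%d perms)\n",
              x$K, x$pic_variance, x$p, x$n_perm))
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression `response ~ predictor` with error covariance equal to the
#' Brownian tree covariance: `beta = (X'C^-1 X)^-1 X'C^-1 y`, slope t-test
#' on n - 2 df, and `r^2 = 1 - RSS/TSS` computed on the GLS-whitened scale
#' (TSS relative to the phylogenetic mean). With `covariance = "identity"`
#' the fit reduces to ordinary least squares.
#'
#' @param tree An ape `phylo` tree.
#' @param response,predictor Named numeric tip vectors.
#' @param covariance `"brownian"` (PGLS) or `"identity"` (ordinary GLS).
#' @param log_both Log10-transform both variables first (requires positive
#'   values).
#' @return A list of class `gls_result`: `coefficients`, `slope_se`,
#'   `t_value`, `p_value`, `r_squared`, `covariance_mode`, `df`.
#' @export
pgls <- function(tree, response, predictor,
                 covariance = c("brownian", "identity"), log_both = FALSE) {
  covariance <- match.arg(covariance)
  prep <- prepare_tree(tree)
  tree <- prep$tree
  y <- trait_for_tree(response, tree)
  x <- trait_for_tree(predictor, tree)
  if (log_both) {
    if (any(y <= 0) || any(x <= 0)) stop("log transform requires positive values")
    y <- log10(y); x <- log10(x)
  }
  n <- length(y)
  C <- if (covariance == "brownian") ape::vcv(tree) else diag(n)
  gls_core(cbind(`(Intercept)` = 1, slope = x), y, C, covariance)
}

# Shared GLS machinery: whiten by the Cholesky factor, OLS on the whitened
# scale, slope inference and GLS r-squared.
gls_core <- function(X, y, C, mode) {
  n <- length(y)
  xnames <- colnames(X)
  U <- chol(C)
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12) stop("collinear predictors in GLS design")
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  resid <- yw - Xw %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  # TSS on the whitened scale around the GLS (phylogenetic) mean
  onew <- backsolve(U, rep(1, n), transpose = TRUE)
  mu <- sum(onew * yw) / sum(onew^2)
  tss <- sum((yw - mu * onew)^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_
  slope_i <- length(beta)  # single-predictor design: slope is last column
  structure(list(coefficients = stats::setNames(beta, xnames),
                 slope_se = se[slope_i],
                 t_value = tval[slope_i],
                 p_value = 2 * stats::pt(abs(tval[slope_i]), df,
                                         lower.tail = FALSE),
                 r_squared = r2, covariance_mode = mode, df = df),
            class = "gls_result")
}

#' @export
print.gls_result <- function(x, ...) {
  cat(sprintf("GLS (%s): slope = %.4f (SE %.4f), t = %.3f, p = %.4g, r2 = %s\n",
              x$covariance_mode, x$coefficients[["slope"]], x$slope_se,
              x$t_value, x$p_value,
              ifelse(is.na(x$r_squared), "NA",
                     sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Linear trend along a phylogenetic order
#'
#' Ordinary least-squares regression of a per-species trait on its ordinal
#' phylogenetic position (outgroup = 0 ... most derived = n - 1), testing
#' for directional change along the tree. The slope sign gives the
#' direction. A constant trait returns slope 0 with r-squared `NA`.
#'
#' @param values Numeric trait per species.
#' @param order Optional integer positions (default `0:(n-1)` in the order
#'   of `values`; see [ladder_order()] for a tree-derived default).
#' @return A `gls_result` with `covariance_mode = "identity"`.
#' @export
gls_trend <- function(values, order = NULL) {
  n <- length(values)
  if (n < 3L) stop("trend test needs at least 3 species")
  if (is.null(order)) order <- seq_len(n) - 1
  if (stats::var(values) == 0) {
    return(structure(list(coefficients = c(`(Intercept)` = values[1],
                                           slope = 0),
                          slope_se = NA_real_, t_value = NA_real_,
                          p_value = NA_real_, r_squared = NA_real_,
                          covariance_mode = "identity", df = n - 2L),
                     class = "gls_result"))
  }
  gls_core(cbind(`(Intercept)` = 1, slope = as.numeric(order)),
           values, diag(n), "identity")
}

#' Ladderized tip order of a tree
#'
#' A tree-derived default for the ordinal phylogenetic position used by
#' [gls_trend()]: tips of the ladderized tree numbered from 0.
#'
#' @param tree An ape `phylo` tree.
#' @return Named integer vector (0-based positions by tip label).
#' @export
ladder_order <- function(tree) {
  lt <- ape::ladderize(tree)
  ord <- lt$edge[lt$edge[, 2] <= length(lt$tip.label), 2]
  stats::setNames(seq_along(ord) - 1L, lt$tip.label[ord])
}
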