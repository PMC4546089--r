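#' Ranked TE-family abundance vector
#'
#' Treats each TE family as a species and its copies (or reads, or scaled
#' genome fractions) as individuals. Abundances may be fractional: pipeline
#' outputs are genome fractions, which are scaled to pseudo-counts by
#' `scale` (default reads per million). Ranks are assigned by descending
#' abundance; ties are ranked by family label order (stable).
#'
#' @param counts Positive numeric abundances.
#' @param families Optional family labels.
#' @param scale Multiplier applied to `counts` (use 1 for raw counts).
#' @return An object of class `abundance_vector` with fields `families`,
#'   `counts` (sorted descending), `J` (total), `S` (richness), `ranks`.
#' @export
abundance_vector <- function(counts, families = NULL, scale = 1) {
  stopifnot(length(counts) >= 1L, all(counts > 0), scale > 0)
  if (is.null(families)) {
    families <- if (!is.null(names(counts))) names(counts) else
      paste0("family", seq_along(counts))
  }
  counts <- counts * scale
  o <- order(-counts, families)
  structure(list(families = families[o], counts = unname(counts[o]),
                 J = sum(counts), S = length(counts),
                 ranks = seq_along(counts)),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat("abundance_vector: S =", x$S, "families, J =",
      format(x$J, digits = 6), "individuals\n")
  invisible(x)
}

as_abundance <- function(x, scale = 1) {
  if (inherits(x, "abundance_vector")) x else abundance_vector(x, scale = scale)
}

#' Brokenstick (null model) expected abundances
#'
#' Individuals are distributed at random among the observed families; no
#' parameters are fitted. The expectation at rank r is
#' `(J/S) * sum_{x=r}^{S} 1/x`, and the expectations sum to J.
#'
#' @param J Total number of individuals.
#' @param S Number of families.
#' @return Numeric vector of expected abundances by rank.
#' @export
expected_null <- function(J, S) {
  stopifnot(S >= 1, J >= S)
  (J / S) * rev(cumsum(1 / rev(seq_len(S))))
}

# Poisson log-likelihood sum(a * log(mu) - mu), the shared convention across
# all five models (the a! constant is dropped; include_constant restores it
# with lgamma for fractional abundances).
poisson_loglik <- function(a, mu, include_constant = FALSE) {
  if (any(mu <= 0) || any(!is.finite(mu))) return(-Inf)
  ll <- sum(a * log(mu) - mu)
  if (include_constant) ll <- ll - sum(lgamma(a + 1))
  ll
}

rad_fit_obj <- function(model, parameters, expected, loglik, k, S,
                        converged = TRUE, note = NULL) {
  structure(list(model = model, parameters = parameters,
                 expected = expected, loglik = loglik, k = k,
                 BIC = -2 * loglik + k * log(S), S = S,
                 converged = converged, note = note),
            class = "rad_fit")
}

#' @export
print.rad_fit <- function(x, ...) {
  cat(sprintf("rad_fit [%s]: loglik = %.4f, k = %d, BIC = %.4f\n",
              x$model, x$loglik, x$k, x$BIC))
  if (length(x$parameters))
    cat("  parameters:", paste(names(x$parameters),
                               format(x$parameters, digits = 5),
                               sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# Deterministic multistart bounded optimization of the Poisson log-likelihood
# over a transformed parameter space.
rad_optimize <- function(a, mu_fun, starts, lower, upper) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[s, ]),
                   function(par) -poisson_loglik(a, mu_fun(par)),
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  best
}

#' Niche-preemption (geometric series) fit
#'
#' Expected abundance `J * alpha * (1 - alpha)^(r-1)`: each rank takes a
#' constant proportion alpha of what remains, a straight line on the
#' log-abundance RAD plot. One parameter, fitted by Poisson ML.
#'
#' @param vec An [abundance_vector()] (or raw counts).
#' @return A `rad_fit`.
#' @export
fit_preemption <- function(vec) {
  v <- as_abundance(vec)
  stopifnot(v$S >= 2)
  a <- v$counts; J <- v$J; r <- v$ranks
  mu_fun <- function(par) {
    alpha <- stats::plogis(par[1])
    J * alpha * (1 - alpha)^(r - 1)
  }
  starts <- matrix(stats::qlogis(c(0.05, 0.2, 0.5, 0.8, 0.95)), ncol = 1)
  best <- rad_optimize(a, mu_fun, starts, -20, 20)
  if (is.null(best)) stop("preemption fit failed to converge")
  alpha <- stats::plogis(best$par[1])
  rad_fit_obj("Preemption", c(alpha = alpha), mu_fun(best$par),
              -best$value, 1L, v$S)
}

#' Lognormal RAD fit
#'
#' Expected abundance `exp(mu + sigma * qnorm((S - r + 0.5) / S))` with
#' `(mu, sigma)` by Poisson ML; assumes log abundances are normally
#' distributed over ranks. Two parameters.
#'
#' @inheritParams fit_preemption
#' @return A `rad_fit`.
#' @export
fit_lognormal <- function(vec) {
  v <- as_abundance(vec)
  stopifnot(v$S >= 3)
  a <- v$counts; S <- v$S; r <- v$ranks
  q <- stats::qnorm((S - r + 0.5) / S)
  mu_fun <- function(par) exp(par[1] + exp(par[2]) * q)
  lm0 <- mean(log(a)); ls0 <- stats::sd(log(a))
  if (!is.finite(ls0) || ls0 <= 0) ls0 <- 0.5
  starts <- cbind(c(lm0, lm0, lm0 - 1, lm0 + 1, lm0),
                  log(c(ls0, ls0 / 2, ls0, ls0, 2 * ls0)))
  best <- rad_optimize(a, mu_fun, starts,
                       c(-30, log(1e-8)), c(30, log(50)))
  if (is.null(best)) stop("lognormal fit failed to converge")
  rad_fit_obj("Lognormal",
              c(mu = best$par[1], sigma = exp(best$par[2])),
              mu_fun(best$par), -best$value, 2L, S)
}

#' Zipf RAD fit
#'
#' Expected abundance `J * p * r^gamma`, with `p` the fitted proportion of
#' the most abundant family (constrained to (0, 1]) and `gamma` a decay
#' coefficient (negative for decreasing abundances). Two parameters by
#' Poisson ML.
#'
#' @inheritParams fit_preemption
#' @return A `rad_fit`.
#' @export
fit_zipf <- function(vec) {
  v <- as_abundance(vec)
  stopifnot(v$S >= 3)
  a <- v$counts; J <- v$J; r <- v$ranks
  # par = (log p, gamma), p <= 1
  mu_fun <- function(par) J * exp(par[1]) * r^par[2]
  p0 <- min(a[1] / J, 0.999)
  starts <- cbind(log(c(p0, p0, 0.5 * p0, 2 * p0, p0)),
                  c(-1, -0.5, -1.5, -1, -2))
  starts[, 1] <- pmin(starts[, 1], 0)
  best <- rad_optimize(a, mu_fun, starts, c(-30, -10), c(0, 10))
  if (is.null(best)) stop("Zipf fit failed to converge")
  rad_fit_obj("Zipf", c(p = exp(best$par[1]), gamma = best$par[2]),
              mu_fun(best$par), -best$value, 2L, v$S)
}

#' Zipf-Mandelbrot RAD fit
#'
#' Expected abundance `J * c * (r + beta)^gamma` with `beta > -1`; reduces to
#' Zipf at `beta = 0` (c = p). Three parameters by Poisson ML; the multistart
#' includes the fitted Zipf solution, so the Mandelbrot log-likelihood is
#' never below the Zipf one (nesting). Non-convergence is flagged, never
#' silent.
#'
#' @inheritParams fit_preemption
#' @return A `rad_fit`.
#' @export
fit_mandelbrot <- function(vec) {
  v <- as_abundance(vec)
  stopifnot(v$S >= 4)
  a <- v$counts; J <- v$J; r <- v$ranks
  # par = (log c, log(beta + 1), gamma)
  mu_fun <- function(par)
    J * exp(par[1]) * (r + exp(par[2]) - 1)^par[3]
  zf <- fit_zipf(v)
  starts <- rbind(
    c(log(zf$parameters[["p"]]), 0, zf$parameters[["gamma"]]), # beta = 0
    c(log(zf$parameters[["p"]]), log(2), zf$parameters[["gamma"]]),
    c(log(zf$parameters[["p"]]), log(6), 1.5 * zf$parameters[["gamma"]]),
    c(log(min(a[1] / J, 0.99)), log(1.5), -1),
    c(log(min(a[1] / J, 0.99)), log(11), -2))
  best <- rad_optimize(a, mu_fun, starts, c(-30, -6, -10), c(5, 6, 10))
  converged <- !is.null(best) && is.finite(best$value)
  if (!converged) {
    return(rad_fit_obj("Mandelbrot", c(c = NA, beta = NA, gamma = NA),
                       rep(NA_real_, v$S), -Inf, 3L, v$S,
                       converged = FALSE,
                       note = "optimizer failed from every start"))
  }
  ll <- -best$value
  # nested model: never report a likelihood below the Zipf optimum
  if (ll < zf$loglik) {
    best$par <- c(log(zf$parameters[["p"]]), 0, zf$parameters[["gamma"]])
    ll <- zf$loglik
  }
  rad_fit_obj("Mandelbrot",
              c(c = exp(best$par[1]), beta = exp(best$par[2]) - 1,
                gamma = best$par[3]),
              mu_fun(best$par), ll, 3L, v$S)
}

#' Fit all five RAD models and rank them by BIC
#'
#' Attempts Null (brokenstick), Preemption, Lognormal, Zipf and Mandelbrot on
#' the same abundance vector under the identical Poisson likelihood
#' convention, and ranks the successful fits ascending by
#' `BIC = -2 loglik + k ln(S)`. Models whose S precondition fails are
#' excluded and listed in `excluded`.
#'
#' @inheritParams fit_preemption
#' @param scale Scale for raw fractional abundances, see
#'   [abundance_vector()].
#' @return An object of class `rad_selection`: `fits` (ranked list),
#'   `best` (winning model name), `delta_bic` (to the runner-up),
#'   `table` (model/loglik/k/BIC data.frame), `excluded`.
#' @export
select_model <- function(vec, scale = 1) {
  v <- as_abundance(vec, scale = scale)
  fitters <- list(
    Null = function(v) {
      mu <- expected_null(v$J, v$S)
      rad_fit_obj("Null", numeric(), mu, poisson_loglik(v$counts, mu), 0L,
                  v$S)
    },
    Preemption = fit_preemption, Lognormal = fit_lognormal,
    Zipf = fit_zipf, Mandelbrot = fit_mandelbrot)
  min_S <- c(Null = 1, Preemption = 2, Lognormal = 3, Zipf = 3,
             Mandelbrot = 4)
  fits <- list(); excluded <- character(); errors <- character()
  for (m in names(fitters)) {
    if (v$S < min_S[[m]]) { excluded <- c(excluded, m); next }
    f <- tryCatch(fitters[[m]](v), error = function(e) conditionMessage(e))
    if (inherits(f, "rad_fit")) fits[[m]] <- f
    else errors <- c(errors, paste0(m, ": ", f))
  }
  if (length(fits) == 0L) {
    stop("every RAD model failed: ", paste(errors, collapse = "; "))
  }
  bic <- vapply(fits, `[[`, 0, "BIC")
  fits <- fits[order(bic)]
  tab <- data.frame(model = names(fits),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, `[[`, 0L, "k"),
                    BIC = vapply(fits, `[[`, 0, "BIC"),
                    row.names = NULL)
  structure(list(fits = fits, best = names(fits)[1],
                 delta_bic = if (length(fits) > 1)
                   tab$BIC[2] - tab$BIC[1] else NA_real_,
                 table = tab, excluded = excluded, errors = errors,
                 abundance = v),
            class = "rad_selection")
}

#' @export
print.rad_selection <- function(x, ...) {
  cat("RAD model selection over S =", x$abundance$S, "families:\n")
  print(x$table, row.names = FALSE)
  cat("best:", x$best, "(delta BIC to runner-up:",
      format(x$delta_bic, digits = 4), ")\n")
  invisible(x)
}

#' Shannon diversity and evenness
#'
#' `H = -sum p_i ln p_i` with `p_i = count_i / J`; evenness `E = H / ln(S)`
#' (undefined at S = 1, reported as `NA`).
#'
#' @inheritParams fit_preemption
#' @return A list of class `diversity_stats`: `H`, `E`, `richness`.
#' @export
diversity_stats <- function(vec) {
  v <- as_abundance(vec)
  p <- v$counts / v$J
  H <- -sum(p * log(p))
  E <- if (v$S > 1) H / log(v$S) else NA_real_
  structure(list(H = H, E = E, richness = v$S), class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("Shannon H = %.4f, evenness E = %s, richness S = %d\n",
              x$H, ifelse(is.na(x$E), "NA", sprintf("%.4f", x$E)),
              x$richness))
  invisible(x)
}

#' Simulate an abundance vector from a RAD model
#'
#' Draws Poisson counts around the model's rank-expectation curve (for the
#' lognormal, the plotting-position curve
#' `exp(mu + sigma * qnorm((S - r + 0.5)/S))`, i.e. the same curve the fit
#' estimates); used for the model recovery simulations.
#'
#' @param model One of "preemption", "lognormal", "zipf".
#' @param S Number of families.
#' @param J Total individuals (expectation scale; unused by the lognormal,
#'   whose scale is `exp(mu)`).
#' @param params Named list of model parameters (`alpha`; `mu`, `sigma`;
#'   `p`, `gamma`).
#' @param seed Integer seed.
#' @return An [abundance_vector()] of the positive draws.
#' @export
rad_simulate <- function(model = c("preemption", "lognormal", "zipf"),
                         S, J, params, seed) {
  model <- match.arg(model)
  r <- seq_len(S)
  with_local_seed(seed, {
    mu <- switch(model,
      preemption = J * params$alpha * (1 - params$alpha)^(r - 1),
      lognormal = exp(params$mu + params$sigma *
                        stats::qnorm((S - r + 0.5) / S)),
      zipf = J * params$p * r^params$gamma)
    x <- stats::rpois(S, mu)
    x <- x[x > 0]
    abundance_vector(x)
  })
}
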