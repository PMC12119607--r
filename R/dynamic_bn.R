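# Dynamic Bayesian network over exposure repetitions.
#
# Transitions follow a first-order multivariate Markov process
#   x_{e,v} = X_{e-1, parents(v)} beta_{e,v} + eps,  eps ~ N(0, sigma2),
# where the previous-exposure block contains the node's own lagged value
# plus its AOP parents evaluated at e-1, and dose enters as an additional
# unpenalized covariate. Because the late phenotypic endpoints are strongly
# correlated, coefficients are ridge-regularized with the penalty selected
# per (node, transition) by closed-form leave-one-out cross-validation.
# Transition probabilities are computed by likelihood weighting: evidence
# particles are proposed uniformly over [cutoff, 2 x marginal mean] and
# weighted by the model's Gaussian marginal density at e-1.

#' Ridge regression with unpenalized intercept
#'
#' Minimizes `||y - b0 - X b||^2 + lambda ||b||^2` with predictors
#' standardized internally; coefficients are returned on the original
#' scale. Columns listed in `unpenalized` (e.g. dose) are excluded from the
#' penalty. `lambda = 0` reduces to OLS.
#'
#' @param X design matrix (no intercept column).
#' @param y response vector.
#' @param lambda ridge penalty, >= 0.
#' @param unpenalized character vector of column names left unpenalized.
#' @return list with `beta` (named, `"(Intercept)"` first), `sigma2`
#'   (residual variance, denominator `n - df` with `df = tr(H)`), `df`, and
#'   `hat` (leverages of the linear smoother, for LOOCV).
#' @export
ridge_fit <- function(X, y, lambda, unpenalized = character(0)) {
  X <- as.matrix(X)
  if (!ncol(X) || !nrow(X)) stop_domain("empty design matrix")
  if (nrow(X) != length(y)) stop_domain("rows(X) must equal length(y)")
  if (lambda < 0) stop_domain("lambda must be >= 0")
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep], `-`), 2,
              sds[keep], `/`)
  A <- cbind(`(Intercept)` = 1, Xs)
  pen <- c(0, ifelse(colnames(Xs) %in% unpenalized, 0, 1))
  G <- crossprod(A) + lambda * diag(pen)
  Minv <- solve(G)
  bs <- drop(Minv %*% crossprod(A, y))
  fitted <- drop(A %*% bs)
  hat <- rowSums((A %*% Minv) * A)
  df <- sum(hat)
  sigma2 <- sum((y - fitted)^2) / max(length(y) - df, 1)
  beta <- setNames(numeric(ncol(X) + 1), c("(Intercept)", colnames(X)))
  beta[colnames(X)[keep]] <- bs[-1] / sds[keep]
  beta["(Intercept)"] <- bs[1] - sum(bs[-1] * mu[keep] / sds[keep])
  list(beta = beta, sigma2 = sigma2, df = df, hat = hat, fitted = fitted)
}

#' Ridge penalty selection by leave-one-out cross-validation
#'
#' Uses the closed-form LOOCV identity for linear smoothers,
#' `e_i^loo = (y_i - yhat_i) / (1 - h_ii)`, so no refitting is needed.
#' Ties (within `1e-10` relative) are broken toward the larger penalty.
#' A constant response is degenerate: the maximum of the grid is returned
#' with a warning.
#'
#' @param X design matrix.
#' @param y response vector (length >= 3).
#' @param grid positive candidate penalties.
#' @param unpenalized passed to [ridge_fit()].
#' @return list with `lambda` (the selected penalty) and `cv_errors`
#'   (mean squared LOOCV error per grid value, named).
#' @export
loocv_lambda <- function(X, y, grid = default_lambda_grid(),
                         unpenalized = character(0)) {
  if (!length(grid) || any(grid <= 0)) stop_domain("grid must be positive and nonempty")
  if (length(y) < 3) stop_domain("need >= 3 rows for LOOCV")
  grid <- sort(grid)
  if (sd(y) == 0) {
    warning("constant response: returning the largest penalty", call. = FALSE)
    return(list(lambda = max(grid),
                cv_errors = setNames(rep(0, length(grid)), format(grid))))
  }
  cv <- vapply(grid, function(l) {
    f <- ridge_fit(X, y, l, unpenalized = unpenalized)
    r <- (y - f$fitted) / (1 - f$hat)
    mean(r^2)
  }, numeric(1))
  best <- min(cv)
  # ties toward more regularization
  lambda <- max(grid[cv <= best * (1 + 1e-10)])
  list(lambda = lambda, cv_errors = setNames(cv, format(grid)))
}

#' Default ridge penalty grid
#'
#' 50 log-spaced values spanning `[1e-3, 1e3]`.
#' @return numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-3, 3, length.out = 50)

#' Fit the dynamic Bayesian network transitions
#'
#' For every non-root node `v` and every transition `e-1 -> e`, regresses
#' the draws of `v` at exposure `e` on the previous-exposure block — `v`'s
#' own value and its AOP parents at `e-1` — plus the dose as an
#' unpenalized covariate (set `include_dose = FALSE` to drop it). Rows are
#' the resampled draws aligned across exposures by (donor, dose, draw
#' index); the resampler guarantees that alignment. The ridge penalty is
#' selected per (node, transition) by [loocv_lambda()] on a subsample of
#' `cv_rows` rows (LOOCV leverages are exact on that subsample; the final
#' fit uses all rows).
#'
#' @param resamples an `aop_resamples` object covering consecutive
#'   exposures.
#' @param graph the [aop_graph].
#' @param lambda_grid candidate penalties.
#' @param include_dose include dose as an unpenalized covariate?
#' @param cv_rows maximum rows used for penalty selection.
#' @param cv_seed seed for the CV subsample.
#' @return object of class `"dbn"`: `transitions[[e]][[v]]` with `parents`
#'   (previous-exposure regressors), `beta`, `sigma2`, `lambda`; plus
#'   `marginals` (per exposure, dose and node: mean and SD of the draws)
#'   and bookkeeping fields.
#' @examples
#' sim <- simulate_invitro(generator_config(N = 3L, E = 3L))
#' rs <- resample_dataset(sim$data, M = 50L, seed = 1)
#' dyn <- fit_dbn(rs)
#' coef(dyn, exposure = 2)$AO
#' @export
fit_dbn <- function(resamples, graph = default_aop(),
                    lambda_grid = default_lambda_grid(),
                    include_dose = TRUE, cv_rows = 2000L, cv_seed = 1L) {
  nodes <- attr(resamples, "nodes")
  exposures <- sort(unique(resamples$exposure))
  if (length(exposures) < 2) stop_domain("need >= 2 exposure slices")
  if (any(diff(exposures) != 1)) {
    stop_domain("missing exposure slice(s): ",
                paste(setdiff(seq(min(exposures), max(exposures)), exposures),
                      collapse = ", "))
  }
  ord_key <- order(resamples$donor, resamples$dose, resamples$draw)
  transitions <- list()
  for (e in exposures[-1]) {
    prev <- resamples[resamples$exposure == e - 1, , drop = FALSE]
    cur <- resamples[resamples$exposure == e, , drop = FALSE]
    prev <- prev[order(prev$donor, prev$dose, prev$draw), , drop = FALSE]
    cur <- cur[order(cur$donor, cur$dose, cur$draw), , drop = FALSE]
    aligned <- identical(prev$donor, cur$donor) &&
      identical(prev$dose, cur$dose) && identical(prev$draw, cur$draw)
    if (!aligned) {
      stop_domain("draws are not aligned between exposures ", e - 1, " and ", e)
    }
    Xprev <- as.matrix(prev[, nodes, drop = FALSE])
    tr_e <- list()
    for (v in setdiff(graph$order, graph$root)) {
      pa <- setdiff(node_parents(graph, v), graph$root)
      regs <- unique(c(v, pa))
      D <- Xprev[, regs, drop = FALSE]
      colnames(D) <- paste0(regs, "_prev")
      unpen <- character(0)
      if (include_dose) {
        D <- cbind(D, dose = prev$dose)
        unpen <- "dose"
      }
      y <- cur[[v]]
      n <- length(y)
      if (n > cv_rows) {
        set.seed(substream_seed(cv_seed, c(e, match(v, nodes))))
        sub <- sample.int(n, cv_rows)
      } else {
        sub <- seq_len(n)
      }
      sel <- loocv_lambda(D[sub, , drop = FALSE], y[sub], grid = lambda_grid,
                          unpenalized = unpen)
      fit <- ridge_fit(D, y, sel$lambda, unpenalized = unpen)
      tr_e[[v]] <- list(parents = colnames(D), beta = fit$beta,
                        sigma2 = fit$sigma2, lambda = sel$lambda,
                        cv_errors = sel$cv_errors)
    }
    transitions[[as.character(e)]] <- tr_e
  }
  marg <- aggregate(resamples[, nodes, drop = FALSE],
                    by = list(exposure = resamples$exposure,
                              dose = resamples$dose),
                    FUN = mean)
  marg_sd <- aggregate(resamples[, nodes, drop = FALSE],
                       by = list(exposure = resamples$exposure,
                                 dose = resamples$dose),
                       FUN = sd)
  structure(
    list(graph = graph, transitions = transitions,
         marginal_mean = marg, marginal_sd = marg_sd,
         exposures = exposures, include_dose = include_dose,
         lambda_grid = lambda_grid, nodes = nodes),
    class = "dbn"
  )
}

#' @export
print.dbn <- function(x, ...) {
  cat("Dynamic Bayesian network:", length(x$transitions),
      "transition(s) over exposures", paste(range(x$exposures), collapse = "-"),
      "\n")
  for (e in names(x$transitions)) {
    lams <- sapply(x$transitions[[e]], `[[`, "lambda")
    cat(sprintf("  %s -> %s : lambda* in [%.3g, %.3g]\n",
                as.integer(e) - 1L, e, min(lams), max(lams)))
  }
  invisible(x)
}

#' @export
coef.dbn <- function(object, exposure = NULL, ...) {
  if (is.null(exposure)) {
    lapply(object$transitions, function(tr) lapply(tr, `[[`, "beta"))
  } else {
    lapply(object$transitions[[as.character(exposure)]], `[[`, "beta")
  }
}

#' @export
summary.dbn <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$transitions), function(e) {
    tr <- object$transitions[[e]]
    do.call(rbind, lapply(names(tr), function(v) {
      data.frame(exposure = as.integer(e), node = v,
                 lambda = tr[[v]]$lambda, sigma2 = tr[[v]]$sigma2,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(table = tab), class = "summary.dbn")
}

#' @export
print.summary.dbn <- function(x, ...) {
  cat("Dynamic BN transition summary\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# Marginal mean/SD of a node at (exposure, dose), linearly interpolated in
# dose between the fitted dose levels.
dbn_marginal <- function(model, node, exposure, dose) {
  mm <- model$marginal_mean
  ms <- model$marginal_sd
  sel <- mm$exposure == exposure
  if (!any(sel)) stop_domain("no marginal information at exposure ", exposure)
  d <- mm$dose[sel]
  if (length(d) == 1) {
    return(c(mean = mm[sel, node], sd = ms[sel, node]))
  }
  c(mean = approx(d, mm[sel, node], xout = dose, rule = 2)$y,
    sd = approx(d, ms[sel, node], xout = dose, rule = 2)$y)
}

#' Likelihood-weighted transition probability
#'
#' Estimates `P(target_e > Delta | evidence_{e-1} in [low, high], dose)`
#' under the fitted transition model. Evidence particles are proposed
#' uniformly over the range (default: `[cutoff, 2 x marginal mean]` with
#' `cutoff = delta`, the activation threshold) and weighted by the Gaussian
#' likelihood of the evidence under the model's marginal at `e-1`; the
#' remaining previous-exposure regressors are drawn from their marginals,
#' the target is sampled from the fitted transition, and `p` is the
#' weighted fraction of particles with target > `delta`.
#'
#' @param model a fitted `"dbn"`.
#' @param target target node (at exposure `exposure`).
#' @param exposure exposure repetition of the target; evidence sits at
#'   `exposure - 1`.
#' @param evidence evidence node identifier.
#' @param dose dose (ug/mL) conditioned on.
#' @param delta activation threshold, natural-log scale.
#' @param evidence_range optional `c(low, high)` overriding the default
#'   `[delta, 2 x marginal mean]`.
#' @param particles number of particles.
#' @param seed integer seed.
#' @return object of class `"transition_result"`: `p`, `ess` (effective
#'   sample size), `se` (weighted MC standard error), `range`, `particles`.
#' @export
transition_probability <- function(model, target, exposure, evidence,
                                   dose, delta, evidence_range = NULL,
                                   particles = 10000L, seed = 1L) {
  stopifnot(inherits(model, "dbn"))
  tr <- model$transitions[[as.character(exposure)]]
  if (is.null(tr)) stop_domain("model has no transition into exposure ", exposure)
  f <- tr[[target]]
  if (is.null(f)) stop_domain("unknown target node '", target, "'")
  if (particles < 1) stop_domain("particle count must be >= 1")
  em <- dbn_marginal(model, evidence, exposure - 1, dose)
  if (is.null(evidence_range)) {
    evidence_range <- c(delta, 2 * em["mean"])
  }
  lo <- evidence_range[1]; hi <- evidence_range[2]
  if (!(lo < hi)) {
    stop_domain("degenerate evidence range [", format(lo), ", ", format(hi),
                "]: widen it (e.g. pass evidence_range explicitly)")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- runif(particles, lo, hi)
  w <- dnorm(u, em["mean"], em["sd"])
  if (sum(w) <= 0) {
    stop_domain("zero total particle weight: evidence range lies too far in ",
                "the marginal's tail; widen the range")
  }
  # previous-exposure regressor block
  regs <- f$parents
  Xp <- matrix(NA_real_, particles, length(regs), dimnames = list(NULL, regs))
  for (r in regs) {
    if (r == "dose") {
      Xp[, r] <- dose
    } else {
      nd <- sub("_prev$", "", r)
      if (nd == evidence) {
        Xp[, r] <- u
      } else {
        m <- dbn_marginal(model, nd, exposure - 1, dose)
        Xp[, r] <- rnorm(particles, m["mean"], m["sd"])
      }
    }
  }
  mean_t <- drop(cbind(1, Xp) %*% f$beta)
  t_draw <- mean_t + rnorm(particles, 0, sqrt(f$sigma2))
  ind <- as.numeric(t_draw > delta)
  wsum <- sum(w)
  p <- sum(w * ind) / wsum
  ess <- wsum^2 / sum(w^2)
  se <- sqrt(sum((w / wsum)^2 * (ind - p)^2))
  structure(list(p = unname(p), ess = unname(ess), se = unname(se),
                 range = unname(c(lo, hi)), particles = particles,
                 target = target, evidence = evidence,
                 exposure = exposure, dose = dose, delta = delta),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf(
    "P(%s_%d > %.3f | %s_%d in [%.3f, %.3f], dose %.0f) = %.4f (ESS %.0f)\n",
    x$target, x$exposure, x$delta, x$evidence, x$exposure - 1,
    x$range[1], x$range[2], x$dose, x$p, x$ess))
  invisible(x)
}

#' Transition-probability distribution over donor subsets
#'
#' Reruns the resample -> fit -> transition-probability pipeline on every
#' subset of `k` of the `N` donors (all `choose(N, k)` combinations — 20
#' for the default 3-of-6) and summarizes the spread of the transition
#' probability per (exposure, dose) as box statistics.
#'
#' @param data an `invitro_data` data.frame covering all donors.
#' @param graph the [aop_graph].
#' @param k donor subset size.
#' @param target,evidence target/evidence nodes (see
#'   [transition_probability()]).
#' @param exposures transitions to evaluate (target exposures >= 2).
#' @param doses doses to evaluate.
#' @param delta activation threshold, natural-log scale.
#' @param M resampler draws per cell (kept modest: the pipeline runs once
#'   per subset).
#' @param particles particles per transition query.
#' @param seed master seed.
#' @param lambda_grid passed to [fit_dbn()].
#' @return data.frame with one row per (exposure, dose): `n_subsets`,
#'   box statistics `min`, `q1`, `median`, `q3`, `max`; the per-subset
#'   probabilities are kept in attribute `"subset_probabilities"`.
#' @export
donor_subset_distribution <- function(data, graph = default_aop(), k = 3L,
                                      target = "AO", evidence = "KE4",
                                      exposures = NULL, doses = NULL,
                                      delta = threshold_to_log(2, "log2FC"),
                                      M = 200L, particles = 5000L, seed = 1L,
                                      lambda_grid = default_lambda_grid()) {
  donors <- sort(unique(data$donor))
  N <- length(donors)
  if (k > N) stop_domain("k = ", k, " exceeds the number of donors (", N, ")")
  subsets <- combn(donors, k, simplify = FALSE)
  doses <- doses %||% setdiff(sort(unique(data$dose)), 0)
  exposures <- exposures %||% (min(data$exposure) + 1):max(data$exposure)
  probs <- array(NA_real_,
                 dim = c(length(subsets), length(exposures), length(doses)),
                 dimnames = list(NULL, exposures, doses))
  for (si in seq_along(subsets)) {
    sub_data <- data[data$donor %in% subsets[[si]], , drop = FALSE]
    rs <- resample_dataset(sub_data, graph, M = M,
                           seed = substream_seed(seed, si))
    dyn <- fit_dbn(rs, graph, lambda_grid = lambda_grid)
    for (ei in seq_along(exposures)) for (di in seq_along(doses)) {
      probs[si, ei, di] <- tryCatch(
        transition_probability(
          dyn, target = target, exposure = exposures[ei],
          evidence = evidence, dose = doses[di], delta = delta,
          particles = particles,
          seed = substream_seed(seed, c(si, ei, di)))$p,
        error = function(err) {
          warning("subset ", si, ", exposure ", exposures[ei], ", dose ",
                  doses[di], ": ", conditionMessage(err), call. = FALSE)
          NA_real_
        })
    }
  }
  rows <- do.call(rbind, lapply(seq_along(exposures), function(ei) {
    do.call(rbind, lapply(seq_along(doses), function(di) {
      pk <- probs[, ei, di][!is.na(probs[, ei, di])]
      fn <- if (length(pk)) five_num(pk) else
        c(min = NA_real_, q1 = NA_real_, median = NA_real_,
          q3 = NA_real_, max = NA_real_)
      data.frame(exposure = exposures[ei], dose = doses[di],
                 n_subsets = length(subsets), t(fn),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  attr(rows, "subset_probabilities") <- probs
  attr(rows, "subsets") <- subsets
  rows
}

#' Serialize a fitted dynamic BN to JSON
#'
#' @param model a fitted `"dbn"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dbn_json <- function(model, path) {
  obj <- list(transitions = lapply(model$transitions, function(tr) {
    lapply(tr, function(f) {
      list(parents_prev = f$parents, beta = as.list(f$beta),
           sigma2 = f$sigma2, lambda_star = f$lambda)
    })
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
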