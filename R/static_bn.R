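# Static linear-Gaussian Bayesian network over the AOP.
#
# For one exposure repetition, every non-root node v is modeled as
#   x_v | x_parents ~ N( x_parents' beta_v, sigma2_v ),
# fitted by OLS on the pooled resampled draws (all donors and doses) with
# the dose appended as the root-node value. Risk summaries are
# threshold-exceedance probabilities P(node > Delta | dose) estimated by
# forward (ancestral) sampling with the dose fixed as an interventional
# root assignment.

#' Fit a Gaussian Bayesian network to one exposure slice
#'
#' Pools the resampled log fold-change draws of every (donor, dose) cell at
#' one exposure repetition and fits, per non-root node, an ordinary
#' least-squares regression of the node on its AOP parents (the dose column
#' is the root node's value, in ug/mL). Predictors are standardized
#' internally for numerical stability and coefficients are returned on the
#' original scale. Exactly collinear parents raise an error naming them.
#'
#' @param resamples an `aop_resamples` object from [resample_dataset()].
#' @param graph the [aop_graph] the network is defined on.
#' @param exposure exposure repetition to fit.
#' @return an object of class `"gbn"`: per-node `parents`, `beta` (named,
#'   first element `"(Intercept)"`), `sigma2` (residual variance,
#'   denominator `n - p`) and in-sample `r2`; plus `graph`, `exposure`,
#'   `nobs` and the fitted `dose_range`.
#' @seealso [forward_sample()], [event_probability()], [probability_curve()]
#' @examples
#' sim <- simulate_invitro(generator_config(N = 3L, E = 2L))
#' rs <- resample_dataset(sim$data, M = 50L, seed = 1)
#' fit <- fit_gbn(rs, exposure = 2)
#' coef(fit)$AO
#' @export
fit_gbn <- function(resamples, graph = default_aop(), exposure) {
  nodes <- attr(resamples, "nodes")
  sl <- resamples[resamples$exposure == exposure, , drop = FALSE]
  if (!nrow(sl)) stop_domain("no resampled draws at exposure ", exposure)
  X <- as.matrix(sl[, c(nodes), drop = FALSE])
  X <- cbind(X, dose = sl$dose)
  colnames(X)[ncol(X)] <- graph$root
  fits <- list()
  for (v in setdiff(graph$order, graph$root)) {
    pa <- node_parents(graph, v)
    fits[[v]] <- ols_node_fit(X[, pa, drop = FALSE], X[, v], v)
  }
  structure(
    list(graph = graph, exposure = exposure, fits = fits, nobs = nrow(X),
         dose_range = range(sl$dose)),
    class = "gbn"
  )
}

# OLS with internal standardization of predictors; coefficients
# back-transformed to the original scale.
ols_node_fit <- function(Xp, y, node) {
  n <- length(y)
  p <- ncol(Xp)
  mu <- colMeans(Xp)
  sds <- apply(Xp, 2, sd)
  if (any(sds == 0)) {
    # constant parent: carried by the intercept, slope 0
    keep <- sds > 0
  } else {
    keep <- rep(TRUE, p)
  }
  Xs <- sweep(sweep(Xp[, keep, drop = FALSE], 2, mu[keep], `-`), 2,
              sds[keep], `/`)
  A <- cbind(`(Intercept)` = 1, Xs)
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    bad <- colnames(A)[qa$pivot[(qa$rank + 1):ncol(A)]]
    stop_domain("collinear parents for node '", node, "': ",
                paste(bad, collapse = ", "))
  }
  bs <- qr.coef(qa, y)
  res <- y - A %*% bs
  sigma2 <- sum(res^2) / max(n - ncol(A), 1)
  beta <- setNames(numeric(p + 1), c("(Intercept)", colnames(Xp)))
  beta[colnames(Xp)[keep]] <- bs[-1] / sds[keep]
  beta["(Intercept)"] <- bs[1] - sum(bs[-1] * mu[keep] / sds[keep])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  list(parents = colnames(Xp), beta = beta, sigma2 = sigma2, r2 = r2)
}

#' @export
print.gbn <- function(x, ...) {
  cat("Gaussian Bayesian network fit, exposure", x$exposure,
      "(", x$nobs, "draws )\n")
  for (v in names(x$fits)) {
    f <- x$fits[[v]]
    cat(sprintf("  %-5s ~ %-22s sigma2 = %-8.4g R2 = %.3f\n", v,
                paste(f$parents, collapse = " + "), f$sigma2,
                if (is.na(f$r2)) NA else f$r2))
  }
  invisible(x)
}

#' @export
coef.gbn <- function(object, ...) {
  lapply(object$fits, function(f) f$beta)
}

#' @export
summary.gbn <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$fits), function(v) {
    f <- object$fits[[v]]
    data.frame(node = v, parents = paste(f$parents, collapse = "+"),
               sigma2 = f$sigma2, r2 = f$r2, stringsAsFactors = FALSE)
  }))
  structure(list(exposure = object$exposure, nobs = object$nobs, table = tab),
            class = "summary.gbn")
}

#' @export
print.summary.gbn <- function(x, ...) {
  cat("GBN fit at exposure", x$exposure, "on", x$nobs, "draws\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Conditional-mean predictions from a fitted GBN
#'
#' For each non-root node returns `x_parents' beta`, the model's
#' conditional mean given the observed parent values in `newdata`.
#'
#' @param object a fitted `"gbn"`.
#' @param newdata data.frame/matrix with one column per node (log fold
#'   change) and a column named after the root (dose).
#' @param ... unused.
#' @return matrix of conditional means, one column per non-root node.
#' @export
predict.gbn <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  out <- sapply(names(object$fits), function(v) {
    f <- object$fits[[v]]
    Xp <- as.matrix(newdata[, f$parents, drop = FALSE])
    drop(cbind(1, Xp) %*% f$beta)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(object$fits)))
  out
}

#' Forward (ancestral) sampling from a fitted GBN
#'
#' Fixes the dose root at the given value (an interventional assignment)
#' and samples every non-root node in topological order from
#' `N(x_parents' beta, sigma2)`. With `epsilon > 0` each sample's dose is
#' drawn uniformly from `[dose - epsilon, dose + epsilon]`, reproducing the
#' windowed query `P(KE > Delta | d in [d +/- eps])`.
#'
#' @param model a fitted `"gbn"`.
#' @param dose root dose in ug/mL; values outside the fitted range warn
#'   (extrapolation) but proceed.
#' @param M number of samples.
#' @param seed integer seed.
#' @param epsilon half-width of the dose window (default 0: exact dose).
#' @return M x (|nodes| + 1) matrix (dose column plus each node, log scale).
#' @export
forward_sample <- function(model, dose, M = 10000L, seed = 1L, epsilon = 0) {
  stopifnot(inherits(model, "gbn"))
  if (M < 1) stop_domain("M must be >= 1")
  if (epsilon < 0) stop_domain("epsilon must be >= 0")
  if (dose < model$dose_range[1] - epsilon ||
      dose > model$dose_range[2] + epsilon) {
    warning("dose ", dose, " outside fitted range [",
            paste(format(model$dose_range), collapse = ", "),
            "]: extrapolating", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- model$graph
  ord <- setdiff(g$order, g$root)
  x <- matrix(NA_real_, M, length(ord) + 1,
              dimnames = list(NULL, c(g$root, ord)))
  x[, g$root] <- if (epsilon > 0) runif(M, dose - epsilon, dose + epsilon) else dose
  for (v in ord) {
    f <- model$fits[[v]]
    mean_v <- drop(cbind(1, x[, f$parents, drop = FALSE]) %*% f$beta)
    x[, v] <- mean_v + rnorm(M, 0, sqrt(f$sigma2))
  }
  x
}

#' @export
simulate.gbn <- function(object, nsim = 1, seed = NULL, dose, epsilon = 0, ...) {
  forward_sample(object, dose = dose, M = nsim, seed = seed, epsilon = epsilon)
}

#' Threshold-exceedance probability P(node > Delta | dose)
#'
#' Monte-Carlo estimate: the fraction of forward samples at the queried
#' dose whose node value exceeds the log-scale activation threshold
#' `delta`, with the binomial standard error `sqrt(p (1 - p) / M)`.
#'
#' @param model a fitted `"gbn"`.
#' @param node node identifier.
#' @param delta activation threshold on the natural-log fold-change scale
#'   (use [threshold_to_log()] to convert FC / log2FC / log10FC).
#' @param dose queried dose (ug/mL).
#' @param epsilon dose-window half-width (see [forward_sample()]).
#' @param M number of forward samples.
#' @param seed integer seed.
#' @return list with `p`, `se`, `M`.
#' @export
event_probability <- function(model, node, delta, dose, epsilon = 0,
                              M = 10000L, seed = 1L) {
  if (M < 1) stop_domain("M must be >= 1")
  if (!node %in% names(model$fits)) stop_domain("unknown node '", node, "'")
  x <- forward_sample(model, dose, M = M, seed = seed, epsilon = epsilon)
  p <- mean(x[, node] > delta)
  list(p = p, se = sqrt(p * (1 - p) / M), M = M)
}

#' Convert an activation threshold to the natural-log scale
#'
#' Thresholds appear in three conventions — plain fold change (e.g. the
#' typical in vitro activation cut of FC = 2, i.e. 10^0.301), log2 fold
#' change and log10 fold change. All are converted explicitly; no scale is
#' ever implied.
#'
#' @param value threshold value (must be > 0 on the FC scale).
#' @param scale one of `"FC"`, `"log2FC"`, `"log10FC"`.
#' @return the threshold Delta in natural-log units.
#' @examples
#' threshold_to_log(2, "FC") / log(10)    # 0.301
#' threshold_to_log(1.5, "FC") / log(10)  # 0.176
#' @export
threshold_to_log <- function(value, scale = c("FC", "log2FC", "log10FC")) {
  scale <- match.arg(scale)
  switch(scale,
         FC = {
           if (any(value <= 0)) stop_domain("FC threshold must be > 0")
           log(value)
         },
         log2FC = value * log(2),
         log10FC = value * log(10))
}

#' Per-node goodness of fit of a GBN on a resampled slice
#'
#' Squared Pearson correlation between the model's predicted conditional
#' mean (given the observed parent values) and the observed node values.
#' Zero-variance nodes are reported as `NA`.
#'
#' @param model a fitted `"gbn"`.
#' @param resamples an `aop_resamples` object.
#' @param exposure exposure slice to evaluate on (default: the fitted one).
#' @return named numeric vector of R-squared values.
#' @export
goodness_of_fit <- function(model, resamples, exposure = model$exposure) {
  nodes <- attr(resamples, "nodes")
  sl <- resamples[resamples$exposure == exposure, , drop = FALSE]
  if (!nrow(sl)) stop_domain("no draws at exposure ", exposure)
  X <- cbind(as.matrix(sl[, nodes, drop = FALSE]), sl$dose)
  colnames(X)[ncol(X)] <- model$graph$root
  pred <- predict(model, X)
  sapply(names(model$fits), function(v) {
    obs <- X[, v]
    if (sd(obs) == 0 || sd(pred[, v]) == 0) return(NA_real_)
    cor(obs, pred[, v])^2
  })
}

#' Probability-versus-dose curve
#'
#' Evaluates [event_probability()] on a dose grid, yielding the
#' dose-probability relationship as a continuous curve for one node,
#' threshold and exposure.
#'
#' @inheritParams event_probability
#' @param dose_grid numeric vector of doses (ug/mL).
#' @param threshold_label optional label stored in the output (e.g. the FC
#'   value before log conversion); defaults to `exp(delta)`.
#' @return data.frame of class `"probability_table"` with columns
#'   `exposure`, `node`, `dose`, `threshold_fc`, `probability`, `se`.
#' @export
probability_curve <- function(model, node, delta, dose_grid, epsilon = 0,
                              M = 10000L, seed = 1L,
                              threshold_label = exp(delta)) {
  if (!length(dose_grid)) stop_domain("dose grid is empty")
  rows <- lapply(seq_along(dose_grid), function(i) {
    ep <- event_probability(model, node, delta, dose_grid[i],
                            epsilon = epsilon, M = M,
                            seed = substream_seed(seed, i))
    data.frame(exposure = model$exposure, node = node, dose = dose_grid[i],
               threshold_fc = threshold_label, probability = ep$p, se = ep$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("probability_table", "data.frame")
  out
}

#' @export
plot.probability_table <- function(x, ...) {
  keys <- interaction(x$exposure, x$node, x$threshold_fc, drop = TRUE)
  doses <- sort(unique(x$dose))
  mat <- sapply(levels(keys), function(k) {
    sub <- x[keys == k, ]
    sub$probability[match(doses, sub$dose)]
  })
  matplot(doses, mat, type = "b", pch = 16, lty = 1,
          xlab = "dose (ug/mL nicotine)", ylab = "P(node > threshold)",
          ylim = c(0, 1), ...)
  legend("bottomright", legend = levels(keys), col = seq_len(ncol(mat)),
         pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Serialize a fitted GBN to JSON
#'
#' @param model a fitted `"gbn"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gbn_json <- function(model, path) {
  obj <- list(
    exposure = model$exposure, nobs = model$nobs,
    nodes = lapply(model$fits, function(f) {
      list(parents = f$parents, beta = as.list(f$beta), sigma2 = f$sigma2,
           r2 = f$r2)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
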