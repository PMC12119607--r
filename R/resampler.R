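# Lognormal Bayesian resampling of a sparse fold-change dataset.
#
# Each (donor, exposure, dose) cell is summarized by its per-node mean fbar
# and SD s; moment matching maps these to a lognormal location
#   mu = ln( fbar^2 / sqrt(fbar^2 + s^2) )
# and squared scale
#   sigma2 = ln( 1 + s^2 / fbar^2 ),
# the off-diagonal covariance is built from a per-exposure response-response
# correlation matrix, and M multivariate-normal draws per cell expand the
# dataset in log space.

#' Lognormal location and squared scale from a cell mean and SD
#'
#' Moment-matching identities: if `X ~ lognormal(mu, sigma2)` then
#' `E[X] = fbar` and `SD[X] = s` exactly when
#' `mu = ln(fbar^2 / sqrt(fbar^2 + s^2))` and
#' `sigma2 = ln(1 + s^2 / fbar^2)`.
#'
#' @param fbar positive sample mean fold change (vectorized).
#' @param s nonnegative sample SD (vectorized).
#' @return `lognormal_location`: the location `mu`; `lognormal_scale2`: the
#'   squared scale `sigma2` (0 iff `s = 0`).
#' @export
lognormal_location <- function(fbar, s) {
  if (any(!is.finite(fbar)) || any(fbar <= 0)) stop_domain("fbar must be > 0")
  if (any(s < 0)) stop_domain("s must be >= 0")
  log(fbar^2 / sqrt(fbar^2 + s^2))
}

#' @rdname lognormal_location
#' @export
lognormal_scale2 <- function(fbar, s) {
  if (any(!is.finite(fbar)) || any(fbar <= 0)) stop_domain("fbar must be > 0")
  if (any(s < 0)) stop_domain("s must be >= 0")
  log1p(s^2 / fbar^2) # log1p keeps tiny s/fbar ratios from underflowing
}

#' Per-exposure response-response correlation matrix
#'
#' Pearson correlation of the per-cell mean log fold changes across all
#' (donor, dose) cells at one exposure repetition, pairwise over nodes.
#' Nodes that are constant across cells get zero off-diagonal entries with
#' a warning (their correlation is undefined).
#'
#' @param data an `invitro_data` data.frame.
#' @param exposure exposure repetition index.
#' @param nodes node order for the matrix (default: nodes present).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
estimate_correlations <- function(data, exposure, nodes = NULL) {
  sl <- data[data$exposure == exposure, , drop = FALSE]
  if (!nrow(sl)) stop_domain("no data at exposure ", exposure)
  nodes <- nodes %||% unique(sl$node)
  sl <- sl[sl$node %in% nodes, , drop = FALSE]
  cellkey <- interaction(sl$donor, sl$dose, drop = TRUE, lex.order = TRUE)
  cells <- levels(cellkey)
  if (length(cells) < 3) stop_domain("need >= 3 (donor, dose) cells at exposure ", exposure)
  m <- matrix(NA_real_, length(cells), length(nodes),
              dimnames = list(cells, nodes))
  agg <- aggregate(log(sl$fold_change),
                   by = list(cell = cellkey, node = sl$node), FUN = mean)
  m[cbind(match(agg$cell, cells), match(agg$node, nodes))] <- agg$x
  sds <- apply(m, 2, sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  rho <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (any(constant) || anyNA(rho)) {
    warning("constant node(s) at exposure ", exposure, ": ",
            paste(nodes[constant], collapse = ", "),
            "; off-diagonal correlations set to 0", call. = FALSE)
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  rho
}

#' Cell covariance matrix from lognormal scales and a correlation matrix
#'
#' Diagonal entries are the per-node `sigma2 = ln(1 + s^2/fbar^2)`;
#' off-diagonals are `rho_vv' * sqrt(sigma2_v * sigma2_v')`.
#'
#' @param fbar named vector of cell means (one per node, in `rho`'s order).
#' @param s matching vector of cell SDs.
#' @param rho correlation matrix (unit diagonal, symmetric).
#' @return symmetric covariance matrix.
#' @export
build_covariance <- function(fbar, s, rho) {
  if (length(fbar) != length(s) || length(fbar) != nrow(rho) ||
      nrow(rho) != ncol(rho)) {
    stop_domain("dimension mismatch between fbar, s and rho")
  }
  sigma2 <- lognormal_scale2(fbar, s)
  cov <- rho * sqrt(outer(sigma2, sigma2))
  diag(cov) <- sigma2
  dimnames(cov) <- dimnames(rho)
  (cov + t(cov)) / 2
}

#' Nearest-PSD repair by eigenvalue clipping
#'
#' A correlation matrix pooled per exposure combined with per-cell
#' variances can yield an indefinite covariance. `repair_psd` clips
#' negative eigenvalues at zero and rescales so the original diagonal is
#' restored exactly (a congruence transform, which preserves positive
#' semi-definiteness). Already-PSD input is returned unchanged.
#'
#' @param cov symmetric matrix.
#' @param tol eigenvalues above `-tol` count as nonnegative.
#' @return PSD matrix with the input's diagonal; attribute
#'   `"repair_distance"` carries the Frobenius distance to the input
#'   (0 when no repair was needed).
#' @export
repair_psd <- function(cov, tol = 1e-10) {
  if (!isTRUE(all.equal(cov, t(cov)))) stop_domain("cov must be symmetric")
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) >= -tol) {
    attr(cov, "repair_distance") <- 0
    return(cov)
  }
  lam <- pmax(ev$values, 0)
  rep_cov <- ev$vectors %*% (lam * t(ev$vectors))
  d_new <- diag(rep_cov)
  d_old <- diag(cov)
  scale <- ifelse(d_new > 0, sqrt(d_old / d_new), 0)
  out <- rep_cov * outer(scale, scale)
  diag(out) <- d_old
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(cov)
  attr(out, "repair_distance") <- sqrt(sum((out - cov)^2))
  out
}

# Eigendecomposition square root; tolerates PSD-singular matrices.
cov_sqrt <- function(cov, tol = 1e-8) {
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) < -tol * max(abs(ev$values), 1)) {
    stop_domain("covariance is not positive semi-definite; run repair_psd() first")
  }
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Multivariate-normal draws for one cell
#'
#' Draws `M` i.i.d. realizations from `MVN(mu, cov)` in log space,
#' deterministically given `seed`. A zero covariance returns `M` copies of
#' `mu` exactly. `z` supplies pre-drawn standard normals (M x |V|) when the
#' caller needs common random numbers across exposure slices.
#'
#' @param mu location vector.
#' @param cov PSD covariance matrix.
#' @param M number of draws.
#' @param seed integer seed (ignored when `z` is given).
#' @param z optional M x length(mu) matrix of standard normal variates.
#' @return M x length(mu) matrix, columns named after `mu`.
#' @export
draw_realizations <- function(mu, cov, M, seed = NULL, z = NULL) {
  if (M < 1) stop_domain("M must be >= 1")
  p <- length(mu)
  if (is.null(z)) {
    if (!is.null(seed)) set.seed(seed)
    z <- matrix(rnorm(M * p), M, p)
  }
  A <- cov_sqrt(cov)
  x <- sweep(z %*% A, 2, mu, `+`)
  colnames(x) <- names(mu) %||% rownames(cov)
  x
}

#' Bayesian resampling of an in vitro dataset
#'
#' Expands every (donor, exposure, dose) cell of the dataset into `M`
#' log-space multivariate-normal draws (default 1,000 per datapoint):
#' per-node locations and scales by lognormal moment matching, covariance
#' from the per-exposure response-response correlation, eigenvalue-clipping
#' PSD repair where needed. Draw `i` of a given (donor, dose) cell uses the
#' same underlying standard-normal block at every exposure, so draws align
#' across exposures as coherent trajectories — this is what the dynamic
#' transition model regresses on.
#'
#' @param data an `invitro_data` data.frame.
#' @param graph an [aop_graph]; its non-root nodes define the column order.
#' @param M draws per cell.
#' @param seed master seed; every cell derives an independent substream.
#' @param s_floor_frac passed to [summarize_cells()].
#' @return object of class `"aop_resamples"`: a data.frame with columns
#'   `donor`, `exposure`, `dose`, `draw` and one column per node (log fold
#'   change), with attributes `nodes`, `M`, `seed` and `repairs` (per-cell
#'   Frobenius repair distances > 0, if any).
#' @export
resample_dataset <- function(data, graph = default_aop(), M = 1000L,
                             seed = 1L, s_floor_frac = 0.1) {
  nodes <- setdiff(graph$order, graph$root)
  missing_nodes <- setdiff(nodes, unique(data$node))
  if (length(missing_nodes)) {
    stop_domain("dataset lacks node(s): ", paste(missing_nodes, collapse = ", "))
  }
  cells <- summarize_cells(data, s_floor_frac = s_floor_frac)
  exposures <- sort(unique(cells$exposure))
  donors <- sort(unique(cells$donor))
  doses <- sort(unique(cells$dose))

  rho_by_e <- lapply(exposures, function(e) estimate_correlations(data, e, nodes))
  names(rho_by_e) <- exposures

  blocks <- vector("list", length(donors) * length(doses) * length(exposures))
  repairs <- list()
  bi <- 1L
  for (ni in seq_along(donors)) for (di in seq_along(doses)) {
    # common standard-normal block per (donor, dose): aligns draws across e
    set.seed(substream_seed(seed, c(ni, di)))
    z <- matrix(rnorm(M * length(nodes)), M, length(nodes))
    for (e in exposures) {
      cc <- cells[cells$donor == donors[ni] & cells$dose == doses[di] &
                    cells$exposure == e, , drop = FALSE]
      cc <- cc[match(nodes, cc$node), , drop = FALSE]
      if (anyNA(cc$fbar)) {
        stop_domain("missing cell: donor ", donors[ni], ", dose ", doses[di],
                    ", exposure ", e)
      }
      mu <- setNames(lognormal_location(cc$fbar, cc$s), nodes)
      cov <- build_covariance(setNames(cc$fbar, nodes),
                              setNames(cc$s, nodes),
                              rho_by_e[[as.character(e)]])
      cov <- repair_psd(cov)
      rd <- attr(cov, "repair_distance")
      if (rd > 0) {
        repairs[[length(repairs) + 1L]] <-
          data.frame(donor = donors[ni], dose = doses[di], exposure = e,
                     frobenius = rd)
      }
      x <- draw_realizations(mu, cov, M, z = z)
      blocks[[bi]] <- data.frame(donor = donors[ni], exposure = e,
                                 dose = doses[di], draw = seq_len(M), x,
                                 check.names = FALSE)
      bi <- bi + 1L
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out,
            nodes = nodes, M = M, seed = seed,
            repairs = if (length(repairs)) do.call(rbind, repairs) else NULL,
            class = c("aop_resamples", "data.frame"))
}

#' @export
print.aop_resamples <- function(x, ...) {
  cat("Resampled AOP dataset: ", nrow(x), " draws (",
      attr(x, "M"), " per cell) over nodes ",
      paste(attr(x, "nodes"), collapse = ", "), "\n", sep = "")
  rep_log <- attr(x, "repairs")
  if (!is.null(rep_log)) {
    cat("  PSD repairs applied to", nrow(rep_log), "cell(s); max Frobenius",
        format(max(rep_log$frobenius), digits = 3), "\n")
  }
  invisible(x)
}

#' Write resampled draws to per-exposure CSVs with a JSON provenance sidecar
#'
#' @param resamples an `aop_resamples` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_resamples <- function(resamples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (e in sort(unique(resamples$exposure))) {
    p <- file.path(dir, sprintf("resamples_exposure%d.csv", e))
    write.csv(resamples[resamples$exposure == e,
                        setdiff(names(resamples), "exposure")],
              p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  rep_log <- attr(resamples, "repairs")
  side <- file.path(dir, "resamples_provenance.json")
  jsonlite::write_json(
    list(seed = attr(resamples, "seed"), M = attr(resamples, "M"),
         nodes = attr(resamples, "nodes"),
         psd_repairs = if (is.null(rep_log)) list() else rep_log),
    side, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, side))
}
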