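# Synthetic in vitro dataset generator.
#
# Emulates the statistical structure of a repeated whole-cigarette-smoke
# exposure study on donor-derived 3D bronchial epithelial cultures:
# 6 donors x 3 replicates, air control plus 3 WCS doses (nicotine
# 510 / 1,620 / 4,490 ug/mL), 6 exposure repetitions, early-peaking EGFR
# activation and late-rising mucin/GCM/H/hypersecretion dynamics,
# donor-to-donor variability in amplitude and in the exposure at which the
# maximum response occurs, and a responder/non-responder mixture that makes
# late-exposure distributions bimodal. Everything is generated on the log
# fold-change scale and exponentiated, matching the lognormal assumption of
# the resampler.

#' Configuration for the synthetic in vitro generator
#'
#' Returns the default generator configuration, optionally overridden.
#' The defaults encode the study conditions the package models: `N = 6`
#' donors, `R = 3` replicates, `E = 6` exposure repetitions and doses
#' `c(0, 510, 1620, 4490)` ug/mL nicotine (0 is the air control).
#'
#' Per measured node the configuration holds a Hill dose-response
#' (`emax` = maximal log fold change, `ec50` in ug/mL, `slope`), a temporal
#' profile (`peak` exposure index with Gaussian `rise`/`decay` widths, so
#' early nodes peak at exposure 1-2 and late nodes at 6), a per-exposure
#' control `drift` on the log scale (mucin endpoints creep upward even under
#' air), a replicate `noise_sd` (lognormal, natural-log scale) and a `late`
#' flag marking the nodes subject to the responder mixture.
#'
#' Donor heterogeneity: multiplicative response amplitudes
#' `exp(N(0, donor_amp_sd^2))`; an integer backward shift of the late-node
#' temporal peak (`|round(N(0, donor_shift_sd^2))|`, capped at `E - 2`) so
#' some donors peak at exposure 3-4 and others at 6; and a Bernoulli
#' (`responder_fraction`) responder flag — non-responders have their
#' late-node amplitude multiplied by `nonresponder_atten`, which produces
#' the two-component late-exposure mixture.
#'
#' @param ... named overrides of any top-level field, or per-node overrides
#'   via `nodes = list(AO = list(emax = ...), ...)` (merged into defaults).
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(...) {
  node_defaults <- list(
    ROS  = list(emax = log(4),  ec50 = 1500, slope = 1.2, peak = 1, rise = 1.0,
                decay = 3.5, drift = 0,    noise_sd = 0.25, late = FALSE),
    GSH  = list(emax = log(3),  ec50 = 1800, slope = 1.0, peak = 1, rise = 1.0,
                decay = 4.0, drift = 0,    noise_sd = 0.25, late = FALSE),
    AREG = list(emax = log(5),  ec50 = 1200, slope = 1.2, peak = 2, rise = 1.2,
                decay = 4.0, drift = 0,    noise_sd = 0.25, late = FALSE),
    KE1  = list(emax = log(4),  ec50 = 1200, slope = 1.2, peak = 1, rise = 1.0,
                decay = 3.5, drift = 0,    noise_sd = 0.25, late = FALSE),
    KE2  = list(emax = log(6),  ec50 = 1500, slope = 1.0, peak = 3, rise = 2.0,
                decay = 3.0, drift = 0,    noise_sd = 0.80, late = FALSE),
    KE3  = list(emax = log(6),  ec50 = 1400, slope = 1.3, peak = 5, rise = 1.8,
                decay = 3.0, drift = 0.04, noise_sd = 0.25, late = TRUE),
    KE4  = list(emax = log(15), ec50 = 1500, slope = 1.3, peak = 6, rise = 1.8,
                decay = 3.0, drift = 0.04, noise_sd = 0.25, late = TRUE),
    AO   = list(emax = log(15), ec50 = 1500, slope = 1.3, peak = 6, rise = 1.6,
                decay = 3.0, drift = 0.04, noise_sd = 0.25, late = TRUE)
  )
  cfg <- list(
    N = 6L, R = 3L, E = 6L,
    doses = c(0, 510, 1620, 4490),
    nodes = node_defaults,
    donor_amp_sd = 0.3,
    donor_shift_sd = 1.5,
    responder_fraction = 0.5,
    nonresponder_atten = 0.15,
    seed = 20260101L
  )
  dots <- list(...)
  if (length(dots)) {
    if (!is.null(dots$nodes)) {
      for (v in names(dots$nodes)) {
        if (is.null(cfg$nodes[[v]])) stop_domain("unknown node '", v, "' in config")
        cfg$nodes[[v]] <- modifyList(cfg$nodes[[v]], dots$nodes[[v]])
      }
      dots$nodes <- NULL
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop_domain("unknown generator config field(s): ",
                  paste(unknown, collapse = ", "))
    }
    cfg <- modifyList(cfg, dots)
  }
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    stopifnot(N >= 1, R >= 1, E >= 1)
    if (any(doses < 0)) stop_domain("doses must be nonnegative")
    if (is.unsorted(doses)) stop_domain("doses must be sorted increasing")
    if (donor_amp_sd < 0 || donor_shift_sd < 0) {
      stop_domain("donor random-effect SDs must be >= 0")
    }
    if (responder_fraction < 0 || responder_fraction > 1) {
      stop_domain("responder_fraction must lie in [0, 1]")
    }
  })
  for (v in names(cfg$nodes)) {
    p <- cfg$nodes[[v]]
    if (p$noise_sd < 0) stop_domain("noise_sd for ", v, " must be >= 0")
    if (p$ec50 <= 0 || p$slope <= 0) stop_domain("ec50/slope for ", v, " must be > 0")
  }
  invisible(cfg)
}

# Hill saturation term in [0, 1); 0 at dose 0 (air control).
hill_response <- function(d, ec50, slope) {
  ifelse(d <= 0, 0, d^slope / (ec50^slope + d^slope))
}

# Asymmetric Gaussian bump, 1 at the peak exposure.
temporal_profile <- function(e, peak, rise, decay) {
  w <- ifelse(e <= peak, rise, decay)
  exp(-0.5 * ((e - peak) / w)^2)
}

#' Simulate a repeated-exposure in vitro fold-change dataset
#'
#' Draws one synthetic dataset from the generative model described in
#' [generator_config()]. Per replicate the fold change is
#' `exp(m + eps)` with `eps ~ N(0, noise_sd^2)` and expected log fold change
#' `m = amp_n * resp_nv * emax_v * Hill_v(d) * temporal_v(e) +
#' drift_v * (e - 1)`; at the air control (`d = 0`) only the drift term
#' remains, so the expected log fold change at exposure 1 is exactly 0.
#' Generation is deterministic given `config$seed`, with an independent
#' substream per (donor, exposure, dose, node) cell so partial regeneration
#' is stable.
#'
#' @param config a [generator_config()].
#' @return a list with components
#'   \describe{
#'     \item{data}{long-format `data.frame` (class `"invitro_data"`) with
#'       columns `donor`, `exposure`, `dose`, `node`, `replicate`,
#'       `fold_change`;}
#'     \item{truth}{ground truth: `expected` (N x E x |D| x V array of
#'       expected log fold changes), `donor_amp`, `donor_shift`,
#'       `responder`.}
#'   }
#' @examples
#' sim <- simulate_invitro(generator_config(N = 2L, E = 2L))
#' head(sim$data)
#' @export
simulate_invitro <- function(config = generator_config()) {
  validate_generator_config(config)
  nodes <- names(config$nodes)
  N <- config$N; R <- config$R; E <- config$E; doses <- config$doses

  # donor-level random effects from a dedicated substream
  set.seed(substream_seed(config$seed, 1L))
  amp <- exp(rnorm(N, 0, config$donor_amp_sd))
  shift <- pmin(abs(round(rnorm(N, 0, config$donor_shift_sd))), max(config$E - 2L, 0L))
  responder <- runif(N) < config$responder_fraction

  expected <- array(
    NA_real_, dim = c(N, E, length(doses), length(nodes)),
    dimnames = list(donor = seq_len(N), exposure = seq_len(E),
                    dose = doses, node = nodes)
  )
  for (v in seq_along(nodes)) {
    p <- config$nodes[[v]]
    for (n in seq_len(N)) {
      resp <- if (p$late && !responder[n]) config$nonresponder_atten else 1
      peak_n <- if (p$late) max(1L, p$peak - shift[n]) else p$peak
      for (e in seq_len(E)) {
        tmp <- temporal_profile(e, peak_n, p$rise, p$decay)
        expected[n, e, , v] <-
          amp[n] * resp * p$emax * hill_response(doses, p$ec50, p$slope) * tmp +
          p$drift * (e - 1)
      }
    }
  }

  nD <- length(doses); nV <- length(nodes)
  fc <- numeric(N * E * nD * nV * R)
  i <- 1L
  for (n in seq_len(N)) for (e in seq_len(E)) for (di in seq_len(nD)) {
    for (v in seq_len(nV)) {
      set.seed(substream_seed(config$seed, c(2L, n, e, di, v)))
      eps <- rnorm(R, 0, config$nodes[[v]]$noise_sd)
      fc[i:(i + R - 1L)] <- exp(expected[n, e, di, v] + eps)
      i <- i + R
    }
  }
  # index vectors in the same nesting order as the fill loop
  # (donor slowest, then exposure, dose, node, replicate fastest)
  data <- data.frame(
    donor = rep(seq_len(N), each = E * nD * nV * R),
    exposure = rep(rep(seq_len(E), each = nD * nV * R), times = N),
    dose = rep(rep(doses, each = nV * R), times = N * E),
    node = rep(rep(nodes, each = R), times = N * E * nD),
    replicate = rep(seq_len(R), times = N * E * nD * nV),
    fold_change = fc,
    stringsAsFactors = FALSE
  )
  rownames(data) <- NULL
  class(data) <- c("invitro_data", "data.frame")
  truth <- list(expected = expected,
                donor_amp = setNames(amp, seq_len(N)),
                donor_shift = setNames(shift, seq_len(N)),
                responder = setNames(responder, seq_len(N)))
  list(data = data, truth = truth)
}

#' Per-cell summary of a fold-change dataset
#'
#' Collapses replicates to the per-(donor, exposure, dose, node) sample
#' mean and sample standard deviation (denominator `R - 1`) of the fold
#' change — the sufficient statistics the lognormal resampler consumes.
#' Cells with a single replicate have no variance estimate; their SD is
#' floored at `s_floor_frac * mean` (with a warning) so downstream
#' lognormal parameters stay defined.
#'
#' @param data an `invitro_data` data.frame (see [simulate_invitro()]).
#' @param s_floor_frac SD floor for single-replicate cells, as a fraction
#'   of the cell mean.
#' @return data.frame with columns `donor`, `exposure`, `dose`, `node`,
#'   `n_rep`, `fbar`, `s`.
#' @export
summarize_cells <- function(data, s_floor_frac = 0.1) {
  req <- c("donor", "exposure", "dose", "node", "fold_change")
  if (!all(req %in% names(data))) {
    stop_domain("dataset must have columns ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(data$fold_change)) || any(data$fold_change <= 0)) {
    stop_domain("fold_change values must be positive and finite")
  }
  key <- interaction(data$donor, data$exposure, data$dose, data$node,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(data)), key)
  out <- do.call(rbind, lapply(idx, function(ii) {
    fc <- data$fold_change[ii]
    data.frame(donor = data$donor[ii[1]], exposure = data$exposure[ii[1]],
               dose = data$dose[ii[1]], node = data$node[ii[1]],
               n_rep = length(fc), fbar = mean(fc),
               s = if (length(fc) > 1) sd(fc) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (anyNA(out$s)) {
    warning(sum(is.na(out$s)), " single-replicate cell(s): SD floored at ",
            s_floor_frac, " * mean", call. = FALSE)
    out$s[is.na(out$s)] <- s_floor_frac * out$fbar[is.na(out$s)]
  }
  out
}

#' Read / write the long-format in vitro CSV
#'
#' The on-disk format is a plain CSV with header
#' `donor,exposure,dose,node,replicate,fold_change`.
#'
#' @param data an `invitro_data` data.frame.
#' @param path CSV path.
#' @return `read_invitro` returns an `invitro_data` data.frame;
#'   `write_invitro` returns `path` invisibly.
#' @export
write_invitro <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_invitro
#' @export
read_invitro <- function(path) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("donor", "exposure", "dose", "node", "replicate", "fold_change")
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    stop_domain("CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(data$fold_change <= 0)) stop_domain("fold_change must be > 0")
  class(data) <- c("invitro_data", "data.frame")
  data
}
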