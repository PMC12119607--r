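# Odds ratios from model probabilities.
#
# The exposed arm is the exceedance probability of a node at a queried dose
# under the static GBN fitted at the late exposure; the control arm is the
# same model's probability at dose 0. Fold changes are first re-expressed
# relative to the exposure-1 air control (the "absolute" baseline), so any
# upward drift of the control arm over repeated exposures is retained —
# that drift is what gives the control arm nonzero odds.

#' Odds of an event
#'
#' @param p probability in `[0, 1)`.
#' @return `p / (1 - p)`.
#' @export
odds <- function(p) {
  if (any(p < 0 | p > 1)) stop_domain("p must lie in [0, 1]")
  if (any(p == 1)) stop_domain("p = 1 has infinite odds")
  p / (1 - p)
}

#' Odds ratio of two probabilities
#'
#' `odds(p_exposed) / odds(p_control)`. With `correction > 0` a continuity
#' correction is applied: both probabilities are shrunk as
#' `(p * m + correction) / (m + 2 * correction)` with pseudo-count total
#' `m = 1`, which keeps ORs finite when an arm sits at 0 or 1.
#'
#' @param p_exposed,p_control probabilities.
#' @param correction continuity-correction pseudo-count (default 0: off).
#' @return positive odds ratio; `Inf` (with a warning) when the control
#'   odds are 0 and no correction is applied.
#' @export
odds_ratio <- function(p_exposed, p_control, correction = 0) {
  if (correction > 0) {
    adj <- function(p) (p + correction) / (1 + 2 * correction)
    p_exposed <- adj(p_exposed)
    p_control <- adj(p_control)
  }
  if (any(p_control == 0)) {
    warning("control probability 0: infinite odds ratio", call. = FALSE)
  }
  odds(p_exposed) / odds(p_control)
}

#' Re-express fold changes relative to the exposure-1 air control
#'
#' Divides every fold change by the matching donor's and node's mean fold
#' change at exposure 1, dose 0. After this transform the dataset is on an
#' absolute scale in which control-condition drift across exposures (e.g.
#' gradually increasing mucin release under air) remains visible — the
#' prerequisite for a nonzero control-arm probability.
#'
#' @param data an `invitro_data` data.frame containing exposure 1 and
#'   dose 0 for every donor and node.
#' @return the re-baselined `invitro_data` data.frame.
#' @export
rebaseline_to_exposure1 <- function(data) {
  base <- data[data$exposure == 1 & data$dose == 0, , drop = FALSE]
  if (!nrow(base)) stop_domain("dataset has no exposure-1 dose-0 cells")
  key <- function(d) paste(d$donor, d$node, sep = "\r")
  bmean <- tapply(base$fold_change, key(base), mean)
  idx <- match(key(data), names(bmean))
  if (anyNA(idx)) {
    stop_domain("missing exposure-1 air-control baseline for some ",
                "(donor, node) pairs")
  }
  data$fold_change <- data$fold_change / as.numeric(bmean[idx])
  data
}

#' Dose-odds-ratio curve from a late-exposure static GBN
#'
#' Implements the in vitro odds-ratio construction: fold changes are
#' re-baselined to the exposure-1 air control, resampled, and a static GBN
#' is fitted at the late exposure (`exposure`, default 6, read as the time
#' point of disease manifestation; exposure 1 is the initiation of
#' smoking). For each grid dose, `p_exposed` is the exceedance probability
#' of `node` above `threshold` at that dose and `p_control` the same
#' model's probability at dose 0 — drift included — giving one OR per dose.
#' The default threshold, fold change 10, reflects MUC5AC being roughly
#' 10-fold higher in severe COPD than in non-smokers.
#'
#' @param data an `invitro_data` data.frame (raw fold changes; the
#'   re-baselining transform is applied internally).
#' @param graph the [aop_graph].
#' @param node node whose activation defines the event (default `"KE4"`,
#'   GCM/H — the histological hallmark of chronic bronchitis).
#' @param threshold_fc activation threshold on the fold-change scale.
#' @param dose_grid doses (ug/mL) for the exposed arm (default
#'   500-5,000).
#' @param exposure late exposure repetition to fit.
#' @param M resampler draws per cell.
#' @param samples forward samples per probability.
#' @param seed master seed.
#' @param correction continuity correction passed to [odds_ratio()].
#' @return data.frame of class `"or_result"` with columns `node`,
#'   `exposure`, `dose`, `p_exposed`, `p_control`, `odds_exposed`,
#'   `odds_control`, `or`, `degenerate` (flag for probability 0/1 arms).
#' @export
or_vs_dose <- function(data, graph = default_aop(), node = "KE4",
                       threshold_fc = 10, dose_grid = seq(500, 5000, by = 500),
                       exposure = 6, M = 1000L, samples = 20000L, seed = 1L,
                       correction = 0) {
  if (!length(dose_grid)) stop_domain("dose grid is empty")
  delta <- threshold_to_log(threshold_fc, "FC")
  reb <- rebaseline_to_exposure1(data)
  rs <- resample_dataset(reb, graph, M = M, seed = substream_seed(seed, 1L))
  fit <- fit_gbn(rs, graph, exposure = exposure)
  p_ctrl <- event_probability(fit, node, delta, dose = 0, M = samples,
                              seed = substream_seed(seed, 2L))$p
  rows <- lapply(seq_along(dose_grid), function(i) {
    p_exp <- event_probability(fit, node, delta, dose = dose_grid[i],
                               M = samples,
                               seed = substream_seed(seed, c(3L, i)))$p
    degenerate <- p_ctrl %in% c(0, 1) || p_exp %in% c(0, 1)
    or <- if (degenerate && correction == 0) {
      suppressWarnings(odds_ratio(min(p_exp, 1 - 1e-12),
                                  max(p_ctrl, 0)))
    } else {
      odds_ratio(p_exp, p_ctrl, correction = correction)
    }
    data.frame(node = node, exposure = exposure, dose = dose_grid[i],
               p_exposed = p_exp, p_control = p_ctrl,
               odds_exposed = if (p_exp < 1) odds(p_exp) else Inf,
               odds_control = if (p_ctrl < 1) odds(p_ctrl) else Inf,
               or = or, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold_fc") <- threshold_fc
  attr(out, "correction") <- correction
  class(out) <- c("or_result", "data.frame")
  out
}

#' @export
plot.or_result <- function(x, log = "y", ...) {
  plot(x$dose, x$or, type = "b", pch = 16, log = log,
       xlab = "dose (ug/mL nicotine)", ylab = "odds ratio", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}
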