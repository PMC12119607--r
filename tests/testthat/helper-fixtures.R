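# Shared fixtures, built in code. Objects created here are visible to
# every test file; keep them small so the default run stays fast.

# A 3-node chain AOP (dose -> A -> B) used by the closed-form oracles.
chain_graph <- function() {
  aop_graph(
    nodes = c("dose", "A", "B"),
    edges = rbind(c("dose", "A"), c("A", "B")),
    roles = c(dose = "dose", A = "KE", B = "AO")
  )
}

# Wrap a draws data.frame as an `aop_resamples` object so model fitting can
# be exercised on hand-built data with known parameters.
make_resamples <- function(df, nodes, M = max(df$draw)) {
  structure(df, nodes = nodes, M = M, seed = NA_integer_,
            repairs = NULL, class = c("aop_resamples", "data.frame"))
}

# Draws from a known linear-Gaussian chain: A ~ N(a0 + a1 d, s2a),
# B ~ N(b0 + b1 A, s2b), pooled over the given doses.
chain_draws <- function(doses, M, a0, a1, s2a, b0, b1, s2b, seed = 1) {
  set.seed(seed)
  rows <- lapply(doses, function(d) {
    A <- a0 + a1 * d + rnorm(M, 0, sqrt(s2a))
    B <- b0 + b1 * A + rnorm(M, 0, sqrt(s2b))
    data.frame(donor = 1L, exposure = 1L, dose = d, draw = seq_len(M),
               A = A, B = B)
  })
  make_resamples(do.call(rbind, rows), nodes = c("A", "B"))
}

# Closed-form marginal of B at an interventional dose for chain_draws().
chain_b_marginal <- function(d, a0, a1, s2a, b0, b1, s2b) {
  list(mean = b0 + b1 * (a0 + a1 * d), var = b1^2 * s2a + s2b)
}

# One small shaped dataset + resamples reused across files (cheap: N = 3,
# E = 3, M = 80).
small_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_invitro(generator_config(N = 3L, E = 3L, seed = 4242L))
    }
    val
  }
})

small_resamples <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- resample_dataset(small_sim()$data, default_aop(), M = 80L,
                               seed = 99L)
    }
    val
  }
})

# Build a minimal "dbn" object by hand so inference can be tested against
# known transition parameters without a fitting step.
make_manual_dbn <- function(beta, sigma2, marg_mean, marg_sd, dose = 100,
                            evidence = "KE4", target = "AO", exposure = 2L) {
  g <- aop_graph(c("dose", evidence, target),
                 rbind(c("dose", evidence), c(evidence, target)),
                 roles = setNames(c("dose", "KE", "AO"),
                                  c("dose", evidence, target)))
  tr <- list()
  tr[[target]] <- list(parents = paste0(evidence, "_prev"), beta = beta,
                       sigma2 = sigma2, lambda = 1)
  mm <- data.frame(exposure = exposure - 1L, dose = dose)
  mm[[evidence]] <- marg_mean
  mm[[target]] <- marg_mean
  ms <- data.frame(exposure = exposure - 1L, dose = dose)
  ms[[evidence]] <- marg_sd
  ms[[target]] <- marg_sd
  structure(list(graph = g, transitions = setNames(list(tr), exposure),
                 marginal_mean = mm, marginal_sd = ms,
                 exposures = c(exposure - 1L, exposure),
                 include_dose = FALSE, lambda_grid = 1,
                 nodes = c(evidence, target)),
            class = "dbn")
}
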