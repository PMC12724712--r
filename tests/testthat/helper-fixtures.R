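# Shared fixtures. Heavy MCMC fits used by several acceptance blocks are
# computed once per test run and cached in this environment.

.fit_cache <- new.env(parent = emptyenv())

# sampler settings used throughout the suite (fewer chains than the
# analysis defaults but enough iterations for the slow-mixing
# baseline/time-constant ridge; problem sizes documented in the methods
# vignette)
TEST_SAMPLER <- list(chains = 2, draws = 1500, warmup = 1500, adapt = 1000)

evoked_on_data <- function(seed = 101) {
  key <- paste0("on_data_", seed)
  if (!exists(key, .fit_cache)) {
    set.seed(seed)
    assign(key, simulateEvokedCounts("on_double_exp", cohortConfig()$on),
           .fit_cache)
  }
  get(key, .fit_cache)
}

evoked_off_data <- function(seed = 102) {
  key <- paste0("off_data_", seed)
  if (!exists(key, .fit_cache)) {
    set.seed(seed)
    assign(key, simulateEvokedCounts("off_linear_exp", cohortConfig()$off),
           .fit_cache)
  }
  get(key, .fit_cache)
}

cached_fit <- function(tag, counts, variant, seed = 7,
                       sampler = TEST_SAMPLER) {
  if (!exists(tag, .fit_cache)) {
    fit <- fitPiecewise(counts, variant, chains = sampler$chains,
      draws = sampler$draws, warmup = sampler$warmup,
      adapt = sampler$adapt, seed = seed)
    assign(tag, fit, .fit_cache)
  }
  get(tag, .fit_cache)
}

# a PiecewiseFit whose "posterior" is a single known parameter point,
# for closed-form checks of threshold-crossing machinery
point_mass_fit <- function(variant, params, n = 120) {
  cols <- switch(variant,
    on_single_exp = c(r_pre = params$rPre, r_post = params$rPost,
      k_pre = params$kPre, tau1 = params$tau1, tau3 = params$tau3,
      ts = params$ts),
    on_double_exp = c(r_pre = params$rPre, r_post = params$rPost,
      k_pre = params$kPre, k_fast = params$kFast, tau1 = params$tau1,
      tau2 = params$tau2, tau3 = params$tau3, ts = params$ts),
    off_linear_exp = c(a = params$a, b = params$b, c = params$c,
      k = params$k, u0 = params$u0, tau = params$tau, k3 = params$k3,
      ts = params$ts))
  dm <- matrix(rep(cols, each = n), nrow = n,
               dimnames = list(NULL, names(cols)))
  tc <- seq(-10 + 0.025, 100 - 0.025, by = 0.05)
  new("PiecewiseFit", variant = variant, draws = dm, binCenters = tc,
      counts = integer(length(tc)), nChains = 1L, seed = 1L,
      diagnostics = list(), converged = TRUE)
}
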