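# Independent oracles and shared fixtures for the test suite.

# O(n^2) brute-force horizontal visibility graph: edge (i, j) iff every
# sample strictly between is below min(x_i, x_j). Uses running maxima, so it
# shares no code with the stack-based implementation under test.
hvg_oracle <- function(x, fs = 1) {
  n <- length(x)
  deg <- integer(n)
  wdeg <- numeric(n)
  for (i in seq_len(n - 1)) {
    if (i + 1 <= n) {
      # adjacent samples always see each other
      w <- abs(atan((x[i + 1] - x[i]) * fs))
      deg[i] <- deg[i] + 1L; deg[i + 1] <- deg[i + 1] + 1L
      wdeg[i] <- wdeg[i] + w; wdeg[i + 1] <- wdeg[i + 1] + w
    }
    if (i + 2 > n) next
    between_max <- cummax(x[(i + 1):(n - 1)])
    for (j in (i + 2):n) {
      if (between_max[j - i - 1] < min(x[i], x[j])) {
        w <- abs(atan((x[j] - x[i]) * fs / (j - i)))
        deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
        wdeg[i] <- wdeg[i] + w; wdeg[j] <- wdeg[j] + w
      }
    }
  }
  list(degree = deg, wdegree = wdeg)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_oracle <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# brute-force Pareto front by pairwise dominance
pareto_oracle <- function(pts) {
  n <- nrow(pts)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(pts[j, ] <= pts[i, ]) && any(pts[j, ] < pts[i, ])
    }, TRUE))
  }, TRUE)
  which(keep)
}

# shared cache so expensive fixtures are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one small fitted synthetic subject, reused across GA-dependent tests
small_subject_fit <- function() {
  cached("small_subject_fit", function() {
    g <- generate_subject(param_template("control"), jitter_frac = 0.02,
                          noise_sd = 0.2, n_epochs = 2, seed = 11,
                          subject_id = "cache01")
    seg <- bandpass(average_channels(g$segment, c("F3", "F4")))
    target <- feature_set(make_epochs(seg))
    cfg <- fit_config(pop_size = 16, generations = 10, n_repeats = 2,
                      base_seed = 21, dt_internal = 5e-4)
    list(truth = g$truth, target = target, config = cfg,
         fits = fit_subject(target, cfg))
  })
}
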