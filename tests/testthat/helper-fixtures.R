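# Shared fixture builders. Everything is generated in code from fixed seeds.

random_scan <- function(seed, n_timepoints = 120, n_regions = 12,
                        mean_fd = 0.2, tr = 2) {
  withr::with_seed(seed, {
    regional_timeseries(
      matrix(rnorm(n_timepoints * n_regions), n_timepoints, n_regions),
      tr_seconds = tr, mean_fd = mean_fd,
      scan_id = paste0("scan", seed))
  })
}

# reference scans rendered from a known basis through the oscillator model
rendered_reference <- function(seed, n_scans = 4, n_timepoints = 300,
                               n_regions = 20, K = 4, noise_sd = 0) {
  basis <- generate_gradient_basis(n_regions, K, seed = seed)
  model <- build_coupling_matrix(seq(0.15, 0.3, length.out = K),
                                 rep(0.04, K), tr_seconds = 2)
  scans <- lapply(seq_len(n_scans), function(i) {
    g <- simulate_gradient_timeseries(model, n_timepoints,
                                      forcing_sd = 0.05 * seq_len(K)^-0.5,
                                      seed = seed + i)
    render_bold(g, basis, region_noise_sd = noise_sd, seed = seed + 100 + i)
  })
  list(basis = basis, scans = scans, model = model)
}

# linear structure-function cohort with 3 planted components
planted_plsr_cohort <- function(seed, n = 120, n_regions = 30,
                                n_edges = 200, snr = 2,
                                effect = c(3, 2, 1)) {
  withr::with_seed(seed, {
    patterns <- qr.Q(qr(matrix(rnorm(n_regions * 3), n_regions, 3)))
    edge_load <- qr.Q(qr(matrix(rnorm(n_edges * 3), n_edges, 3)))
    s <- matrix(rnorm(n * 3), n, 3)
    X <- s %*% diag(effect) %*% t(patterns) +
      matrix(rnorm(n * n_regions, 0, mean(effect) / snr / sqrt(n_regions)),
             n, n_regions)
    Y <- s %*% diag(effect) %*% t(edge_load) +
      matrix(rnorm(n * n_edges, 0, mean(effect) / snr / sqrt(n_edges)),
             n, n_edges)
    list(X = X, Y = Y, scores = s, patterns = patterns,
         edge_loadings = edge_load)
  })
}

# the 15 gradient-pair names for K = 6, in row-major order
pair_names_t <- function() {
  out <- c()
  for (i in 1:5) for (j in (i + 1):6) out <- c(out, paste0("g", i, "-g", j))
  out
}
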