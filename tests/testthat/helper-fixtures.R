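# Shared builders for small test problems. Everything is generated in code;
# sizes are kept tiny so unit tests run in seconds.

# symmetric random connectome with zero diagonal, max-normalized
tiny_connectome <- function(n, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(runif(n * n, 0, 0.5), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    connectome(w)
  })
}

# small self-consistent observation: latent trajectory from a known theta,
# projected through a random gain, with Gaussian feature noise
tiny_problem <- function(n = 4, Tn = 25, m = 3, seed = 1, noise_sd = 0.1) {
  conn <- tiny_connectome(n, seed)
  withr::with_seed(seed + 100, {
    G <- matrix(runif(m * n, 0.1, 1), m, n)
    priors <- vep_priors(1, n)
    theta <- unpack_theta(priors$mean + rnorm(3 * n + 6, 0, 0.05), n)
    Y <- predict_latent_states(theta, conn, T = Tn)
    mu <- theta$alpha * log(t(G %*% exp(Y$X))) + theta$beta
    S <- mu + matrix(rnorm(Tn * m, 0, noise_sd), Tn, m)
    list(conn = conn, gain = G, priors = priors, theta = theta,
         obs = vep_observation(S, G, row_normalize = FALSE,
                               center_channels = FALSE))
  })
}

# the bundled reference scenario at reduced size; simulation takes ~1 s
reduced_dataset <- function(n = 12, seed = 1) {
  net <- synthetic_network(n, ez = c(1, 2), pz = 3:6, n_sensors = 12,
                           seed = seed)
  ds <- simulate_seizure_dataset(seizure_scenario(ez = c(1, 2), pz = 3:6),
                                 net, seed = seed)
  list(net = net, ds = ds)
}
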