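test_that("gain coefficients follow the inverse-square vertex sum", {
  sensors <- data.frame(label = "s1", x = 0, y = 0, z = 0)
  # one vertex at distance 2, area 1: G = 1/4
  surf1 <- data.frame(region = 1, x = 2, y = 0, z = 0, area = 1)
  expect_equal(compute_gain(surf1, sensors, c = 1, dist_floor = 0)[1, 1],
               0.25, ignore_attr = TRUE)
  # vertices at distances 1 and 2: G = 1 + 1/4
  surf2 <- data.frame(region = 1, x = c(1, 2), y = 0, z = 0, area = 1)
  expect_equal(compute_gain(surf2, sensors, c = 1, dist_floor = 0)[1, 1],
               1.25, ignore_attr = TRUE)
  # linear in the scaling coefficient
  expect_equal(compute_gain(surf2, sensors, c = 2, dist_floor = 0),
               2 * compute_gain(surf2, sensors, c = 1, dist_floor = 0),
               ignore_attr = TRUE)
  # coincident sensor and vertex without a clamp is an error
  surf0 <- data.frame(region = 1, x = 0, y = 0, z = 0, area = 1)
  expect_error(compute_gain(surf0, sensors, dist_floor = 0), "coincides")
  # clamp keeps it finite
  expect_true(is.finite(compute_gain(surf0, sensors, dist_floor = 1)[1, 1]))
})

test_that("gain decays monotonically with distance for point regions", {
  sensors <- data.frame(label = c("near", "far"), x = c(1, 5), y = 0, z = 0)
  surf <- data.frame(region = 1, x = 0, y = 0, z = 0, area = 1)
  G <- compute_gain(surf, sensors, dist_floor = 0.5)
  expect_gt(G["near", 1], G["far", 1])
  expect_true(all(G >= 0))
})

test_that("sensor projection is the linear gain map", {
  phi <- matrix(rnorm(12), 4, 3)
  expect_equal(project_to_sensors(phi, diag(4)), phi)
  G <- matrix(runif(8), 2, 4)
  expect_equal(project_to_sensors(matrix(5, 4, 3), G),
               matrix(5 * rowSums(G), 2, 3))
  expect_equal(project_to_sensors(matrix(c(1, 3), 2, 1),
                                  matrix(c(1, 2), 1, 2)),
               matrix(7, 1, 1))
  # linearity
  a <- matrix(rnorm(8), 4, 2); b <- matrix(rnorm(8), 4, 2)
  expect_equal(project_to_sensors(2 * a + 3 * b, G),
               2 * project_to_sensors(a, G) + 3 * project_to_sensors(b, G))
  expect_error(project_to_sensors(matrix(0, 3, 2), G), "match")
})

test_that("synthetic network generator is seeded and structured", {
  n1 <- synthetic_network(10, ez = c(1, 2), pz = 3:5, seed = 7)
  n2 <- synthetic_network(10, ez = c(1, 2), pz = 3:5, seed = 7)
  expect_identical(n1, n2)
  w <- n1$connectome$weights
  expect_equal(max(w), 1)
  expect_true(all(diag(w) == 0))
  # every PZ region is coupled to an EZ region above the median weight
  med <- median(w[upper.tri(w)])
  for (j in 3:5) expect_gt(max(w[j, 1:2]), med)
  expect_error(synthetic_network(10, ez = c(1, 2), pz = c(2, 3), seed = 1))
})

test_that("scenario validation enforces the excitability ordering", {
  expect_error(seizure_scenario(ez = 1, pz = 1))
  expect_error(seizure_scenario(ez = 1, pz = 2, x0_ez = -2.5, x0_pz = -1.8))
  sc <- seizure_scenario(ez = c(2, 1), pz = c(6, 3))
  expect_equal(sc$ez, c(1, 2))
  expect_equal(sc$x0_ez, -1.8)
  expect_equal(sc$x0_pz, -2.3)
  expect_equal(sc$x0_background, -3.0)
})

test_that("the reference scenario recruits the EZ before the PZ", {
  fx <- reduced_dataset(seed = 1)
  ds <- fx$ds
  expect_setequal(ds$truth$recruited, 1:6)
  expect_lt(max(ds$truth$onsets[1:2]), min(ds$truth$onsets[3:6]))
  expect_true(all(is.na(ds$truth$onsets[7:12])))
  # same seed reproduces the dataset exactly
  ds2 <- simulate_seizure_dataset(seizure_scenario(ez = c(1, 2), pz = 3:6),
                                  fx$net, seed = 1)
  expect_identical(ds$seeg, ds2$seeg)
})

test_that("an all-background network recruits nothing", {
  net <- synthetic_network(6, ez = 1, pz = 2, n_sensors = 4, seed = 3)
  # every region at (essentially) background excitability
  sc <- seizure_scenario(ez = 1, pz = 2, x0_ez = -2.999, x0_pz = -2.9995)
  ds <- simulate_seizure_dataset(sc, net, seed = 3)
  expect_length(ds$truth$recruited, 0)
})

test_that("observation noise hits the target channel-averaged SNR", {
  withr::with_seed(42, {
    clean <- matrix(rnorm(8 * 20000, sd = rep(c(1, 2), each = 4)), 8, 20000)
  })
  noisy <- add_observation_noise(clean, target_snr = 2, seed = 9)
  v_n <- apply(noisy - clean, 1, var)
  snr_hat <- mean(apply(clean, 1, var) / v_n)
  expect_equal(snr_hat, 2, tolerance = 0.05)
  # disabled noise returns the input; same seed reproduces the realization
  expect_identical(add_observation_noise(clean, Inf), clean)
  expect_identical(add_observation_noise(clean, 1, seed = 5),
                   add_observation_noise(clean, 1, seed = 5))
  expect_false(identical(add_observation_noise(clean, 1, seed = 5),
                         add_observation_noise(clean, 1, seed = 6)))
  expect_error(add_observation_noise(matrix(0, 2, 10), 1), "zero variance")
})

test_that("connectome construction normalizes and validates", {
  w <- matrix(c(0, 2, 4, 0), 2, 2)
  cn <- connectome(w)
  expect_equal(max(cn$weights), 1)
  expect_equal(unname(cn$weights[2, 1]), 0.5)
  expect_equal(unname(cn$weights[1, 2]), 1)
  expect_error(connectome(matrix(c(0, -1, 1, 0), 2, 2)), "nonnegative")
})
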