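test_that("generate_stand honours counts, seeds and layer ordering", {
  cfg <- stand_config(n_layers = 1, trees_per_layer = 5L, seed = 7)
  st <- generate_stand(cfg)
  expect_equal(nrow(st$trees), 5L)
  expect_true(all(st$trees$layer == 1L))

  st2 <- generate_stand(cfg)
  expect_identical(st$trees, st2$trees)            # same seed, same stand
  st3 <- generate_stand(stand_config(n_layers = 1, trees_per_layer = 5L,
                                     seed = 8))
  expect_false(identical(st$trees$x, st3$trees$x)) # different seed differs

  two <- generate_stand(stand_config(n_layers = 2, seed = 1))
  expect_lt(max(two$trees[layer == 2, height]),
            min(two$trees[layer == 1, height]))

  expect_error(stand_config(n_layers = 2,
                            layer_height_ranges = list(c(10, 20), c(15, 25))),
               "decreasing")
})

test_that("simulate_scan bookkeeping: returns per pulse, classes, truth", {
  st <- generate_stand(stand_config(plot_radius = 8, n_layers = 2, seed = 2))
  cl <- simulate_scan(st, scan_config(pulse_density = 4, seed = 3))
  dt <- as.data.table(cl)
  per_pulse <- dt[, .(n = .N, nr = number_of_returns[1],
                      ok = all(sort(return_number) == seq_len(.N))),
                  by = pulse_id]
  expect_true(all(per_pulse$ok))
  expect_true(all(per_pulse$n == per_pulse$nr))
  expect_true(all(per_pulse$n <= 4L))
  veg <- dt[point_class == "vegetation"]
  expect_true(all(veg$truth_tree_id %in% st$trees$tree_id))
  expect_true(all(is.na(dt[point_class == "ground", truth_tree_id])))

  # zero trees: every pulse yields exactly one ground return
  empty <- generate_stand(stand_config(plot_radius = 8, n_layers = 1,
                                       trees_per_layer = 1L, seed = 1))
  empty$trees <- empty$trees[0]
  cl0 <- simulate_scan(empty, scan_config(pulse_density = 2, seed = 1))
  expect_true(all(cl0$point_class == "ground"))
  expect_true(all(cl0$number_of_returns == 1L))
  expect_equal(nrow(cl0), nrow(attr(cl0, "pulses")))
})

test_that("opaque canopy blocks everything below except gaps", {
  st <- generate_stand(stand_config(plot_radius = 8, n_layers = 2, seed = 5))
  cl <- simulate_scan(st, scan_config(pulse_density = 6,
                                      interception_return_prob = 1,
                                      transmission_prob = 0, noise_sd = 0,
                                      seed = 6))
  dt <- as.data.table(cl)
  # a pulse that hit layer 1 can yield no deeper return at all
  l1_pulses <- dt[truth_layer == 1L, unique(pulse_id)]
  deeper <- dt[pulse_id %in% l1_pulses & (point_class == "ground" |
                                            truth_layer > 1L)]
  expect_equal(nrow(deeper), 0L)
})

test_that("realized layer ratio matches per-pulse probability enumeration", {
  st <- generate_stand(stand_config(plot_radius = 11, n_layers = 3,
                                    seed = 11))
  scan <- scan_config(pulse_density = 100, interception_return_prob = 0.9,
                      transmission_prob = 0.25, noise_sd = 0, seed = 12)
  cl <- simulate_scan(st, scan)
  pulses <- attr(cl, "pulses")
  expect_gte(nrow(pulses), 1e5)
  realized <- as.data.table(cl)[point_class == "vegetation",
                                .N, by = truth_layer][order(truth_layer)]
  expected <- enumerate_layer_expectation(st, pulses, q = 0.9, t = 0.25,
                                          max_returns = 4L)
  r_obs <- realized$N[2] / realized$N[1]
  r_exp <- expected[2] / expected[1]
  expect_lt(abs(r_obs - r_exp) / r_exp, 0.20)
  # absolute counts agree too (tighter law-of-large-numbers check)
  expect_lt(abs(realized$N[1] - expected[1]) / expected[1], 0.05)
  expect_lt(abs(realized$N[2] - expected[2]) / expected[2], 0.10)
})

test_that("occlusion produces non-increasing layer densities (statistical)", {
  counts <- sapply(1:5, function(s) {
    st <- generate_stand(stand_config(plot_radius = 8, n_layers = 3,
                                      seed = s))
    cl <- simulate_scan(st, scan_config(pulse_density = 8, seed = s + 100))
    dt <- as.data.table(cl)[point_class == "vegetation" & !in_buffer]
    sapply(1:3, function(k) sum(dt$truth_layer == k))
  })
  avg <- rowMeans(counts)
  expect_true(all(diff(avg) < 0))
})

test_that("generate_plot_sample is reproducible and spans the layer mix", {
  scan <- scan_config(pulse_density = 3, seed = 1)
  p1 <- generate_plot_sample(4, scan, layer_mix = c(1L, 2L, 3L, 4L),
                             plot_radius = 6, seed = 42)
  p2 <- generate_plot_sample(4, scan, layer_mix = c(1L, 2L, 3L, 4L),
                             plot_radius = 6, seed = 42)
  expect_equal(as.data.frame(p1[[2]]$cloud), as.data.frame(p2[[2]]$cloud))
  nlayers <- vapply(p1, function(p) max(p$stem_map$layer), integer(1))
  expect_identical(sort(unique(nlayers)), 1:4)

  # accounting identity: total points == sum of per-pulse return counts,
  # and realized pulse count tracks pulse_density * scanned area
  cl <- p1[[3]]$cloud
  dt <- as.data.table(cl)
  expect_identical(nrow(dt),
                   sum(dt[, .(nr = number_of_returns[1]), by = pulse_id]$nr))
  half <- 6 + 5
  expect_lt(abs(nrow(attr(cl, "pulses")) / ((2 * half)^2 * 3) - 1), 0.1)
})
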