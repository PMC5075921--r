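test_that("the Hill transfer has midpoint h, range [0,1) and is increasing", {
  for (h in default_hill_grid()) {
    hp <- hill_params(2, h)
    expect_equal(hill_transfer(h, hp), 0.5)
    expect_equal(hill_transfer(0, hp), 0)
    x <- seq(0, 1, by = 0.05)
    fx <- hill_transfer(x, hp)
    expect_true(all(fx >= 0 & fx < 1))
    expect_true(all(diff(fx) > 0))
  }
  expect_equal(hill_transfer(0.8, hill_params(2, 0.4)), 0.64 / 0.8)
  expect_error(hill_transfer(1.2), "\\[0, 1\\]")
  expect_error(hill_params(2, 1.5), "\\(0, 1\\)")
  expect_error(hill_params(0, 0.5), "positive")
})

test_that("node_update reproduces AND/OR truth tables in boolean mode", {
  nodes <- c("i", "k", "j")
  B <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  B[c("i", "k"), "j"] <- 1L
  # AND gate: both regulators in clause 1
  and_m <- logic_model(nodes, B)
  # OR gate: separate clauses
  C <- matrix(1L, 3, 3, dimnames = list(nodes, nodes))
  C["k", "j"] <- 2L
  or_m <- logic_model(nodes, B, C = C)
  expect_equal(node_update(c(1, 0, 0), "j", and_m, mode = "boolean"), 0)
  expect_equal(node_update(c(1, 1, 0), "j", and_m, mode = "boolean"), 1)
  expect_equal(node_update(c(1, 0, 0), "j", or_m, mode = "boolean"), 1)
  expect_equal(node_update(c(0, 0, 0), "j", or_m, mode = "boolean"), 0)
  # fuzzy AND of an activator at 0.5 (h = 0.5) and an inhibitor at 0
  R <- matrix(1L, 3, 3, dimnames = list(nodes, nodes))
  R["k", "j"] <- 0L
  mix_m <- logic_model(nodes, B, R = R)
  expect_equal(node_update(c(0.5, 0, 0), "j", mix_m), 0.5)
  expect_error(node_update(c(0, 0, 0), "i", and_m), "no regulators")
})

test_that("gate enumeration yields the Bell-number set partitions", {
  expect_length(enumerate_gate_encodings(0), 0)
  expect_length(enumerate_gate_encodings(1), 1)
  expect_length(enumerate_gate_encodings(2), 2)
  expect_length(enumerate_gate_encodings(3), 5)
  expect_length(enumerate_gate_encodings(4), 15)
  # canonical restricted-growth form, no duplicates
  encs <- enumerate_gate_encodings(3)
  keys <- vapply(encs, paste, character(1), collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  for (e in encs) {
    expect_equal(e[1], 1L)
    expect_true(all(e <= cummax(c(1L, head(e, -1))) + 1L))
  }
})

test_that("boolean-mode gates match a logical DNF evaluator for indegree <= 3", {
  for (k in 1:3) {
    nodes <- c(paste0("p", seq_len(k)), "t")
    B <- matrix(0L, k + 1, k + 1, dimnames = list(nodes, nodes))
    B[seq_len(k), "t"] <- 1L
    sign_grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))
    input_grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))
    for (labels in enumerate_gate_encodings(k)) {
      C <- matrix(1L, k + 1, k + 1, dimnames = list(nodes, nodes))
      C[seq_len(k), "t"] <- labels
      for (srow in seq_len(nrow(sign_grid))) {
        R <- matrix(1L, k + 1, k + 1, dimnames = list(nodes, nodes))
        R[seq_len(k), "t"] <- sign_grid[srow, ]
        model <- logic_model(nodes, B, R = R, C = C)
        got <- apply(input_grid, 1, function(x)
          node_update(c(x, 0), "t", model, mode = "boolean"))
        want <- apply(input_grid, 1, function(x)
          dnf_oracle(x, sign_grid[srow, ], labels))
        expect_equal(unname(got), unname(want))
      }
    }
  }
})

test_that("steady-state simulation converges on chains and honors clamps", {
  model <- chain3_model(h = 0.5)
  res <- simulate_steady_state(model, inputs = c(s = 1),
                               config = simulation_config(mode = "boolean"))
  expect_true(res$converged)
  expect_equal(unname(res$state), c(1, 1, 1))
  # fuzzy: a = f(1) = 1/(1 + 0.25) = 0.8, b = f(0.8) = 0.64/0.89
  res_f <- simulate_steady_state(model, inputs = c(s = 1))
  expect_true(res_f$converged)
  expect_equal(unname(res_f$state["a"]), 0.8)
  expect_equal(unname(res_f$state["b"]), 0.64 / (0.64 + 0.25))
  expect_error(simulate_steady_state(model), "stimulated")
})

test_that("oscillating boolean dynamics are reported as non-converged at 5m", {
  model <- oscillator2_model()
  cfg <- simulation_config(mode = "boolean")
  res <- simulate_steady_state(model, config = cfg)
  expect_false(res$converged)
  expect_equal(res$iterations, 5L * model$m)
  # the same feedback loop under fuzzy dynamics still yields states in [0,1]
  res_f <- simulate_steady_state(model)
  expect_true(all(res_f$state >= 0 & res_f$state <= 1))
})

test_that("time-series simulation matches the reference R update loop", {
  set.seed(7)
  for (rep in 1:5) {
    spec <- truth_network_spec(6, 8, n_feedback_loops = 1, n_and_gates = 1,
                               inhibition_fraction = 0.3, seed = rep)
    model <- make_truth_network(spec)
    init <- setNames(round(runif(model$m), 3), model$nodes)
    for (mode in c("boolean", "fuzzy")) {
      got <- simulate_timeseries(model, init, n_points = 8,
                                 config = simulation_config(mode = mode))
      want <- r_simulate(model, init, 8, mode = mode)
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(all(got >= 0 & got <= 1))
    }
  }
})

test_that("time-series simulation respects clamps, length and trivial cases", {
  model <- chain3_model()
  init <- c(s = 0, a = 0.2, b = 0.9)
  one <- simulate_timeseries(model, init, n_points = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one[1, ], init)
  ts <- simulate_timeseries(model, init, inputs = c(s = 0.6), n_points = 12)
  expect_equal(nrow(ts), 12)
  expect_true(all(ts[, "s"] == 0.6))
  # acyclic model reaches a fixed point within m steps; the steady-state
  # simulator agrees with the tail of the series
  st <- simulate_steady_state(model, inputs = c(s = 0.6))
  expect_true(st$converged)
  expect_equal(ts[12, ], st$state, tolerance = 1e-5)
  # a model with no edges never changes state
  empty <- logic_model(c("x", "y"), matrix(0L, 2, 2))
  flat <- simulate_timeseries(empty, c(x = 0.3, y = 0.8), n_points = 5)
  expect_true(all(flat[, "x"] == 0.3) && all(flat[, "y"] == 0.8))
})

test_that("a two-node oscillator alternates states in boolean mode", {
  model <- oscillator2_model()
  ts <- simulate_timeseries(model, c(u = 1, v = 0), n_points = 4,
                            config = simulation_config(mode = "boolean"))
  expect_equal(unname(ts[, "u"]), c(1, 1, 0, 0))
  expect_equal(unname(ts[, "v"]), c(0, 1, 1, 0))
})

test_that("model validation rejects malformed encodings", {
  nodes <- c("x", "y")
  B <- matrix(0L, 2, 2, dimnames = list(nodes, nodes))
  B["x", "y"] <- 1L
  C <- matrix(1L, 2, 2); C[1, 2] <- 3L
  expect_error(logic_model(nodes, B, C = C), "1..indegree")
  expect_error(logic_model(nodes, diag(2)), "self-loops")
  expect_error(logic_model(nodes, B, roles = c(y = "stimulated")),
               "stimulated")
})
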