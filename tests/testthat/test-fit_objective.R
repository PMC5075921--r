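test_that("mse_loss is the mean squared difference over all cells", {
  expect_equal(mse_loss(matrix(c(0, 1), 1), matrix(c(0, 1), 1)), 0)
  expect_equal(mse_loss(matrix(c(0, 1), 1), matrix(c(1, 0), 1)), 1)
  expect_equal(mse_loss(matrix(0.5), matrix(0)), 0.25)
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("dtw_align handles identical, stretched and reversed series", {
  y <- c(0.1, 0.5, 0.9)
  same <- dtw_align(y, y)
  expect_equal(same$loss, 0)
  expect_equal(same$a, 1:3)
  expect_equal(same$b, 1:3)
  # a stretched binary step aligns with zero loss
  expect_equal(dtw_align(c(0, 1), c(0, 0, 1, 1))$loss, 0)
  # exhaustive-oracle agreement on a short awkward pair
  y2 <- c(0, 1, 0); z2 <- c(1, 0)
  expect_equal(dtw_align(y2, z2)$loss, dtw_oracle(y2, z2))
  expect_error(dtw_align(numeric(), 1), "non-empty")
})

test_that("dtw warp paths satisfy endpoint, monotonicity and continuity", {
  set.seed(42)
  for (rep in 1:50) {
    y <- runif(sample(2:5, 1))
    z <- runif(sample(2:5, 1))
    al <- dtw_align(y, z)
    expect_equal(al$a[1], 1)
    expect_equal(al$b[1], 1)
    expect_equal(al$a[al$S], length(y))
    expect_equal(al$b[al$S], length(z))
    da <- diff(al$a); db <- diff(al$b)
    expect_true(all(da %in% 0:1) && all(db %in% 0:1))
    expect_true(all(da + db >= 1))
    expect_equal(al$loss, al$total / al$S)
  }
})

test_that("dtw equals the exhaustive path oracle on random short pairs", {
  set.seed(1)
  for (rep in 1:60) {
    y <- round(runif(sample(1:5, 1)), 3)
    z <- round(runif(sample(1:5, 1)), 3)
    expect_equal(dtw_loss(y, z), dtw_oracle(y, z), tolerance = 1e-10)
    # symmetry of the loss
    expect_equal(dtw_loss(y, z), dtw_loss(z, y), tolerance = 1e-12)
  }
})

test_that("equal-length dtw never exceeds the diagonal alignment", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    y <- runif(n); z <- runif(n)
    expect_lte(dtw_loss(y, z), mean((y - z)^2) + 1e-12)
  }
})

test_that("timeseries_loss sums per-node dtw losses and checks coverage", {
  y1 <- c(0, 1, 1); y2 <- c(1, 0.5, 0)
  ds <- timeseries_dataset(list(list(
    values = cbind(a = y1, b = y2), time = 1:3)))
  z <- cbind(a = c(0, 0, 1, 1, 1, 1, 1, 1, 1),
             b = c(1, 1, 0.5, 0.5, 0, 0, 0, 0, 0))
  expect_equal(timeseries_loss(ds, z),
               dtw_loss(y1, z[, "a"]) + dtw_loss(y2, z[, "b"]))
  expect_equal(timeseries_loss(ds, z), dtw_oracle(y1, z[, "a"]) +
                 dtw_oracle(y2, z[, "b"]), tolerance = 1e-10)
  expect_error(timeseries_loss(ds, z[, "a", drop = FALSE]), "lacks measured")
  # a single measured node reduces to dtw_align of that node
  ds1 <- timeseries_dataset(list(list(values = cbind(a = y1), time = 1:3)))
  expect_equal(timeseries_loss(ds1, z[, "a", drop = FALSE]),
               dtw_align(y1, z[, "a"])$loss)
})

test_that("sliding-window alignment takes the best window placement", {
  y <- c(0, 1)
  z <- cbind(a = c(1, 1, 1, 0, 1, 1))
  ds <- timeseries_dataset(list(list(values = cbind(a = y), time = 1:2)))
  full <- timeseries_loss(ds, z)
  slid <- timeseries_loss(ds, z, window = 2, stride = 1)
  expect_equal(slid, 0) # window at positions 4:5 matches exactly
  expect_gt(full, 0)
})

test_that("prior_penalty reduces to the qualitative disagreement count", {
  nodes <- c("x", "y", "z")
  prior <- prior_network(
    data.frame(source = c("x", "y"), target = c("y", "z"), sign = 1L,
               confidence = 1),
    roles = setNames(rep("measured", 3), nodes))
  B <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  B["x", "y"] <- 1L; B["y", "z"] <- 1L
  expect_equal(prior_penalty(B, prior), 0)
  # drop one prior edge (cost 1) and add a non-prior edge (cost 1)
  B2 <- B; B2["y", "z"] <- 0L; B2["x", "z"] <- 1L
  expect_equal(prior_penalty(B2, prior), 2)
  # quantitative: excluding a 0.8-confidence edge costs 0.8; including a
  # w-confidence edge costs 1 - w
  priorq <- prior_network(
    data.frame(source = "x", target = "y", sign = 1L, confidence = 0.8),
    roles = setNames(rep("measured", 3), nodes))
  expect_equal(prior_penalty(matrix(0L, 3, 3,
                                    dimnames = list(nodes, nodes)), priorq),
               0.8)
  expect_equal(prior_penalty(B, priorq), (1 - 0.8) + 1)
})

test_that("indegree_penalty is the hinge on indegree excess", {
  nodes <- letters[1:4]
  B <- matrix(0L, 4, 4, dimnames = list(nodes, nodes))
  B[1:3, "d"] <- 1L
  expect_equal(indegree_penalty(B, 3L), 0)
  expect_equal(indegree_penalty(B, 2L), 1)
  B[c(1, 2), "c"] <- 1L
  expect_equal(indegree_penalty(B, c(a = 2L, b = 2L, c = 1L, d = 1L)), 3)
  expect_equal(indegree_penalty(matrix(0L, 4, 4,
                                       dimnames = list(nodes, nodes)), 0L), 0)
})

test_that("objective composes loss and weighted penalties exactly", {
  model <- chain3_model()
  conditions <- lapply(c(0, 0.5, 1), function(v)
    list(stimuli = c(s = v), inhibitors = character()))
  ds <- make_steady_state_panel(model, conditions)
  prior <- prior_network(
    cbind(model_edges(model)[, c("source", "target", "sign")],
          confidence = 1),
    roles = model$roles, d_max = 2L)
  # perfect fit, perfect binary prior: total 0 at any weights
  obj <- objective(model, ds, prior, objective_config(gamma = 0.5))
  expect_equal(obj$total, 0)
  expect_equal(obj$loss, 0)
  # an off-model candidate decomposes additively
  wrong <- chain3_model(h = 0.3)
  for (gl in list(c(0, 0), c(0.5, 0.5), c(1.2, 0.3))) {
    o <- objective(wrong, ds, prior,
                   objective_config(gamma = gl[1], lam = gl[2]))
    expect_equal(o$total,
                 o$loss + gl[1] * o$prior_penalty + gl[2] * o$indegree_penalty)
  }
  # monotone in gamma and lambda for a fixed model
  B2 <- wrong$B; B2["s", "b"] <- 1L
  dense <- logic_model(wrong$nodes, B2, roles = wrong$roles,
                       hill = wrong$hill)
  o1 <- objective(dense, ds, prior, objective_config(gamma = 0.2, lam = 0.2))
  o2 <- objective(dense, ds, prior, objective_config(gamma = 0.9, lam = 0.2))
  o3 <- objective(dense, ds, prior, objective_config(gamma = 0.2, lam = 0.9))
  expect_gte(o2$total, o1$total)
  expect_gte(o3$total, o1$total)
})

test_that("hand-computed objective arithmetic matches", {
  # single node pair, one condition: loss 0.25, prior penalty 0.8 (one
  # excluded 0.8-confidence edge), indegree penalty 0 -> 0.25 + 0.4 = 0.65
  nodes <- c("s", "a")
  B <- matrix(0L, 2, 2, dimnames = list(nodes, nodes))
  model <- logic_model(nodes, B, roles = c(s = "stimulated", a = "measured"))
  ds <- steady_state_dataset(
    list(list(stimuli = c(s = 1), inhibitors = character())),
    matrix(0.5, 1, 1, dimnames = list(NULL, "a")))
  prior <- prior_network(
    data.frame(source = "s", target = "a", sign = 1L, confidence = 0.8),
    roles = c(s = "stimulated", a = "measured"))
  o <- objective(model, ds, prior, objective_config(gamma = 0.5, lam = 0.5))
  expect_equal(o$loss, 0.25)
  expect_equal(o$prior_penalty, 0.8)
  expect_equal(o$indegree_penalty, 0)
  expect_equal(o$total, 0.25 + 0.5 * 0.8)
})

test_that("datasets validate their inputs", {
  expect_error(steady_state_dataset(list(), matrix(1.5, 1, 1,
                                                   dimnames = list(NULL, "a"))),
               "one measurement row")
  expect_error(steady_state_dataset(
    list(list(stimuli = numeric(), inhibitors = character())),
    matrix(1.5, 1, 1, dimnames = list(NULL, "a"))), "normalize")
  expect_error(timeseries_dataset(list(list(values = cbind(a = 0.5)))),
               "at least 2")
})
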