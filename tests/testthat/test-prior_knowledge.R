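test_that("publication classification uses a strict threshold", {
  expect_equal(classify_publication(112, 111), "high_throughput")
  expect_equal(classify_publication(111, 111), "low_throughput")
  expect_equal(classify_publication(1, 111), "low_throughput")
  expect_equal(classify_publication(c(5, 200)), c("low_throughput", "high_throughput"))
  expect_error(classify_publication(0), "positive")
  expect_error(classify_publication(10, 0), "positive")
})

test_that("the high-throughput cutoff can be recomputed from counts", {
  counts <- c(rep(1:9, each = 10), rep(500, 10))
  thr <- ht_threshold_from_counts(counts)
  # 90% of publications endorse <= thr reactions, the top screens more
  expect_true(mean(counts <= thr) >= 0.9)
  expect_true(thr < 500)
  expect_error(ht_threshold_from_counts(integer()), "non-negative")
})

test_that("confidence scoring combines study types with a cap", {
  # single-type columns
  expect_equal(score_reaction(0, 0), 0)
  expect_equal(score_reaction(1, 0), 0.8)
  expect_equal(score_reaction(2, 0), 0.9)
  expect_equal(score_reaction(0, 1), 0.25)
  expect_equal(score_reaction(0, 3), 0.75)
  expect_equal(score_reaction(0, 7), 0.85)
  # combination rule: low-throughput base + 0.05 per high-throughput study
  expect_equal(score_reaction(1, 2), 0.9)
  expect_equal(score_reaction(2, 1), 0.95)
  # cap
  expect_equal(score_reaction(3, 2), 0.95)
  expect_equal(score_reaction(10, 10), 0.95)
  expect_error(score_reaction(-1, 0), "non-negative")
})

test_that("confidence scoring is monotone and bounded", {
  grid <- expand.grid(nl = 0:6, nh = 0:6)
  s <- score_reaction(grid$nl, grid$nh)
  expect_true(all(s >= 0 & s <= 0.95))
  expect_true(all(score_reaction(grid$nl + 1, grid$nh) >= s))
  expect_true(all(score_reaction(grid$nl, grid$nh + 1) >= s))
})

test_that("build_prior scores edges and merges duplicate records", {
  rec <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "B"),
                    sign = c("activation", "inhibition", "activation"),
                    n_low = c(1, 2, 1), n_high = 0)
  net <- build_prior(rec, roles = c(A = "stimulated", B = "measured",
                                    C = "measured"))
  expect_s3_class(net, "prior_network")
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$source == "A", ]
  expect_equal(ab$confidence, 0.9) # 1 + 1 low-throughput endorsements
  expect_equal(net$edges[net$edges$source == "B", "sign"], -1L)
  # a single-record edge scores the 1-endorsement value
  one <- build_prior(rec[1, ], roles = c(A = "measured", B = "measured"))
  expect_equal(one$edges$confidence, 0.8)
  expect_error(build_prior(rec, roles = c(A = "input")), "unknown role")
})

test_that("an empty record set with declared nodes gives an edgeless network", {
  net <- build_prior(data.frame(source = character(), target = character(),
                                sign = integer(), n_low = integer(),
                                n_high = integer()),
                     roles = c(X = "measured", Y = "stimulated"))
  expect_equal(nrow(net$edges), 0)
  expect_setequal(net$nodes, c("X", "Y"))
})

test_that("compression merges tandem edges with min confidence and sign product", {
  # A(designated) -0.8-> u -0.6-> B(designated)
  net <- prior_network(
    data.frame(source = c("A", "u"), target = c("u", "B"),
               sign = 1L, confidence = c(0.8, 0.6)),
    roles = c(A = "measured", B = "measured", u = "undesignated"))
  cmp <- compress_network(net)
  expect_equal(nrow(cmp$edges), 1)
  expect_equal(cmp$edges$source, "A")
  expect_equal(cmp$edges$target, "B")
  expect_equal(cmp$edges$confidence, 0.6)
  expect_false("u" %in% cmp$nodes)

  # inhibition x activation composes to inhibition, min score kept
  net2 <- prior_network(
    data.frame(source = c("A", "u"), target = c("u", "B"),
               sign = c(-1L, 1L), confidence = c(0.7, 0.9)),
    roles = c(A = "measured", B = "measured", u = "undesignated"))
  cmp2 <- compress_network(net2)
  expect_equal(cmp2$edges$sign, -1L)
  expect_equal(cmp2$edges$confidence, 0.7)

  # two inhibitions compose to activation
  net3 <- prior_network(
    data.frame(source = c("A", "u"), target = c("u", "B"),
               sign = c(-1L, -1L), confidence = c(0.5, 0.9)),
    roles = c(A = "measured", B = "measured", u = "undesignated"))
  expect_equal(compress_network(net3)$edges$sign, 1L)
})

test_that("compression preserves designated nodes and is idempotent", {
  # a longer cascade with a converging and a diverging undesignated node
  edges <- data.frame(
    source = c("S", "u1", "u2", "M1", "u3", "u3"),
    target = c("u1", "u2", "M1", "u3", "M2", "M3"),
    sign = c(1L, -1L, 1L, 1L, 1L, -1L),
    confidence = c(0.9, 0.8, 0.7, 0.95, 0.6, 0.5))
  roles <- c(S = "stimulated", M1 = "measured", M2 = "measured",
             M3 = "measured", u1 = "undesignated", u2 = "undesignated",
             u3 = "undesignated")
  net <- prior_network(edges, roles = roles)
  cmp <- compress_network(net)
  expect_true(all(c("S", "M1", "M2", "M3") %in% cmp$nodes))
  expect_false(any(c("u1", "u2", "u3") %in% cmp$nodes))
  # path bottleneck confidence preserved: S -> M1 had min 0.7 along the chain
  sm1 <- cmp$edges[cmp$edges$source == "S" & cmp$edges$target == "M1", ]
  expect_equal(sm1$confidence, 0.7)
  expect_equal(sm1$sign, -1L) # one inhibition on the original chain
  # diverging: M1 -> M2 and M1 -> M3 with min(0.95, .) confidences
  expect_equal(cmp$edges[cmp$edges$target == "M2", "confidence"], 0.6)
  expect_equal(cmp$edges[cmp$edges$target == "M3", "confidence"], 0.5)
  # idempotent, and edge/node counts never grow
  again <- compress_network(cmp)
  expect_identical(again$edges, cmp$edges)
  expect_identical(again$nodes, cmp$nodes)
  expect_lte(nrow(cmp$edges), nrow(net$edges))
  expect_true(all(cmp$nodes %in% net$nodes))
})

test_that("fully designated networks pass through compression unchanged", {
  net <- prior_network(
    data.frame(source = c("A", "B"), target = c("B", "C"), sign = 1L,
               confidence = c(0.8, 0.9)),
    roles = c(A = "stimulated", B = "measured", C = "measured"))
  cmp <- compress_network(net)
  expect_identical(cmp$edges, net$edges)
})

test_that("compression drops incoming edges of stimulated nodes", {
  net <- prior_network(
    data.frame(source = c("A", "B"), target = c("B", "A"), sign = 1L,
               confidence = 0.8),
    roles = c(A = "stimulated", B = "measured"))
  cmp <- compress_network(net)
  expect_equal(nrow(cmp$edges), 1)
  expect_equal(cmp$edges$target, "B")
})

test_that("hub undesignated nodes with many-in many-out are not merged", {
  edges <- data.frame(source = c("A", "B", "u", "u"),
                      target = c("u", "u", "C", "D"),
                      sign = 1L, confidence = 0.9)
  roles <- c(A = "measured", B = "measured", C = "measured", D = "measured",
             u = "undesignated")
  cmp <- compress_network(prior_network(edges, roles = roles))
  expect_true("u" %in% cmp$nodes)
  expect_equal(nrow(cmp$edges), 4)
})
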