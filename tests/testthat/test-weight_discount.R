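test_that("combined_weight matches hand evaluation and boundary cases", {
  # agreement: sim == clar == s gives W = s
  s <- c(0.2, 0.5, 0.9)
  expect_equal(combined_weight(s, s)$w, s, tolerance = 1e-12)

  # pure similarity bound
  expect_equal(combined_weight(1, 0)$w, 0.5)

  # hand evaluation of the damped form
  expect_equal(combined_weight(0.743, 0.252)$w,
               0.5 * (0.743 + 0.252 * exp(-0.491)), tolerance = 1e-12)

  # amplifying mode multiplies by exp(+| |) instead
  expect_equal(combined_weight(0.6, 0.2, exponent_mode = "amplifying")$w,
               0.5 * (0.6 + 0.2 * exp(0.4)), tolerance = 1e-12)

  expect_error(combined_weight(1.2, 0.5), class = "dsfusion_validation_error")
  expect_error(combined_weight(c(0.1, 0.2), 0.5),
               class = "dsfusion_validation_error")
})

test_that("combined_weight is bounded and monotone in similarity (grid)", {
  grid <- seq(0, 1, by = 0.05)
  for (clar in grid) {
    w <- combined_weight(grid, rep(clar, length(grid)))$w
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(diff(w) >= -1e-12))  # non-decreasing in sim at fixed clar
  }
})

test_that("baseline_weight implements the four reference schemes", {
  sim <- c(0.8, 0.4)
  clar <- c(0.5, 1.0)
  expect_equal(baseline_weight(sim, clar, "conflict_only")$w, sim)
  expect_equal(baseline_weight(sim, clar, "clarity_only")$w, clar)
  expect_equal(baseline_weight(sim, clar, "product")$w, c(1, 1))
  expect_equal(baseline_weight(sim, clar, "arithmetic_mean")$w,
               c(0.65, 0.7))
  expect_equal(baseline_weight(c(0.5, 0.5), c(0.5, 0.5),
                               "arithmetic_mean")$w, c(0.5, 0.5))
  # conflict_only on the counterexample: proportional to raw (1.4, 1.4, 0.8)
  ce <- counterexample_evidence()
  w <- baseline_weight(similarity_scores(ce), clarity_scores(ce),
                       "conflict_only")$w
  expect_equal(w / w[3], c(1.4, 1.4, 0.8) / 0.8, tolerance = 1e-9)
  expect_error(baseline_weight(sim, clar, "nope"))
})

test_that("trust_discount reallocates mass and self-normalizes", {
  f5 <- activity_frame()
  m <- singleton_mass(f5, c(0.145, 0.724, 0.127, 0.003, 0.001))

  # full trust: unchanged
  expect_equal(singleton_probs(trust_discount(m, 1)), singleton_probs(m),
               tolerance = 1e-12)

  # uniform BPA is a fixed point for any weight
  for (w in c(0, 0.3, 0.8)) {
    expect_equal(singleton_probs(trust_discount(uniform_mass(f5), w)),
                 singleton_probs(uniform_mass(f5)), tolerance = 1e-12)
  }

  # direct evaluation at W = 0.5 with the frame-minus-one divisor
  p <- singleton_probs(m)
  got <- singleton_probs(trust_discount(m, 0.5))
  expect_equal(got, 0.5 * p + 0.125 * (1 - p), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_equal(which.max(got), which.max(p))  # top class preserved

  # literal divisor 2 renormalizes to a valid BPA
  lit <- singleton_probs(trust_discount(m, 0.5, "literal_two"))
  expect_equal(sum(lit), 1, tolerance = 1e-12)
  raw <- 0.5 * p + 0.25 * (1 - p)
  expect_equal(lit, raw / sum(raw), tolerance = 1e-12)

  f2 <- ds_frame(c("A", "B"))
  expect_error(trust_discount(make_mass(f2, c("A|B" = 1)), 0.5),
               class = "dsfusion_unsupported_error")
  expect_error(trust_discount(m, 1.2), class = "dsfusion_validation_error")
})

test_that("frame_minus_one discount sums to 1 without renormalization", {
  # algebraic identity W + (1-W)/(n-1) * (n-1) = 1, checked to 1e-12
  set.seed(23)
  for (n in 2:6) {
    f <- ds_frame(LETTERS[1:n])
    for (rep in 1:10) {
      p <- singleton_probs(random_bpa(f, singleton_only = TRUE))
      w <- stats::runif(1)
      q <- p * w + ((1 - w) / (n - 1)) * (1 - p)
      expect_equal(sum(q), 1, tolerance = 1e-12)
    }
  }
})

test_that("discount_all maps element-wise and keeps fusion feasible", {
  ev <- example_bpas()
  w <- c(0.4, 0.5, 0.6)
  out <- discount_all(ev, w)
  expect_length(out, 3)
  expect_equal(singleton_probs(out[[2]]),
               singleton_probs(trust_discount(ev[[2]], 0.5)),
               tolerance = 1e-12)
  # identity weights pass evidence through unchanged
  same <- discount_all(ev, c(1, 1, 1))
  for (i in 1:3) {
    expect_equal(singleton_probs(same[[i]]), singleton_probs(ev[[i]]),
                 tolerance = 1e-12)
  }
  # any positive weight leaves all classes positive, so k < 1 downstream
  pos <- discount_all(ev, c(0.2, 0.9, 0.55))
  expect_true(all(vapply(pos, function(m) all(singleton_probs(m) > 0),
                         logical(1))))
  expect_lt(combine_all(pos)$conflict_k, 1)
  expect_error(discount_all(ev, c(0.5, 0.5)),
               class = "dsfusion_validation_error")
})

test_that("dissenter conflict penalty grows with conflict level (sweep)", {
  # The weight itself is deliberately non-monotone in the conflict level:
  # near-uniform dissent is penalized through clarity, sharp dissent through
  # similarity, and the crossover creates a dip. What does hold on the grid:
  # the dissenter's similarity score is non-increasing in conflict_level at
  # fixed fuzziness, and its clarity-term contribution stays damped so the
  # fused decision follows the majority at the reference scenario.
  for (fz in c(0, 0.3, 0.6, 1)) {
    s_last <- Inf
    for (cl in seq(0, 1, by = 0.1)) {
      ev <- conflict_scenario(n_classes = 2, n_evidence = 3,
                              conflict_level = cl, fuzziness_level = fz)
      s <- similarity_scores(ev)$normalized[3]
      expect_lte(s, s_last + 1e-9)
      s_last <- s
    }
  }
  # at the reference scenario the full chain follows the fuzzy majority
  ev <- conflict_scenario(2, 3, conflict_level = 6 / 7, fuzziness_level = 0.6)
  p <- singleton_probs(fuse_evidence(ev, fusion_config("proposed"))$fused)
  expect_gt(p[["B"]], p[["A"]])
})
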