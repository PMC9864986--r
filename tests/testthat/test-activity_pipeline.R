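test_that("fit_prototypes takes per-class means and validates input", {
  d <- data.frame(x = c(1, 3, 10), label = c("A", "A", "B"))
  proto <- fit_prototypes(d)
  expect_equal(unname(proto$values["x", ]), c(2, 10))
  expect_equal(proto$frame$labels, c("A", "B"))

  # single row per class: that row's values
  d1 <- data.frame(x = c(4, 7), y = c(0, 1), label = c("A", "B"))
  p1 <- fit_prototypes(d1)
  expect_equal(unname(p1$values[, "B"]), c(7, 1))

  # zero-noise synthetic data recovers the generating prototypes exactly
  ref <- activity_prototypes()
  d0 <- generate_dataset(ref, noise_sd = 0, n_per_class = 3, seed = 1)
  fit <- fit_prototypes(d0, frame = ref$frame)
  expect_equal(fit$values[ref$sensors, ], ref$values, tolerance = 1e-12)

  expect_error(fit_prototypes(d, frame = ds_frame(c("A", "B", "C"))),
               class = "dsfusion_validation_error")
  expect_error(fit_prototypes(data.frame(label = "A")),
               class = "dsfusion_validation_error")
  expect_error(fit_prototypes(d[0, ]), class = "dsfusion_validation_error")
})

test_that("generate_bpa reproduces the published evidence rows", {
  proto <- activity_prototypes()
  reading <- example_reading()
  published <- rbind(
    ACC  = c(0.145, 0.724, 0.127, 0.003, 0.001),
    GYRO = c(0.217, 0.249, 0.502, 0.018, 0.013),
    BPM  = c(0.113, 0.155, 0.628, 0.078, 0.025)
  )
  # BPM row matches the printed rounding exactly; all rows within 1e-3
  bpm <- singleton_probs(generate_bpa(reading, proto, "BPM"))
  expect_equal(unname(round(bpm, 3)), published["BPM", ])
  for (s in rownames(published)) {
    got <- singleton_probs(generate_bpa(reading, proto, s))
    expect_true(all(abs(got - published[s, ]) <= 1e-3 + 1e-12))
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_true(all(got > 0))
  }
  expect_error(generate_bpa(reading, proto, "EMG"),
               class = "dsfusion_validation_error")
})

test_that("generate_bpa limits and monotonicity", {
  proto <- activity_prototypes()
  # exact prototype hit concentrates essentially all mass on that class
  at_walk <- c(ACC = 9.7433, GYRO = 0.39, BPM = 101)
  m <- singleton_probs(generate_bpa(at_walk, proto, "ACC"))
  expect_gt(m[["walking"]], 1 - 1e-9)

  # equidistant between two far-separated prototypes: equal masses
  f <- ds_frame(c("A", "B", "C"))
  pt <- new_prototype_table(f, matrix(c(0, 2, 100), 1,
                                      dimnames = list("s", f$labels)))
  eq <- singleton_probs(generate_bpa(c(s = 1), pt, "s"))
  expect_equal(eq[["A"]], eq[["B"]], tolerance = 1e-12)

  # moving a reading toward a prototype never decreases that class's mass
  walk_mass <- vapply(seq(101, 103.4, length.out = 10), function(bpm) {
    singleton_probs(generate_bpa(c(BPM = bpm), proto, "BPM"))[["walking"]]
  }, numeric(1))
  expect_true(all(diff(walk_mass) >= -1e-12))
})

test_that("classify runs every scheme and is stable to sensor order", {
  proto <- activity_prototypes()
  reading <- example_reading()

  ds <- classify(reading, proto, fusion_config("ds"))
  expect_true(all(abs(singleton_probs(ds$fused) -
                        c(0.0496, 0.3901, 0.5602, 0.0001, 0.0000)) <= 1e-3))
  expect_equal(ds$decision, "walking")

  prop <- classify(reading, proto, fusion_config("proposed"))
  expect_equal(prop$decision, "walking")
  expect_gt(singleton_probs(prop$fused)[["walking"]],
            singleton_probs(prop$fused)[["standing"]])
  expect_length(prop$weights$w, 3)
  expect_s3_class(prop$similarity, "similarity_scores")

  for (sc in c("conflict_only", "clarity_only", "product",
               "arithmetic_mean")) {
    r <- classify(reading, proto, fusion_config(sc))
    expect_equal(sum(singleton_probs(r$fused)), 1, tolerance = 1e-9)
  }

  # sensor (row) order of the prototype table does not change the decision
  perm <- new_prototype_table(proto$frame,
                              proto$values[c("BPM", "ACC", "GYRO"), ])
  expect_equal(classify(reading, perm, fusion_config("proposed"))$decision,
               prop$decision)

  # two agreeing near-certain sensors: Dempster reinforcement
  f <- ds_frame(c("A", "B"))
  pt2 <- new_prototype_table(f, matrix(c(0, 10, 0, 10), 2, byrow = TRUE,
                                       dimnames = list(c("s1", "s2"),
                                                       f$labels)))
  r2 <- classify(c(s1 = 0.5, s2 = 0.5), pt2, fusion_config("ds"))
  expect_equal(r2$decision, "A")
  input_mass <- singleton_probs(generate_bpa(c(s1 = 0.5), pt2, "s1"))[["A"]]
  expect_gt(singleton_probs(r2$fused)[["A"]], input_mass)
})

test_that("evaluate produces a coherent confusion matrix and kappa", {
  proto <- activity_prototypes()
  d0 <- generate_dataset(proto, noise_sd = 0, n_per_class = 4, seed = 2)
  for (sc in c("ds", "proposed")) {
    ev <- evaluate(d0, proto, fusion_config(sc))
    expect_equal(ev$weighted_accuracy, 1)
    expect_equal(ev$kappa, 1)
    expect_equal(ev$kappa_band, "almost perfect")
    expect_equal(unname(rowSums(ev$confusion)), rep(4, 5))
  }
  expect_error(evaluate(d0[0, ], proto), class = "dsfusion_validation_error")
  bad <- d0; bad$label[1] <- "swimming"
  expect_error(evaluate(bad, proto), class = "dsfusion_validation_error")
})

test_that("kappa agrees with the independent pair-based oracle", {
  set.seed(29)
  proto <- activity_prototypes()
  d <- generate_dataset(proto, n_per_class = 12, seed = 31)
  ev <- evaluate(d, proto, fusion_config("proposed"))
  # recompute predictions independently for the oracle
  pred <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    reading <- as.numeric(d[i, proto$sensors]); names(reading) <- proto$sensors
    pred[i] <- classify(reading, proto, fusion_config("proposed"))$decision
  }
  expect_equal(ev$kappa, oracle_kappa(d$label, pred), tolerance = 1e-12)
  expect_equal(ev$weighted_accuracy, mean(d$label == pred), tolerance = 1e-12)

  # random label pairs: confusion-matrix kappa == marginal-probability kappa
  for (rep in 1:5) {
    truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
    guess <- sample(c("A", "B", "C"), 60, replace = TRUE)
    cm <- table(factor(truth, levels = c("A", "B", "C")),
                factor(guess, levels = c("A", "B", "C")))
    p0 <- sum(diag(cm)) / 60
    pe <- sum(rowSums(cm) * colSums(cm)) / 60^2
    expect_equal((p0 - pe) / (1 - pe), oracle_kappa(truth, guess),
                 tolerance = 1e-12)
  }
})

test_that("kappa_band maps coefficients to the interpretation labels", {
  expect_equal(kappa_band(0.1), "slight")
  expect_equal(kappa_band(0.35), "fair")
  expect_equal(kappa_band(0.5), "moderate")
  expect_equal(kappa_band(0.75), "substantial")
  expect_equal(kappa_band(0.95), "almost perfect")
  expect_equal(kappa_band(-0.2), "poor")
})
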