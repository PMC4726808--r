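test_that("outcome vectors read the classical joint grouped by target state", {
  v <- build_vectors(pd_average_net(), "P2")
  expect_equal(v$a, c(0.435, 0.370), tolerance = 1e-12)
  expect_equal(v$b, c(0.065, 0.130), tolerance = 1e-12)
  expect_equal(v$states, c("defect", "cooperate"))

  # guessed-condition game: direct products of prior and conditionals
  croson1 <- record_to_network(stp_studies("T9")[1, ])
  v9 <- build_vectors(croson1, "P2")
  expect_equal(v9$a, c(0.085, 0.340), tolerance = 1e-12)
  expect_equal(v9$b, c(0.415, 0.160), tolerance = 1e-12)

  # deterministic prior zeroes one component
  det <- two_node_net(0.6, 0.4, prior1 = 1)
  expect_equal(build_vectors(det, "P2")$a[2], 0)

  # no interference pair once the parent is observed
  expect_error(build_vectors(pd_average_net(), "P2",
                             evidence = c(P1 = "defect")),
               class = "qlbn_no_pair")
})

test_that("law-of-cosines triangle matches the worked example", {
  ang <- triangle(build_vectors(pd_average_net(), "P2"))
  expect_equal(ang$norm_c, 0.4410, tolerance = 0.0005)
  expect_equal(ang$norm_a, 0.5711, tolerance = 0.0005)
  expect_equal(ang$norm_b, 0.1453, tolerance = 0.0005)
  expect_equal(ang$theta_A, 2.6102, tolerance = 0.01)
  expect_equal(ang$theta_B, 0.1294, tolerance = 0.01)
  expect_equal(ang$theta_C, 0.4023, tolerance = 0.01)
  expect_equal(ang$phi, 0.1046, tolerance = 0.001)
})

test_that("triangle angles sum to pi and theta_C matches cosine similarity", {
  # all two-path literature fixtures
  for (tid in c("T1", "T2", "T9", "T10")) {
    recs <- stp_studies(tid)
    for (i in seq_len(nrow(recs))) {
      net <- record_to_network(recs[i, ])
      tgt <- if (identical(recs$game[i], "two_stage_gamble")) "G2" else "P2"
      v <- build_vectors(net, tgt)
      ang <- triangle(v)
      expect_equal(ang$theta_A + ang$theta_B + ang$theta_C, pi,
                   tolerance = 1e-6)
      cos_sim <- sum(v$a * v$b) / (ang$norm_a * ang$norm_b)
      expect_equal(cos(ang$theta_C), cos_sim, tolerance = 1e-9)
    }
  }
  # 500 seeded random vector pairs
  withr::with_seed(77, {
    for (k in 1:500) {
      a <- runif(2, 0.01, 1)
      b <- runif(2, 0.01, 1)
      if (sqrt(sum((a - b)^2)) < 1e-8) next
      ang <- triangle(a, b)
      expect_equal(ang$theta_A + ang$theta_B + ang$theta_C, pi,
                   tolerance = 1e-6)
      expect_equal(cos(ang$theta_C),
                   sum(a * b) / (ang$norm_a * ang$norm_b),
                   tolerance = 1e-9)
    }
  })
})

test_that("collinear vectors give a flat triangle", {
  b <- c(0.2, 0.1)
  ang <- triangle(2 * b, b)
  expect_equal(ang$theta_C, 0, tolerance = 1e-7)
  expect_equal(ang$theta_A + ang$theta_B, pi, tolerance = 1e-6)
  expect_error(triangle(c(0, 0), b), class = "qlbn_degenerate")
})

test_that("piecewise heuristic selects the printed branch and phase", {
  ang <- triangle(build_vectors(pd_average_net(), "P2"))
  hp <- heuristic_phase(ang)
  expect_equal(hp$branch, "otherwise")
  expect_equal(hp$theta, 2.7393, tolerance = 0.01)

  # strongly dissimilar vectors: phi > 0.2 halves theta_C's subtraction
  ang_st <- triangle(c(0.485, 0.42), c(0.015, 0.08))
  hp_st <- heuristic_phase(ang_st)
  expect_equal(hp_st$branch, "phi>0.2")
  expect_equal(hp_st$theta, pi - ang_st$theta_C / 2, tolerance = 1e-12)
  expect_equal(hp_st$theta, 2.8057, tolerance = 0.01)

  # negative phi forces full destructive interference
  fake <- tibble::tibble(theta_A = 1.8, theta_B = 1.0, theta_C = 0.34,
                         phi = -0.35)
  expect_equal(heuristic_phase(fake)$theta, pi)
  expect_equal(heuristic_phase(fake)$branch, "phi<0")

  # boundaries fall in the otherwise branch (strict inequalities)
  for (phi0 in c(0, 0.2)) {
    fk <- tibble::tibble(theta_A = 1, theta_B = 1, theta_C = 0.5, phi = phi0)
    expect_equal(heuristic_phase(fk)$branch, "otherwise")
  }
})

test_that("heuristic output is in (0, pi] and destructive on all fixtures", {
  for (tid in c("T1", "T2", "T9", "T10")) {
    recs <- stp_studies(tid)
    for (i in seq_len(nrow(recs))) {
      net <- record_to_network(recs[i, ])
      tgt <- if (identical(recs$game[i], "two_stage_gamble")) "G2" else "P2"
      pred <- qlbn_predict(net, tgt)
      expect_true(pred$theta > 0 && pred$theta <= pi)
      expect_lte(cos(pred$theta), 0)
    }
  }
})

test_that("end-to-end predictions reproduce the verified fixture rows", {
  cases <- list(
    # study conditions, queried variable, expected probability
    list(rec = stp_studies("T1")[6, ], tgt = "P2", p = 0.7208),  # average PD
    list(rec = stp_studies("T1")[1, ], tgt = "P2", p = 0.6408),
    list(rec = stp_studies("T2")[1, ], tgt = "G2", p = 0.3641),
    list(rec = stp_studies("T9")[2, ], tgt = "P2", p = 0.4390),
    list(rec = stp_studies("T10")[8, ], tgt = "P2", p = 0.7122)
  )
  for (cs in cases) {
    pred <- qlbn_predict(record_to_network(cs$rec), cs$tgt)
    expect_equal(pred$p, cs$p, tolerance = 0.005)
  }
  pd <- qlbn_predict(record_to_network(stp_studies("T1")[6, ]), "P2",
                     observed = 0.64)
  expect_equal(pd$fit_error, 12.63, tolerance = 0.5)
})

test_that("swapping target states swaps the vector geometry", {
  net <- pd_average_net()
  f <- triangle(build_vectors(net, "P2", state = "defect"))
  g <- triangle(build_vectors(net, "P2", state = "cooperate"))
  expect_equal(g$norm_a, f$norm_b, tolerance = 1e-12)
  expect_equal(g$norm_b, f$norm_a, tolerance = 1e-12)
  expect_equal(g$norm_c, f$norm_c, tolerance = 1e-12)
  expect_equal(g$theta_A, f$theta_B, tolerance = 1e-12)
  expect_equal(g$theta_B, f$theta_A, tolerance = 1e-12)
  expect_equal(g$theta_C, f$theta_C, tolerance = 1e-12)

  # when both orientations fire the phi<0 branch the phase is pi either
  # way and the predicted distribution simply permutes
  ts <- record_to_network(stp_studies("T2")[1, ])
  p_play <- qlbn_predict(ts, "G2", state = "play")
  p_stop <- qlbn_predict(ts, "G2", state = "stop")
  expect_equal(p_play$branch, "phi<0")
  expect_equal(p_stop$branch, "phi<0")
  expect_equal(p_play$p, 1 - p_stop$p, tolerance = 1e-12)
})

test_that("degenerate geometry falls back to the classical collapse", {
  det <- two_node_net(1, 1)  # b = (0, 0): no cooperate mass anywhere
  expect_warning(pred <- qlbn_predict(det, "P2"), "Degenerate")
  expect_true(pred$degenerate)
  expect_equal(pred$theta, pi / 2)
  expect_equal(pred$p, classical_infer(det, "P2")$prob[1], tolerance = 1e-12)
})

test_that("more than two hidden completions get per-pair phases", {
  net <- chain3_net()
  # six destructive pairwise phases can drive a score negative here; the
  # result is flagged rather than clipped
  pred <- suppressWarnings(qlbn_predict(net, "A"))
  expect_equal(length(pred$phases), choose(4, 2))
  expect_true(all(pred$phases > 0 & pred$phases <= pi))
  qi <- suppressWarnings(quantum_infer(net, "A", phases = pred$phases))
  expect_equal(unname(qi$prob), unname(pred$result$prob), tolerance = 1e-12)
  expect_true(qi$nonphysical)
})
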