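# Rate laws, generator structure, detailed balance, the ML277 rule,
# variants and stationary distributions.

test_that("rate laws evaluate the exponential voltage dependence", {
  a2 <- rate_law(0.0047, 37.7, +1)
  expect_equal(evaluate_rate(a2, 0), 0.0047)
  a1 <- rate_law(0.00070, 46.0, +1)
  expect_equal(evaluate_rate(a1, 46.0), 0.00070 * exp(1), tolerance = 1e-12)
  b3 <- rate_law(0.048, 41.5, -1)
  expect_equal(evaluate_rate(b3, 0), 0.048)
  # monotone with sign = direction
  v <- seq(-100, 100, by = 20)
  expect_true(all(diff(evaluate_rate(a1, v)) > 0))
  expect_true(all(diff(evaluate_rate(b3, v)) < 0))
  expect_error(evaluate_rate(a1, NaN), "finite")
  expect_error(rate_law(-1, 10), "prefactor")
  expect_error(rate_law(1, 0), "slope")
})

test_that("generator has the ten scheme edges, no RC-open edge, zero row sums", {
  for (v in c(-120, 0, 40, 80)) {
    Q <- build_generator(ctrl, v)
    expect_equal(Q["RC", "IO"], 0)
    expect_equal(Q["RC", "AO"], 0)
    expect_equal(Q["AO", "RC"], 0)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    expect_equal(sum(off > 0), 10)
  }
  Q0 <- build_generator(ctrl, 0)
  expect_equal(Q0["AO", "AC"], 853.08)   # coupling rates at v = 0
  expect_equal(Q0["IC", "AC"], 0.0047)   # prefactor at v = 0
})

test_that("printed control set obeys detailed balance on the cycle", {
  rep <- loop_balance_report(ctrl)
  expect_true(rep$cycle)
  # brute-force products of the four printed constants on each side
  expect_equal(rep$forward_product, 0.0047 * 0.89 * 0.048 * 103.82)
  expect_equal(rep$reverse_product, 0.96 * 0.15 * 853.08 * 0.00017)
  expect_equal(rep$ratio, 1, tolerance = 0.01)
  expect_true(rep$slope_consistent)
  expect_lt(rep$max_voltage_variation, 1e-10)
})

test_that("halving k2 alone halves the loop ratio; open loop reports no cycle", {
  p <- ctrl; p$k2 <- ctrl$k2 / 2
  rep <- loop_balance_report(p)
  r0 <- loop_balance_report(ctrl)$ratio
  expect_equal(rep$ratio / r0, 2, tolerance = 1e-12)  # reverse halves
  f351a <- make_variant(ctrl, "no_IO_coupling")
  expect_false(loop_balance_report(f351a)$cycle)
  expect_equal(loop_balance_report(f351a)$message, "no cycle")
})

test_that("balanced_c3 restores ratio one and is linear in k2_new", {
  expect_equal(balanced_c3(ctrl, 426.54), 0.024, tolerance = 0.005)
  expect_equal(balanced_c3(ctrl, 853.08),
               0.96 * 0.15 * 853.08 * 0.00017 / (0.0047 * 0.89 * 103.82))
  expect_equal(balanced_c3(ctrl, 213.27), balanced_c3(ctrl, 853.08) / 4,
               tolerance = 1e-12)
  set.seed(7)
  mults <- stats::runif(10, 0.1, 3)
  c3s <- vapply(mults, function(f) balanced_c3(ctrl, ctrl$k2 * f),
                numeric(1))
  expect_equal(c3s, mults * balanced_c3(ctrl, ctrl$k2), tolerance = 1e-12)
  for (f in mults) {
    p <- ctrl; p$k2 <- ctrl$k2 * f; p$c3 <- balanced_c3(ctrl, p$k2)
    expect_equal(loop_balance_report(p)$ratio, 1, tolerance = 1e-12)
  }
  bad <- make_variant(ctrl, "no_IO_coupling")
  expect_error(balanced_c3(bad, 100), "degenerate")
})

test_that("the ML277 rule halves k2 and rebalances c3", {
  m <- apply_ml277(ctrl)
  expect_equal(m$k2, 426.54)
  expect_equal(m$c3, 0.024, tolerance = 0.005)
  expect_equal(loop_balance_report(m)$ratio, 1, tolerance = 0.01)
  same <- setdiff(names(ctrl), c("k2", "c3", "label"))
  expect_identical(ctrl[same], m[same])
  mm <- apply_ml277(m)               # rule composes
  expect_equal(mm$k2, 213.27)
  expect_equal(mm$c3, m$c3 / 2, tolerance = 1e-12)
})

test_that("variants restrict the reachable set and zero the right coupling", {
  il <- make_variant(ctrl, "intermediate_locked")
  expect_setequal(reachable_states(il), c("IC", "IO"))
  al <- make_variant(ctrl, "activated_locked")
  expect_setequal(reachable_states(al), c("AC", "AO"))
  nao <- make_variant(ctrl, "no_AO_coupling")
  expect_equal(nao$k1, 0)
  expect_false("AO" %in% reachable_states(nao))
  nio <- make_variant(ctrl, "no_IO_coupling")
  expect_equal(nio$k3, 0)
  expect_false("IO" %in% reachable_states(nio))
  expect_error(make_variant(ctrl, "nonsense"), "unknown variant")
})

test_that("activated-locked equilibrium is the two-state value", {
  al <- make_variant(ctrl, "activated_locked")
  ss <- steady_state(al, 0)
  expect_equal(ss[["AO"]], 0.89 / (0.89 + 853.08), tolerance = 1e-10)
  ssm <- steady_state(apply_ml277(al), 0)
  expect_equal(ssm[["AO"]] / ss[["AO"]],
               (0.89 / (0.89 + 426.54)) / (0.89 / (0.89 + 853.08)),
               tolerance = 1e-10)
  # k2 is irrelevant when AO is unreachable
  nao <- make_variant(ctrl, "no_AO_coupling")
  expect_equal(steady_state(apply_ml277(nao), 40),
               steady_state(nao, 40), tolerance = 1e-12)
})

test_that("steady state is stationary, normalized, and matches an eigen oracle", {
  set.seed(11)
  for (i in 1:10) {
    p <- perturbed_params()
    v <- stats::runif(1, -120, 80)
    ss <- steady_state(p, v)
    expect_true(all(ss >= 0))
    expect_equal(sum(ss), 1, tolerance = 1e-10)
    Q <- build_generator(p, v)
    expect_lt(max(abs(ss %*% Q)), 1e-10)
    expect_equal(unname(ss), eigen_steady(Q), tolerance = 1e-9)
  }
  expect_gt(steady_state(ctrl, -300)[["RC"]], 0.999)
})

test_that("steady state equals the long-time limit of integration", {
  prot <- qk_protocol(data.frame(v_mV = 40, duration_ms = 60000),
                      sampling_interval_ms = 100)
  traj <- integrate_occupancy(ctrl, prot)
  final <- traj$occupancy[nrow(traj$occupancy), ]
  expect_equal(final, steady_state(ctrl, 40), tolerance = 1e-6)
})

test_that("reducible chains are rejected with the disconnected states named", {
  p <- ctrl
  p$k1 <- 0; p$k3 <- 0   # open row cut off from the closed row
  p$variant <- NULL
  err <- tryCatch(steady_state(p, 0), error = function(e) conditionMessage(e))
  expect_match(err, "reducible|disconnected")
})
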