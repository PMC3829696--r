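test_that("default rate matrix matches its printed definition", {
  Q <- default_rates(0.5, 1)
  off <- Q[row(Q) != col(Q)]
  expect_true(all(off == 0.5))             # full symmetry at theta=.5, kappa=1

  Q2 <- default_rates(0.5, 2.1)
  expect_equal(Q2["C", "T"], 1.05)         # kappa (1 - theta)
  expect_equal(Q2["T", "C"], 1.05)         # kappa theta
  expect_equal(Q2["C", "G"], 0.5)

  Q3 <- default_rates(0.3, 2)
  expect_equal(Q3["T", "C"], 2 * 0.3)      # kappa theta
  expect_equal(Q3["C", "A"], 0.7)          # 1 - theta
  expect_equal(Q3["A", "G"], 2 * 0.3)
  expect_equal(Q3["G", "A"], 2 * 0.7)

  expect_error(default_rates(0, 1))
  expect_error(default_rates(0.5, -1))
})

test_that("single-site stationarity of the default process", {
  # flow balance at m_C = m_G = theta/2, m_A = m_T = (1-theta)/2
  for (theta in c(0.3, 0.62)) for (kappa in c(1, 3.4)) {
    Q <- default_rates(theta, kappa)
    m <- c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2,
           T = (1 - theta) / 2)
    inflow <- as.vector(m %*% Q)
    outflow <- m * rowSums(Q)
    expect_equal(inflow, unname(outflow), tolerance = 1e-12)
  }
})

test_that("context_rate multiplies the two neighbor factors onto Q", {
  fv <- factor_vector(kappa = 2)
  # all factors 1: rate equals the default for every context
  Q <- default_rates(0.4, 2)
  for (x in NUCS) for (z in NUCS)
    expect_equal(context_rate(fv, x, "G", "A", z, 0.4), Q["G", "A"])

  fv2 <- factor_vector(kappa = 2, mode = "rna")
  fv2 <- set_factor(fv2, "A,C>G", 0.7)
  fv2 <- set_factor(fv2, "C>G,T", 2)
  expect_equal(context_rate(fv2, "A", "C", "G", "T", 0.4),
               1.4 * Q["C", "G"])

  # the classical CpG deamination parameterization: kappa = 2.1,
  # f(C>T, G) = 27.6 / 2.1 gives rate 27.6 (1 - theta) in CpG context
  fv3 <- factor_vector(kappa = 2.1, factors = c("C>T,G" = 27.6 / 2.1))
  for (theta in c(0.3, 0.5))
    expect_equal(context_rate(fv3, "A", "C", "T", "G", theta),
                 27.6 * (1 - theta))
  expect_error(context_rate(fv, "A", "C", "C", "G", 0.5), "differ")
})

test_that("change_count reproduces worked examples and the string oracle", {
  expect_identical(change_count(c("C", "A"), c("C", "A", "T", "G")), -1L)
  expect_identical(change_count(c("T", "T"), c("T", "C", "T", "T")), 2L)
  expect_identical(change_count(c("A", "A"), c("G", "G", "T", "C")), 0L)
  # exhaustive: all 16 targets x all 192 events against substring counting
  for (i in NUCS) for (j in NUCS) for (l in NUCS) for (k in NUCS) {
    if (j == l) next
    for (dn in DINUC16) {
      b <- change_count(dn, c(i, j, l, k))
      expect_identical(b, as.integer(change_count_oracle(dn, c(i, j, l, k))))
      expect_true(b %in% -2:2)
    }
  }
  expect_error(change_count("AA", c("A", "C", "C", "G")), "middle")
})

test_that("strand-symmetric factor setting updates the paired entry", {
  fv <- factor_vector(kappa = 3, mode = "dna", factors = c("C>T,G" = 12))
  expect_equal(get_factor(fv, "C>T,G"), 12)
  expect_equal(get_factor(fv, "C,G>A"), 12)   # complementary-strand partner
  fv_rna <- factor_vector(kappa = 3, mode = "rna",
                          factors = c("C>T,G" = 12))
  expect_equal(get_factor(fv_rna, "C,G>A"), 1)  # free in RNA mode
})

test_that("composition derivative matches brute-force summation", {
  set.seed(11)
  for (rep in 1:5) {
    d <- random_d()
    fv <- random_fv(mode = "rna", n_active = 3)
    theta <- runif(1, 0.2, 0.8)
    dd <- composition_derivative(d, theta, fv)
    expect_lt(max(abs(dd - deriv_oracle(d, theta, fv))), 1e-12)
    expect_lt(abs(sum(dd)), 1e-12)       # each event destroys 2, creates 2
  }
})

test_that("derivative vanishes at the default-process stationary product", {
  for (theta in c(0.3, 0.55)) for (kappa in c(1, 2.1)) {
    p <- c((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2)
    d <- outer(p, p)
    dd <- composition_derivative(d, theta, factor_vector(kappa = kappa))
    expect_lt(max(abs(dd)), 1e-12)
  }
})

test_that("inconsistent margins are rejected", {
  d <- random_d()
  d[1, 2] <- d[1, 2] + 0.05
  d <- d / sum(d)
  expect_error(composition_derivative(d, 0.5, factor_vector()), "margins")
})

test_that("equilibrium of the context-free model is the independent product", {
  for (kappa in c(1, 2.1, 5)) for (theta in c(0.3, 0.5, 0.7)) {
    eq <- equilibrium(theta, factor_vector(kappa = kappa))
    expect_lt(max(abs(eq$oe - 1)), 1e-8)
    expect_lt(abs(eq$omega - theta), 1e-8)
  }
})

test_that("CpG hypermutation depletes CpG and enriches TpG/CpA equally", {
  fv <- factor_vector(kappa = 3, mode = "dna", factors = c("C>T,G" = 12))
  eq <- equilibrium(0.5, fv)
  expect_lt(eq$oe[["CG"]], 1)
  expect_gt(eq$oe[["TG"]], 1)
  expect_gt(eq$oe[["CA"]], 1)
  expect_equal(eq$oe[["TG"]], eq$oe[["CA"]], tolerance = 1e-9)
})

test_that("equilibrium conserves probability and margin consistency", {
  set.seed(12)
  for (rep in 1:4) {
    fv <- random_fv(mode = "rna", n_active = 2)
    eq <- equilibrium(runif(1, 0.25, 0.75), fv)
    expect_lt(abs(sum(eq$d) - 1), 1e-10)
    expect_lt(max(abs(rowSums(eq$d) - colSums(eq$d))), 1e-9)
    expect_true(all(eq$d >= 0))
    expect_lt(eq$residual, 1e-10)
  }
})

test_that("DNA-mode equilibria are strand-symmetric", {
  set.seed(13)
  for (rep in 1:3) {
    fv <- random_fv(mode = "dna", n_active = 2)
    eq <- equilibrium(runif(1, 0.3, 0.7), fv)
    # d_XY = d_Y'X': reverse both axes (A<->T, C<->G is index reversal)
    expect_lt(max(abs(eq$d - t(eq$d[4:1, 4:1]))), 1e-8)
  }
})

test_that("build_curve of the default model is flat at 1 with omega = theta", {
  cv <- build_curve(factor_vector(kappa = 2),
                    theta_grid = seq(0.2, 0.8, by = 0.05))
  expect_lt(max(abs(cv$M - 1)), 1e-8)
  expect_equal(cv$omega, cv$theta_grid, tolerance = 1e-8)
})

test_that("build_curve validates its grid", {
  fv <- factor_vector()
  expect_error(build_curve(fv, theta_grid = seq(0.2, 0.4, by = 0.05)),
               "at least 10")
  expect_error(build_curve(fv, theta_grid = rep(0.5, 12)), "increasing")
  expect_error(build_curve(fv, theta_grid = seq(0, 0.9, by = 0.05)),
               "inside")
})

test_that("CpG-model curve rises in omega and is grid-converged", {
  fv <- factor_vector(kappa = 3, mode = "dna", factors = c("C>T,G" = 12))
  grid <- seq(0.05, 0.95, by = 0.02)
  cv <- build_curve(fv, grid)
  expect_true(all(diff(cv$M[, "CG"]) > 0))   # CpG o/e increases with G+C
  # halving the grid spacing changes interpolated values by ~1e-3 at most
  # over the fitted G+C span — well below composition sampling noise
  cv2 <- build_curve(fv, seq(0.05, 0.95, by = 0.01))
  probe <- seq(0.2, 0.8, length.out = 100)
  expect_lt(max(abs(predict_curve(cv, probe) - predict_curve(cv2, probe))),
            2e-3)
})

test_that("predict_curve interpolates linearly and refuses extrapolation", {
  fv <- factor_vector(kappa = 3, mode = "dna", factors = c("C>T,G" = 6))
  cv <- build_curve(fv, seq(0.2, 0.8, by = 0.05))
  g <- 4
  expect_equal(predict_curve(cv, cv$omega[g]), cv$M[g, ])
  mid <- (cv$omega[g] + cv$omega[g + 1]) / 2
  expect_equal(predict_curve(cv, mid), (cv$M[g, ] + cv$M[g + 1, ]) / 2,
               tolerance = 1e-12)
  expect_error(predict_curve(cv, 0.05), "outside")
  expect_error(predict_curve(cv, 0.99), "outside")
})

test_that("raising a rate approximates lowering its reverse rate", {
  # f(W>X, Y) = v and f(X>W, Y) = 1/v change the Y-context W<->X rate
  # ratio identically, so they push the equilibrium the same way; the
  # agreement is close for small v and degrades as v grows, because the
  # unchanged competing substitution channels break the exact equivalence
  diffs <- vapply(c(2, 6, 12), function(v) {
    fwd <- factor_vector(kappa = 2, mode = "dna",
                         factors = stats::setNames(v, "C>T,G"))
    rev <- factor_vector(kappa = 2, mode = "dna",
                         factors = stats::setNames(1 / v, "T>C,G"))
    oe_f <- equilibrium(0.5, fwd)$oe
    oe_r <- equilibrium(0.5, rev)$oe
    # same direction of effect wherever the effect is appreciable
    strong <- abs(oe_f - 1) > 0.02
    expect_true(all(sign(oe_f[strong] - 1) == sign(oe_r[strong] - 1)))
    max(abs(oe_f - oe_r))
  }, numeric(1))
  expect_lt(diffs[1], 0.06)              # near-equivalence at v = 2
  expect_true(all(diff(diffs) > 0))      # deviation grows with v
})

test_that("factor vectors round-trip through JSON", {
  fv <- factor_vector(kappa = 2.7, mode = "rna",
                      factors = c("C>T,G" = 9.5, "A,G>C" = 0.3))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_factor_json(fv, path)
  back <- read_factor_json(path)
  expect_equal(back$kappa, fv$kappa)
  expect_equal(back$mode, fv$mode)
  expect_equal(back$up, fv$up)
  expect_equal(back$down, fv$down)
})
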