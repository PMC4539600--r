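test_that("zero state gives basal synthesis only", {
  p <- defaultParameters()
  s <- speciesList()
  expect_equal(auxinReactionRate(s, p),
               unname(param(p, "k_auxin_basal")))
  expect_equal(ethyleneReactionRate(s, p),
               unname(param(p, "k_ET_basal")))
  expect_equal(cytokininReactionRate(s, p, "vascular"),
               unname(param(p, "k_CK_syn")))
  expect_equal(cytokininReactionRate(s, p, "epidermis"), 0)
  expect_equal(aux1ExpressionRates(s, p)$AUX1m,
               unname(param(p, "k_AUX1m_basal")))
})

test_that("negative concentrations are rejected", {
  p <- defaultParameters()
  s <- speciesList(auxin = -1)
  expect_error(auxinReactionRate(s, p), "negative concentration")
})

test_that("cytokinin inhibition of auxin synthesis saturates to a residual", {
  p <- defaultParameters()
  big <- speciesList(CK = 1e9)
  r <- param(p, "r_auxin_CK")
  expect_equal(auxinReactionRate(big, p),
               unname(param(p, "k_auxin_basal") * r), tolerance = 1e-6)
  # monotone non-increasing in CK, non-decreasing in X
  cks <- seq(0, 5, by = 0.25)
  rates <- vapply(cks, function(ck)
    auxinReactionRate(speciesList(CK = ck, X = 0.3), p), numeric(1))
  expect_true(all(diff(rates) <= 0))
  xs <- seq(0, 5, by = 0.25)
  ratesX <- vapply(xs, function(x)
    auxinReactionRate(speciesList(X = x, CK = 0.3), p), numeric(1))
  expect_true(all(diff(ratesX) >= 0))
})

test_that("the alternative cytokinin regulation activates auxin synthesis", {
  p <- setParamFlag(defaultParameters(), "ck_activates_auxin", TRUE)
  rates <- vapply(c(0, 0.5, 2), function(ck)
    auxinReactionRate(speciesList(CK = ck), p), numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("cytokinin synthesis is restricted and auxin-inhibited", {
  p <- defaultParameters()
  # epidermal point: pure decay
  s <- speciesList(CK = 0.7, auxin = 1)
  expect_equal(cytokininReactionRate(s, p, "epidermis"),
               -unname(param(p, "d_CK")) * 0.7)
  # vascular: synthesis strictly decreasing in auxin
  rates <- vapply(seq(0, 3, by = 0.2), function(a)
    cytokininReactionRate(speciesList(auxin = a), p, "vascular"),
    numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("ethylene synthesis is synergistic in auxin and cytokinin and PLS-independent", {
  p <- defaultParameters()
  base <- ethyleneReactionRate(speciesList(auxin = 0.2, CK = 0.2), p)
  upA <- ethyleneReactionRate(speciesList(auxin = 0.4, CK = 0.2), p)
  upC <- ethyleneReactionRate(speciesList(auxin = 0.2, CK = 0.4), p)
  expect_gt(upA, base)
  expect_gt(upC, base)
  withPLS <- ethyleneReactionRate(speciesList(auxin = 0.2, CK = 0.2,
                                              PLSp = 5), p)
  expect_identical(withPLS, base)
})

test_that("random states match the hand-expanded rate formulas", {
  p <- defaultParameters()
  v <- p@values
  set.seed(7)
  for (i in 1:20) {
    s <- speciesList(auxin = runif(1, 0, 3), CK = runif(1, 0, 3),
                     ET = runif(1, 0, 3), X = runif(1, 0, 2),
                     PLSp = runif(1, 0, 2), Ras = runif(1, 0, 1),
                     Ra = runif(1, 0, 1), Re = runif(1, 0, 1),
                     Res = runif(1, 0, 1), CTR1 = runif(1, 0, 1),
                     CTR1s = runif(1, 0, 1), PLSm = runif(1, 0, 1),
                     PINm = runif(1, 0, 1), PINp = runif(1, 0, 1),
                     AUX1m = runif(1, 0, 1), AUX1p = runif(1, 0, 1))
    # independent symbolic re-evaluation, written out in full
    fCK <- v[["r_auxin_CK"]] + (1 - v[["r_auxin_CK"]]) /
      (1 + s$CK / v[["K_auxin_CK"]])
    expect_equal(auxinReactionRate(s, p),
      (v[["k_auxin_basal"]] +
         v[["k_auxin_X"]] * s$X / (v[["K_auxin_X"]] + s$X)) * fCK -
        v[["d_auxin"]] * s$auxin)
    expect_equal(ethyleneReactionRate(s, p),
      v[["k_ET_basal"]] + v[["k_ET_syn"]] *
        (s$auxin / (v[["K_ET_auxin"]] + s$auxin)) *
        (s$CK / (v[["K_ET_CK"]] + s$CK)) - v[["d_ET"]] * s$ET)
    expect_equal(pinExpressionRates(s, p)$PINm,
      v[["k_PINm_basal"]] *
        (1 + v[["a_PINm_auxin"]] * s$auxin / (v[["K_PINm_auxin"]] + s$auxin)) *
        (1 + v[["a_PINm_X"]] * s$X / (v[["K_PINm_X"]] + s$X)) /
        (1 + s$CK / v[["K_PINm_CK"]]) - v[["d_PINm"]] * s$PINm)
    expect_equal(aux1ExpressionRates(s, p)$AUX1m,
      v[["k_AUX1m_basal"]] +
        v[["k_AUX1m_X"]] * s$X / (v[["K_AUX1m_X"]] + s$X) -
        v[["d_AUX1m"]] * s$AUX1m)
    expect_equal(plsExpressionRates(s, p)$PLSm,
      v[["k_PLSm_basal"]] +
        v[["k_PLSm_auxin"]] * (s$Ras / (v[["K_PLSm_Ra"]] + s$Ras)) /
          (1 + s$X / v[["K_PLSm_X"]]) - v[["d_PLSm"]] * s$PLSm)
  }
})

test_that("receptor pairs are conservative over trajectories", {
  p <- defaultParameters()
  rc <- receptorCascadeRates(speciesList(auxin = 1, ET = 0.5, PLSp = 0.3,
                                         Ra = 0.4, Ras = 0.6, Re = 0.7,
                                         Res = 0.3, CTR1 = 0.5,
                                         CTR1s = 0.5, X = 0.2), p)
  expect_equal(rc$Ra + rc$Ras, 0)
  expect_equal(rc$Re + rc$Res, 0)
  expect_equal(rc$CTR1 + rc$CTR1s, 0)
  # pure-cascade integration keeps totals constant
  s <- speciesList(auxin = 0.8, ET = 1.2, PLSp = 0.2, Ra = 0.9, Ras = 0.1,
                   Re = 0.9, Res = 0.1, CTR1 = 0.9, CTR1s = 0.1, X = 0.1)
  dt <- 0.01
  for (k in 1:2000) {
    rc <- receptorCascadeRates(s, p)
    for (nm in names(rc)) s[[nm]] <- s[[nm]] + dt * rc[[nm]]
  }
  expect_equal(s$Ra + s$Ras, 1, tolerance = 1e-10)
  expect_equal(s$Re + s$Res, 1, tolerance = 1e-10)
  expect_equal(s$CTR1 + s$CTR1s, 1, tolerance = 1e-10)
  expect_true(all(unlist(s[c("Ra", "Ras", "Re", "Res", "CTR1", "CTR1s",
                             "X")]) >= 0))
})

test_that("a step increase of ethylene raises steady downstream signalling X", {
  p <- defaultParameters()
  steadyX <- function(et) {
    s <- speciesList(auxin = 0.5, ET = et, PLSp = 0.3, Ra = 0.9, Ras = 0.1,
                     Re = 0.9, Res = 0.1, CTR1 = 0.9, CTR1s = 0.1, X = 0.1)
    dt <- 0.05
    for (k in 1:8000) {
      rc <- receptorCascadeRates(s, p)
      for (nm in names(rc)) s[[nm]] <- s[[nm]] + dt * rc[[nm]]
    }
    s$X
  }
  expect_gt(steadyX(2), steadyX(0.5))
})

test_that("ET=0 with PLS present drives the receptor to its active maximum", {
  p <- defaultParameters()
  s <- speciesList(ET = 0, PLSp = 0.5, Re = 0.5, Res = 0.5)
  rc <- receptorCascadeRates(s, p)
  expect_gt(rc$Res, 0)  # active pool still growing at 50/50
})

test_that("pls knockout and the auxin-regulation ablation behave as specified", {
  p <- applyGenotype(defaultParameters(), "pls")
  s <- speciesList(auxin = 2, Ras = 0.9, X = 0.1, PLSm = 0.4, PLSp = 0.7)
  r <- plsExpressionRates(s, p)
  expect_equal(r$PLSp, -unname(param(p, "d_PLSp")) * 0.7)
  expect_equal(r$PLSm, -unname(param(p, "d_PLSm")) * 0.4)
  # ablation removes the Ra* dependence
  pAbl <- setParamFlag(defaultParameters(), "pls_auxin_regulation_off", TRUE)
  lo <- plsExpressionRates(speciesList(Ras = 0.01), pAbl)$PLSm
  hi <- plsExpressionRates(speciesList(Ras = 0.99), pAbl)$PLSm
  expect_identical(lo, hi)
  # without ablation, transcription at Ras=0 is the basal floor
  r0 <- plsExpressionRates(speciesList(), defaultParameters())$PLSm
  expect_equal(r0, unname(param(defaultParameters(), "k_PLSm_basal")))
})

test_that("PIN transcription responds to CK repression and X elevation", {
  p <- defaultParameters()
  floorRate <- pinExpressionRates(speciesList(CK = 1e9), p)$PINm
  expect_lt(floorRate, pinExpressionRates(speciesList(CK = 0), p)$PINm / 5)
  lowX <- pinExpressionRates(speciesList(X = 0.05, auxin = 0.5, CK = 0.3),
                             p)$PINm
  hiX <- pinExpressionRates(speciesList(X = 1, auxin = 0.5, CK = 0.3),
                            p)$PINm
  expect_gt(hiX, lowX)
})

test_that("AUX1 transcription increases with X to saturation", {
  p <- defaultParameters()
  xs <- c(0, 0.1, 0.5, 2, 10)
  rates <- vapply(xs, function(x)
    aux1ExpressionRates(speciesList(X = x), p)$AUX1m, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[5], unname(param(p, "k_AUX1m_basal") +
                               param(p, "k_AUX1m_X")))
})

test_that("reaction terms at the zero state are non-negative for all species", {
  p <- defaultParameters()
  R <- allReactionRates(speciesList(), p, "vascular")
  expect_true(all(R >= 0))
  R2 <- allReactionRates(speciesList(), p, "epidermis")
  expect_true(all(R2 >= 0))
})

test_that("single-cell steady state: pls raises CK, lowers auxin, leaves ET unchanged", {
  # one boundary cell: the full network plus shoot-side auxin influx
  # (X-repressed), rootward PIN efflux and gas exchange, integrated
  # pointwise to steady state
  singleCell <- function(genotypeName, L = 30) {
    p <- applyGenotype(defaultParameters(), genotypeName)
    v <- p@values
    s <- speciesList(auxin = 0.1, ET = 1, CK = 0.1, PLSm = 0.1, PLSp = 0.1,
                     PINm = 0.1, PINp = 0.1, AUX1m = 0.1, AUX1p = 0.1,
                     Ra = 0.9, Ras = 0.1, Re = 0.9, Res = 0.1,
                     CTR1 = 0.9, CTR1s = 0.1, X = 0.1)
    dt <- 0.05
    for (k in 1:80000) {
      R <- allReactionRates(s, p, "vascular")
      R[, "auxin"] <- R[, "auxin"] +
        v[["I0_auxin"]] / (1 + s$X / v[["K_X_influx"]]) / L -
        v[["P_PIN"]] / L * s$auxin
      R[, "ET"] <- R[, "ET"] +
        v[["k_bnd_ET"]] * (v[["ET_shoot"]] - s$ET) / L
      R[, "CK"] <- R[, "CK"] +
        v[["k_bnd_CK"]] * (v[["CK_shoot"]] - s$CK) / L
      for (nm in colnames(R)) s[[nm]] <- s[[nm]] + dt * R[, nm]
    }
    s
  }
  wt <- singleCell("wt")
  pls <- singleCell("pls")
  expect_lt(abs(pls$ET / wt$ET - 1), 0.01)
  expect_gt(pls$CK, wt$CK)
  expect_lt(pls$auxin, wt$auxin)
})
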