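test_that("PCG solves SPD systems to the requested residual", {
  set.seed(3)
  n <- 60
  B <- Matrix::rsparsematrix(n, n, density = 0.08)
  A <- Matrix::forceSymmetric(Matrix::crossprod(B) + Matrix::Diagonal(n, 1))
  b <- rnorm(n)
  xTrue <- as.numeric(Matrix::solve(A, b))
  # Jacobi preconditioner
  dinv <- 1 / Matrix::diag(A)
  res <- pcgSolve(A, b, tol = 1e-10, maxit = 1000,
                  prec = function(r) dinv * r)
  expect_true(res$converged)
  expect_equal(res$x, xTrue, tolerance = 1e-8)
  # residual actually below tolerance
  expect_lt(sqrt(sum((b - as.numeric(A %*% res$x))^2)) / sqrt(sum(b^2)),
            1e-10)
})

test_that("assembled steady operator has zero residual on a uniform dead state", {
  map <- miniMap()
  p <- closedParams()
  st <- initialState(map, p)
  st@point[, c("auxin", "ET", "CK")] <- 0.4
  sys <- assembleSystem(map, st, p, dt = Inf)
  for (sp in c("auxin", "ET", "CK")) {
    resid <- as.numeric(sys[[sp]]$A %*% st@point[, sp]) - sys[[sp]]$b
    expect_lt(max(abs(resid)), 1e-12)
  }
  expect_error(assembleSystem(map, initialState(miniMap(nMZ = 5), p), p),
               "inconsistent")
})

test_that("operator rows reproduce the hand-assembled five-point stencil", {
  map <- miniMap()
  p <- defaultParameters()
  st <- initialState(map, p)
  sys <- assembleSystem(map, st, p, dt = Inf)
  A <- sys$ET$A
  v <- p@values
  h <- gridSpacing(map)
  nr <- map@dims[1]
  # an interior cytosol point away from the shoot boundary
  i <- regionMask(map, zone = "MZ")[10]
  row <- A[i, ]
  nbrs <- c(i - 1, i + 1, i - nr, i + nr)
  expect_equal(row[i], 4 * v[["D_ET"]] / h^2 + v[["d_ET"]])
  for (j in nbrs) expect_equal(row[j], -v[["D_ET"]] / h^2)
  expect_equal(sum(row != 0), 5)
})

test_that("Picard steady state matches long explicit time integration", {
  map <- miniMap(nMZ = 2, nEZ = 1)
  p <- slowParams()
  st <- steadyCache("mini_slow", function()
    picardSteadyState(map, p, settings = solverSettings()))
  expect_true(st@converged)
  ex <- steadyCache("mini_slow_explicit", function()
    integrateModel(map, p, "wt", tEnd = 4000, dt = 0.05))
  for (sp in colnames(st@state@point)) {
    a <- st@state@point[, sp]; b <- ex@point[, sp]
    scale <- max(abs(a))
    if (scale == 0) next
    expect_lt(max(abs(a - b)) / scale, 1e-3)
  }
  expect_lt(max(abs(st@state@mem - ex@mem)) / max(st@state@mem), 1e-3)
})

test_that("time integration: identity at tEnd = 0 and exponential decay", {
  map <- miniMap()
  p <- applyGenotype(slowParams(), "pls")  # no PLS transcription
  st0 <- initialState(map, p)
  expect_identical(integrateModel(map, p, "wt", tEnd = 0, state = st0)@point,
                   st0@point)
  stT <- integrateModel(map, p, "wt", tEnd = 10, dt = 0.01, state = st0)
  cyt <- which(st0@point[, "PLSm"] > 0)
  expect_equal(stT@point[cyt, "PLSm"],
               st0@point[cyt, "PLSm"] * exp(-unname(param(p, "d_PLSm")) * 10),
               tolerance = 1e-4)
})

test_that("identical inputs give bit-identical steady states", {
  map <- miniMap()
  s <- solverSettings(maxSteps = 40)
  r1 <- picardSteadyState(map, settings = s)
  r2 <- picardSteadyState(map, settings = s)
  expect_identical(r1@state@point, r2@state@point)
  expect_identical(r1@state@mem, r2@state@mem)
})

test_that("steady states are non-negative everywhere and flagged honestly", {
  map <- miniMap()
  res <- miniSteady()
  expect_true(res@converged)
  expect_true(all(res@state@point >= 0))
  expect_true(all(res@state@mem >= 0))
  # membrane pools only on allowed faces
  topo <- rootTopology(map)
  expect_true(all(res@state@mem[!topo$mem$pin, "PINpMem"] == 0))
  # a too-short run reports non-convergence instead of failing silently
  short <- picardSteadyState(map, settings = solverSettings(maxSteps = 3))
  expect_false(short@converged)
})

test_that("halving both solver tolerances leaves the steady state unchanged", {
  base <- miniSteady()
  tight <- steadyCache("mini_tight", function()
    picardSteadyState(miniMap(), settings = solverSettings(
      nonlinearTol = 5e-6, linearTol = 5e-11)))
  for (sp in c("auxin", "ET", "CK", "PINp", "PLSp", "X")) {
    a <- base@state@point[, sp]; b <- tight@state@point[, sp]
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-3)
  }
})

test_that("grid refinement changes region-averaged steady concentrations boundedly", {
  r4 <- miniSteady(spacing = 4)
  r2 <- miniSteady(spacing = 2)
  for (sp in c("auxin", "ET", "CK")) {
    m4 <- regionAverage(r4, sp)
    m2 <- regionAverage(r2, sp)
    expect_lt(abs(m4 - m2) / m2, 0.5)
  }
})

test_that("global mass balance closes at steady state", {
  res <- miniSteady()
  mb <- massBalance(res)
  decaying <- c("auxin", "ET", "CK", "PLSm", "PLSp", "PINm", "PINp",
                "AUX1m", "AUX1p", "X")
  rel <- mb$relative[mb$species %in% decaying]
  expect_true(all(rel < 10 * res@settings@nonlinearTol))
})
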