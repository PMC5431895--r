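test_that("mini-batch k-means is deterministic and near-optimal on small data", {
  set.seed(4)
  X <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
             matrix(rnorm(20, 5, 0.2), 10, 2))
  ## k equal to the number of distinct points: zero inertia
  small <- X[1:6, ]
  cm0 <- fit_minibatch_kmeans(small, k = 6, seed = 1, n_iter = 50)
  expect_equal(cm0$inertia, 0, tolerance = 1e-20)

  ## same seed, same centers; different seed, (generally) different centers
  cm1 <- fit_minibatch_kmeans(X, k = 2, seed = 7)
  cm2 <- fit_minibatch_kmeans(X, k = 2, seed = 7)
  expect_identical(cm1$centers, cm2$centers)

  ## final inertia within 5% of exhaustive Lloyd k-means over 100 restarts
  lloyd <- stats::kmeans(X, centers = 2, nstart = 100)
  expect_lt(cm1$inertia, (lloyd$tot.withinss / nrow(X)) * 1.05)

  expect_error(fit_minibatch_kmeans(matrix(1, 5, 2), k = 2), "distinct")
})

test_that("state assignment is the brute-force nearest-center rule", {
  centers <- matrix(c(0, 0,  1, 0,  0, 1,  2, 2), 4, 2, byrow = TRUE)
  cm <- structure(list(centers = centers, k = 4L, seed = 1L, inertia = 0),
                  class = "cluster_model")
  ## a point equal to center 3 maps to state 3
  expect_equal(assign_states(cm, matrix(c(0, 1), 1)), 3L, ignore_attr = TRUE)
  ## equidistant between centers 1 and 2: the lower index wins
  expect_equal(assign_states(cm, matrix(c(0.5, 0), 1)), 1L, ignore_attr = TRUE)
  ## 100 random points against an explicit O(nk) loop
  set.seed(2)
  P <- matrix(runif(200, -1, 3), 100, 2)
  got <- assign_states(cm, P)
  want <- apply(P, 1, function(p)
    which.min(colSums((t(centers) - p)^2)))
  expect_equal(as.integer(got), as.integer(want))
})

test_that("transition counting is sliding-window and boundary-safe", {
  expect_equal(unname(count_transitions(list(c(1L, 1L, 2L, 2L)), tau = 1,
                                        frame_interval = 1)),
               matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE), ignore_attr = TRUE)
  expect_error(count_transitions(list(c(1L, 2L)), tau = 5, frame_interval = 1),
               "shorter than the MSM lag")
  ## pooled counting never crosses trajectory boundaries
  C2 <- count_transitions(list(c(1L, 2L), c(2L, 1L)), tau = 1, frame_interval = 1)
  expect_equal(unname(C2), matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
  ## random sequence against a brute-force pair loop
  set.seed(6)
  s <- sample.int(4, 500, replace = TRUE)
  C <- count_transitions(list(s), tau = 3, frame_interval = 1, k = 4)
  brute <- matrix(0, 4, 4)
  for (t in 1:(500 - 3)) brute[s[t], s[t + 3]] <- brute[s[t], s[t + 3]] + 1
  expect_equal(unname(C), brute, ignore_attr = TRUE)
})

test_that("ergodic trimming finds the largest strongly connected component", {
  full <- matrix(1, 4, 4)
  expect_equal(largest_connected_set(full), 1:4)
  ## block-diagonal components of sizes 3 and 2: the 3-block wins
  C <- matrix(0, 5, 5)
  C[1:3, 1:3] <- 1; C[4:5, 4:5] <- 1
  expect_equal(suppressMessages(largest_connected_set(C)), 1:3)
  ## random sparse graphs against an independent Tarjan implementation
  set.seed(10)
  for (rep in 1:10) {
    A <- matrix(rbinom(64, 1, 0.2), 8, 8)
    if (all(A == 0)) A[1, 1] <- 1
    comps <- tarjan_scc(A)
    want <- sort(comps[[which.max(lengths(comps))]])
    ## tie-break may differ between implementations; compare sizes, and
    ## membership whenever the largest component is unique
    got <- suppressMessages(largest_connected_set(A))
    sizes <- sort(lengths(comps), decreasing = TRUE)
    expect_equal(length(got), sizes[1])
    if (length(sizes) == 1 || sizes[1] > sizes[2]) expect_equal(got, want)
  }
})

test_that("reversible MLE reproduces closed forms and a likelihood grid search", {
  ## symmetric counts: T is exactly row-normalized C, pi proportional to row sums
  Cs <- matrix(c(6, 2, 3, 2, 8, 1, 3, 1, 4), 3, 3, byrow = TRUE)
  Cs <- (Cs + t(Cs)) / 2
  m <- fit_reversible_msm(Cs, tau = 1)
  expect_equal(unname(m$T), unname(Cs / rowSums(Cs)), tolerance = 1e-9)
  expect_equal(m$pi, rowSums(Cs) / sum(Cs), tolerance = 1e-9)

  ## 2-state count matrix against a nested grid search over the reversible
  ## family T = [[1-a, a], [b, 1-b]] maximizing the count likelihood
  C2 <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE)
  loglik <- function(a, b)
    8 * log(1 - a) + 2 * log(a) + 1 * log(b) + 9 * log(1 - b)
  ctr <- c(0.5, 0.5); width <- 0.5
  for (lvl in 1:8) {
    gr <- seq(-width, width, length.out = 21)
    cand <- expand.grid(a = pmin(pmax(ctr[1] + gr, 1e-6), 1 - 1e-6),
                        b = pmin(pmax(ctr[2] + gr, 1e-6), 1 - 1e-6))
    ll <- mapply(loglik, cand$a, cand$b)
    ctr <- c(cand$a[which.max(ll)], cand$b[which.max(ll)])
    width <- width / 8
  }
  ## NOTE: for 2 states every transition matrix is reversible, so the MLE is
  ## the row-normalized count matrix and the grid search must find it
  m2 <- fit_reversible_msm(C2, tau = 1)
  expect_equal(unname(m2$T[1, 2]), ctr[1], tolerance = 1e-5)
  expect_equal(unname(m2$T[2, 1]), ctr[2], tolerance = 1e-5)
  pi_grid <- c(ctr[2], ctr[1]) / sum(ctr)
  expect_equal(unname(m2$pi), pi_grid, tolerance = 1e-4)
})

test_that("every reversible fit satisfies its structural invariants", {
  set.seed(14)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    C <- matrix(rpois(k * k, 4) + 1, k, k)
    m <- fit_reversible_msm(C, tau = 4.5)
    expect_equal(rowSums(m$T), rep(1, k), tolerance = 1e-12)
    db <- m$pi * m$T - t(m$pi * m$T)
    expect_lt(max(abs(db)), 1e-10)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    expect_equal(max(m$eigenvalues), 1, tolerance = 1e-10)
    expect_lt(max(abs(m$pi %*% m$T - m$pi)), 1e-10)
    expect_true(all(abs(Im(m$eigenvalues)) == 0))
  }
})

test_that("stationary distribution matches long-chain state frequencies", {
  ## generate a long chain from a known reversible matrix, re-estimate
  Tm <- matrix(c(0.90, 0.08, 0.02,
                 0.16, 0.80, 0.04,
                 0.10, 0.10, 0.80), 3, 3, byrow = TRUE)
  pi_true <- Re(eigen(t(Tm))$vectors[, 1]); pi_true <- pi_true / sum(pi_true)
  set.seed(15)
  n <- 60000
  s <- integer(n); s[1] <- 1L
  for (t in 2:n) s[t] <- sample.int(3, 1, prob = Tm[s[t - 1], ])
  m <- build_msm(list(s), tau = 1, frame_interval = 1, k = 3)
  freq <- tabulate(s, 3) / n
  se <- sqrt(pi_true * (1 - pi_true) / (n / 50)) # ~50-step correlation margin
  expect_true(all(abs(m$pi - freq) < 3 * se))
})

test_that("implied timescales reproduce the analytic two-state result", {
  a <- 0.15; b <- 0.05
  pi2 <- c(b, a) / (a + b)
  ## exact balanced counts: C_ij = pi_i T_ij (scaled); the MLE returns T itself
  Tm <- matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE)
  C <- diag(pi2) %*% Tm * 1000
  m <- fit_reversible_msm(C, tau = 4.5)
  expect_equal(implied_timescales(m, 1), -4.5 / log(1 - a - b), tolerance = 1e-10)

  ## lambda_2 = exp(-1) at tau = 4.5 gives exactly 4.5 ns
  lam <- exp(-1)
  a2 <- (1 - lam) / 2
  C2 <- diag(c(0.5, 0.5)) %*% matrix(c(1 - a2, a2, a2, 1 - a2), 2, byrow = TRUE) * 1000
  m2 <- fit_reversible_msm(C2, tau = 4.5)
  expect_equal(implied_timescales(m2, 1), 4.5, tolerance = 1e-10)
})

test_that("timescales are stable across lags once the model is Markovian", {
  cvs <- sample_langevin(small_two_well(seed = 61, n_trajectories = 40L,
                                        frames_per_trajectory = 300L))
  fit <- cv_msm_fit(cvs, k = 15)
  t_tau <- implied_timescales(fit$msm, 1)
  for (mult in 2:3) {
    m2 <- build_msm(fit$states, tau = 4.5 * mult, frame_interval = 0.5, k = 15)
    expect_equal(implied_timescales(m2, 1), t_tau, tolerance = 0.35)
  }
})
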