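test_that("agent encoding dimension and round trip follow the class-major layout", {
  cfg <- coa_config(A = 4L, n_c = 2L, y_d = 2L)
  expect_equal(cfg$dim, 16L)
  expect_equal(coa_config(A = 1L, n_c = 1L, y_d = 2L)$dim, 2L)

  set.seed(3)
  pos <- runif(16)
  p <- decode_agent(pos, cfg)
  expect_equal(dim(p$prototypes), c(4L, 4L))
  expect_equal(p$labels, c(1L, 1L, 0L, 0L))           # positive block first
  expect_equal(p$prototypes[1L, ], pos[1:4])          # new-case-major within class
  expect_equal(encode_prototypes(p, cfg), pos)        # decode . encode = identity
  expect_error(decode_agent(runif(15), cfg), "Dim")
})

test_that("agent fitness is the fraction of training cases its New-cases diagnose", {
  cfg <- coa_config(A = 2L, n_c = 2L, y_d = 2L, k = 1L)
  # prototypes placed exactly on the training cases -> every case recovered
  train_w <- rbind(c(0.9, 0.8), c(0.85, 0.9), c(0.1, 0.2), c(0.15, 0.1))
  labels <- c(1L, 1L, 0L, 0L)
  expect_equal(eval_agent(as.vector(t(train_w)), train_w, labels, cfg), 1)
  # 3 of 4 correct -> 0.75
  labels_off <- c(1L, 0L, 0L, 0L)
  expect_equal(eval_agent(as.vector(t(train_w)), train_w, labels_off, cfg), 0.75)
  # k larger than the prototype count is clipped with a warning
  cfg_big_k <- coa_config(A = 2L, n_c = 2L, y_d = 2L, k = 9L)
  expect_warning(eval_agent(as.vector(t(train_w)), train_w, labels, cfg_big_k),
                 "clipped")
})

test_that("agent fitness agrees with a scalar brute-force oracle on random instances", {
  set.seed(14)
  for (rep in 1:200) {
    A <- sample(1:4, 1)
    n_c <- sample(1:3, 1)
    k <- sample(1:3, 1)
    q <- sample((2 * n_c + 1):12, 1)
    cfg <- coa_config(A = A, n_c = n_c, y_d = 2L, k = k)
    pos <- runif(cfg$dim)
    train_w <- matrix(runif(q * A), ncol = A)
    labels <- sample(c(0L, 1L), q, replace = TRUE)
    expect_equal(suppressWarnings(eval_agent(pos, train_w, labels, cfg)),
                 brute_eval_agent(pos, train_w, labels, A, n_c, k))
  }
})

test_that("the control coefficient decays linearly from 2 to 0 with reflection symmetry", {
  expect_equal(compute_fc(0, 100), 2)
  expect_equal(compute_fc(100, 100), 0)
  expect_equal(compute_fc(50, 100), 1)
  for (itr in 0:100) {
    expect_equal(compute_fc(itr, 100) + compute_fc(100 - itr, 100), 2)
  }
  expect_error(compute_fc(-1, 100), "itr")
  expect_error(compute_fc(101, 100), "itr")
})

test_that("dynamic coefficients match their printed closed forms", {
  ones <- rep(1, 8)
  at_end <- compute_dynamic_coeffs(100, 100, ones)
  expect_equal(unname(at_end$k["k2g2"]), 2.5)     # cubic ratio cancels at itr = max
  expect_equal(unname(at_end$k["k1g3"]), -1.5)    # -3 + 1.5
  expect_equal(unname(at_end$k["k1g1"]), 0.58742, tolerance = 1e-5)
  expect_equal(unname(at_end$k["k1g4"]), -1.5)
  expect_equal(unname(at_end$k["k2g1"]), 2.5)

  at_zero <- compute_dynamic_coeffs(0, 100, ones)
  expect_equal(unname(at_zero$k["k1g1"]), 1.95)
  expect_equal(unname(at_zero$k["k2g2"]), 0.5)

  # rc values scale the injected uniforms by the k coefficients
  draws <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  rc <- compute_dynamic_coeffs(25, 100, draws)
  expect_equal(rc$rc11, unname(rc$k["k1g1"]) * 0.1)
  expect_equal(rc$rc42, unname(rc$k["k2g4"]) * 0.8)
  expect_error(compute_dynamic_coeffs(25, 100, rep(2, 8)), "in \\[0, 1\\]")
})

test_that("attack and encircling coefficients follow their definitions", {
  expect_equal(compute_ac_cc(2, 0.5, 0.5), list(ac = 0, cc = 1))
  expect_equal(compute_ac_cc(1, 1, 0.25)$ac, 1)
  set.seed(5)
  for (i in 1:50) {
    fc <- runif(1, 0, 2); rc1 <- runif(1, 0, 2); rc2 <- runif(1, 0, 2)
    out <- compute_ac_cc(fc, rc1, rc2)
    expect_gte(out$ac, 0)
    expect_gte(out$cc, 0)
    expect_equal(out$ac, fc * abs(2 * rc1 - 1))   # equivalent factored form
  }
})

test_that("the chaotic quadratic map stays inside [0, 1] on normalized positions", {
  b <- list(lo = 0, hi = 1)
  expect_equal(compute_mc(1, b), 0)    # s = 1, u = 1
  expect_equal(compute_mc(0, b), 1)    # s = 0, u = 1
  set.seed(6)
  pos <- runif(10000, min = -2, max = 5)
  mc <- compute_mc(pos, list(lo = -2, hi = 5))
  expect_true(all(mc >= 0 & mc <= 1))
  expect_equal(compute_mc(3, list(lo = 3, hi = 3)), 0)  # degenerate bounds
})

test_that("leader candidates reduce to the leaders when the attack term vanishes", {
  set.seed(7)
  dim <- 6L
  leaders <- lapply(1:4, function(i) runif(dim))
  pos <- runif(dim)
  coeffs <- list(ac = rep(0, 4), cc = runif(4), mc = runif(dim))
  cand <- leader_candidates(pos, leaders, coeffs)
  for (kk in 1:4) expect_equal(cand[[kk]], leaders[[kk]])

  p <- runif(dim)
  same <- lapply(1:4, function(i) p)
  cand2 <- leader_candidates(pos, same, coeffs)
  expect_equal(Reduce(`+`, cand2) / 4, p)
})

test_that("leader candidates match a per-dimension scalar oracle", {
  set.seed(8)
  for (rep in 1:50) {
    dim <- sample(1:8, 1)
    leaders <- lapply(1:4, function(i) runif(dim, -1, 2))
    pos <- runif(dim, -1, 2)
    coeffs <- list(ac = runif(4, 0, 2), cc = runif(4, 0, 2), mc = runif(dim))
    cand <- leader_candidates(pos, leaders, coeffs)
    for (kk in 1:4) {
      for (d in seq_len(dim)) {
        dist <- abs(coeffs$cc[kk] * leaders[[kk]][d] - coeffs$mc[d] * pos[d])
        expect_equal(cand[[kk]][d], leaders[[kk]][d] - coeffs$ac[kk] * dist)
      }
    }
  }
})

test_that("position updates take the leader mean or the chaotic relocation by the z gate", {
  dim <- 4L
  b <- list(lo = rep(0, dim), hi = rep(1, dim))
  p <- rep(0.25, dim)
  same <- lapply(1:4, function(i) p)
  coeffs <- list(ac = rep(0, 4), cc = rep(1, 4), mc = rep(0.5, dim), z = 0.3)
  expect_equal(position_update(runif(dim), same, coeffs, b), p)

  # z >= 0.5 at the upper bound with u = 1: mc = 0 -> relocated to the lower bound
  at_hi <- rep(1, dim)
  coeffs2 <- list(ac = rep(0, 4), cc = rep(1, 4),
                  mc = compute_mc(at_hi, b), z = 0.9)
  expect_equal(position_update(at_hi, same, coeffs2, b), rep(0, dim))

  # the gate threshold sits at 0.5
  set.seed(9)
  chaotic <- 0L
  n_draws <- 2000L
  for (i in seq_len(n_draws)) {
    z <- runif(1)
    cf <- list(ac = rep(0, 4), cc = rep(1, 4), mc = rep(0.123, dim), z = z)
    out <- position_update(at_hi, same, cf, b)
    took_chaotic <- isTRUE(all.equal(out, rep(0.123, dim)))
    expect_equal(took_chaotic, z >= 0.5)
    chaotic <- chaotic + took_chaotic
  }
  expect_gt(chaotic / n_draws, 0.45)
  expect_lt(chaotic / n_draws, 0.55)
})

test_that("prototype generation converges on separable clouds and stays in bounds", {
  d <- make_separable(n_per = 25L, p = 2L, gap = 5, seed = 10L)
  w <- fit_weighting(d)
  train_w <- to_weight_space(w, d)
  cfg <- coa_config(A = ncol(train_w), n_c = 2L, k = 3L, seed = 77L)
  ps <- run_coa(train_w, d$labels, cfg)
  expect_gte(attr(ps, "fitness"), 0.95)
  history <- attr(ps, "history")
  expect_equal(length(history), 101L)
  expect_true(all(diff(history) >= 0))              # attacker never worsens
  expect_true(all(ps$prototypes >= 0 & ps$prototypes <= 1))

  # the prototype set must shrink the training data
  cfg_big <- coa_config(A = ncol(train_w), n_c = 25L, k = 3L, seed = 77L)
  expect_error(run_coa(train_w, d$labels, cfg_big), "must be < Q")

  ps2 <- run_coa(train_w, d$labels, cfg)
  expect_identical(ps$prototypes, ps2$prototypes)   # seeded determinism
})

test_that("one prototype per class separates two point clouds at k = 1", {
  d <- make_separable(n_per = 12L, p = 2L, gap = 6, seed = 12L)
  w <- fit_weighting(d)
  train_w <- to_weight_space(w, d)
  cfg <- coa_config(A = ncol(train_w), n_c = 1L, k = 1L,
                    max_iter = 50L, seed = 13L)
  ps <- run_coa(train_w, d$labels, cfg)
  holdout <- make_separable(n_per = 1L, p = 2L, gap = 6, seed = 99L)
  hw <- to_weight_space(w, holdout)
  pred <- brute_knn(ps$prototypes, ps$labels, hw, k = 1L)
  expect_equal(pred, holdout$labels)
})
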