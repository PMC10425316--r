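#' Configuration for chimp-optimization prototype generation
#'
#' The chimp optimization algorithm (COA) searches for a small artificial
#' training set ("New-cases") in weight space. Each search agent (chimp) is a
#' real vector of length `Dim = A * n_c * y_d` encoding, class block by class
#' block, `n_c` New-cases of `A` weight-space coordinates for each of the
#' `y_d` classes. The four fittest agents — attacker, barrier, chaser and
#' driver — steer every position update.
#'
#' @param A number of weight-space coordinates per New-case (set from the
#'   data at fit time: twice the feature count).
#' @param n_c number of New-cases generated per class.
#' @param y_d number of classes; 2 for the case/control problem.
#' @param k neighbor count used inside the fitness evaluation. Default 3.
#' @param population_size number of chimps, at least 4 (the four leader
#'   roles). Default 20.
#' @param max_iter maximum number of iterations. Default 100.
#' @param u quadratic-map constant of the chaotic term. Default 1.
#' @param bounds list with numeric vectors `lo` and `hi` of length `Dim` (or
#'   length 1, recycled). Defaults to `[0, 1]`, the range of the
#'   naive-Bayes weight space.
#' @param seed optional integer seed applied at the start of [run_coa()].
#' @return An object of class `coa_config`; `$dim` holds `A * n_c * y_d`.
#' @export
coa_config <- function(A, n_c, y_d = 2L, k = 3L, population_size = 20L,
                       max_iter = 100L, u = 1, bounds = NULL, seed = NULL) {
  if (!is_count(A) || !is_count(n_c) || !is_count(y_d)) {
    stopf("A, n_c and y_d must be positive integers")
  }
  if (!is_count(population_size, 4L)) {
    stopf("population_size must be >= 4 (attacker, barrier, chaser, driver)")
  }
  if (!is_count(max_iter)) stopf("max_iter must be a positive integer")
  if (!is_count(k)) stopf("k must be a positive integer")
  dim <- as.integer(A * n_c * y_d)
  lo <- rep_len(bounds$lo %||% 0, dim)
  hi <- rep_len(bounds$hi %||% 1, dim)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi < lo)) {
    stopf("bounds must be finite with hi >= lo")
  }
  structure(
    list(A = as.integer(A), n_c = as.integer(n_c), y_d = as.integer(y_d),
         k = as.integer(k), population_size = as.integer(population_size),
         max_iter = as.integer(max_iter), u = u,
         bounds = list(lo = lo, hi = hi), seed = seed, dim = dim),
    class = "coa_config"
  )
}

#' Decode a chimp position into a prototype set
#'
#' The position vector is laid out class-major: all New-cases of class 1
#' (positive block first), then all New-cases of class 2, each New-case
#' contributing `A` consecutive coordinates.
#'
#' @param position numeric vector of length `cfg$dim`.
#' @param cfg a [coa_config()].
#' @param classes integer labels of the class blocks, positive class first by
#'   default.
#' @return An object of class `prototype_set`: matrix `prototypes`
#'   (`n_c * y_d` rows x `A` columns), integer `labels` per row, and the
#'   layout constants.
#' @export
decode_agent <- function(position, cfg, classes = c(1L, 0L)) {
  stopifnot(inherits(cfg, "coa_config"))
  if (length(position) != cfg$dim) {
    stopf("position length %d != Dim = %d", length(position), cfg$dim)
  }
  if (length(classes) != cfg$y_d) stopf("need %d class labels", cfg$y_d)
  proto <- matrix(position, ncol = cfg$A, byrow = TRUE)
  labels <- rep(as.integer(classes), each = cfg$n_c)
  structure(list(prototypes = proto, labels = labels, A = cfg$A,
                 n_c = cfg$n_c, classes = as.integer(classes)),
            class = "prototype_set")
}

#' Encode a prototype set back into a chimp position
#'
#' Inverse of [decode_agent()]: `encode_prototypes(decode_agent(x, cfg), cfg)`
#' returns `x`.
#'
#' @param p a `prototype_set`.
#' @param cfg a [coa_config()].
#' @return Numeric position vector of length `cfg$dim`.
#' @export
encode_prototypes <- function(p, cfg) {
  stopifnot(inherits(p, "prototype_set"), inherits(cfg, "coa_config"))
  pos <- as.vector(t(p$prototypes))
  if (length(pos) != cfg$dim) stopf("prototype set does not match Dim = %d", cfg$dim)
  pos
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> %d New-cases (%d per class x %d classes), %d coordinates each\n",
              nrow(x$prototypes), x$n_c, length(x$classes), x$A))
  invisible(x)
}

#' Evaluate a chimp: training accuracy of KNN over its New-cases
#'
#' The fitness of an agent is the fraction of training cases whose class is
#' recovered by a K-nearest-neighbor vote over the agent's decoded
#' New-cases (Euclidean distance in weight space): the mean of the 0/1
#' per-case correctness indicator over all `Q` training cases.
#'
#' @param position numeric position vector of length `cfg$dim`.
#' @param train_w weight-space training matrix (`Q` rows).
#' @param train_labels integer 0/1 labels of the training cases.
#' @param cfg a [coa_config()]; `cfg$k` neighbors are used, clipped (with a
#'   warning) to the number of New-cases when it exceeds it.
#' @return Fitness in `[0, 1]`.
#' @export
eval_agent <- function(position, train_w, train_labels, cfg) {
  p <- decode_agent(position, cfg)
  v <- nrow(p$prototypes)
  k <- cfg$k
  if (k > v) {
    warnf("k = %d exceeds the %d New-cases; clipped", k, v)
    k <- v
  }
  pred <- knn_predict(p$prototypes, p$labels, train_w, k)
  mean(pred == train_labels)
}

#' Linearly decaying control coefficient
#'
#' `fc = 2 - 2 * (itr / max_itr)`: 2 at the first iteration, 0 at the last,
#' linear in between. Satisfies the reflection identity
#' `fc(itr) + fc(max_itr - itr) = 2`.
#'
#' @param itr current iteration, in `[0, max_itr]`.
#' @param max_itr maximum iteration count (positive).
#' @return Value in `[0, 2]`.
#' @export
compute_fc <- function(itr, max_itr) {
  if (!is.numeric(max_itr) || max_itr <= 0) stopf("max_itr must be positive")
  if (itr < 0 || itr > max_itr) stopf("itr must lie in [0, max_itr]")
  2 - 2 * (itr / max_itr)
}

#' Dynamic random factors of the four leader groups
#'
#' Computes the eight dynamic coefficients `k1g1..k2g4` at the given
#' iteration and scales the eight supplied uniform draws by them, yielding
#' the random factors `rc11, rc12, ..., rc41, rc42` (one `rc_k1`/`rc_k2`
#' pair per leader). The coefficient schedules are intentionally
#' heterogeneous across the four groups — quarter- and third-power decays for
#' the early groups, cubic ramps for the later ones — and are implemented
#' exactly in that printed form.
#'
#' @param itr current iteration in `[0, max_itr]`.
#' @param max_itr maximum iteration count (positive).
#' @param draws numeric vector of 8 uniforms in `[0, 1]`, consumed in the
#'   order `rc11, rc12, rc21, rc22, rc31, rc32, rc41, rc42`.
#' @return Named list with `rc11..rc42` and the underlying `k` coefficients.
#' @export
compute_dynamic_coeffs <- function(itr, max_itr, draws) {
  if (!is.numeric(max_itr) || max_itr <= 0) stopf("max_itr must be positive")
  if (length(draws) != 8L || any(draws < 0 | draws > 1)) {
    stopf("draws must be 8 values in [0, 1]")
  }
  r <- itr / max_itr
  k1g1 <- 1.95 - 2 * itr^(1 / 4) / max_itr^(1 / 3)
  k2g1 <- 2 * itr^(1 / 3) / max_itr^(1 / 3) + 0.5
  k1g2 <- 1.95 - 2 * itr^(1 / 3) / max_itr^(1 / 4)
  k2g2 <- 2 * r^3 + 0.5
  k1g3 <- -3 * r^3 + 1.5
  k2g3 <- 2 * itr^(1 / 3) / max_itr^(1 / 3) + 0.5
  k1g4 <- -2 * r^3 + 0.5
  k2g4 <- 2 * r^3 + 0.5
  list(rc11 = k1g1 * draws[1L], rc12 = k2g1 * draws[2L],
       rc21 = k1g2 * draws[3L], rc22 = k2g2 * draws[4L],
       rc31 = k1g3 * draws[5L], rc32 = k2g3 * draws[6L],
       rc41 = k1g4 * draws[7L], rc42 = k2g4 * draws[8L],
       k = c(k1g1 = k1g1, k2g1 = k2g1, k1g2 = k1g2, k2g2 = k2g2,
             k1g3 = k1g3, k2g3 = k2g3, k1g4 = k1g4, k2g4 = k2g4))
}

#' Attack and encircling coefficients of one leader
#'
#' `Ac = |2 * fc * rc1 - fc|` and `Cc = 2 * rc2`; both non-negative.
#'
#' @param fc control coefficient from [compute_fc()].
#' @param rc1,rc2 random factors for this leader.
#' @return List with `ac` and `cc`.
#' @export
compute_ac_cc <- function(fc, rc1, rc2) {
  list(ac = abs(2 * fc * rc1 - fc), cc = 2 * rc2)
}

#' Chaotic (quadratic-map) vector of an agent
#'
#' The agent's position is normalized per dimension to `s = (x - lo) /
#' (hi - lo)` and the chaotic value is `mc = |s^2 - u|`, which for `u = 1`
#' and in-bounds positions is guaranteed to lie in `[0, 1]`. Degenerate
#' dimensions (`hi == lo`) yield 0.
#'
#' @param position numeric position vector.
#' @param bounds list with `lo` and `hi` vectors.
#' @param u quadratic-map constant, default 1.
#' @return Numeric vector of per-dimension chaotic values.
#' @export
compute_mc <- function(position, bounds, u = 1) {
  lo <- rep_len(bounds$lo, length(position))
  hi <- rep_len(bounds$hi, length(position))
  span <- hi - lo
  s <- ifelse(span > 0, (position - lo) / span, 0)
  ifelse(span > 0, abs(s^2 - u), 0)
}

#' Candidate positions driven by the four leaders
#'
#' For leader `k` with coefficients `ac_k`, `cc_k`:
#' `D_k = |cc_k * leader_k - mc * x|` and `candidate_k = leader_k - ac_k *
#' D_k`, evaluated element-wise with the agent's chaotic vector `mc`.
#' Candidates are not yet clipped to bounds.
#'
#' @param position the agent's current position vector.
#' @param leaders list of four position vectors (attacker, barrier, chaser,
#'   driver).
#' @param coeffs list with numeric vectors `ac` and `cc` of length 4 and the
#'   chaotic vector `mc`.
#' @return A list of four candidate position vectors.
#' @export
leader_candidates <- function(position, leaders, coeffs) {
  stopifnot(length(leaders) == 4L, length(coeffs$ac) == 4L,
            length(coeffs$cc) == 4L)
  lapply(1:4, function(kk) {
    d <- abs(coeffs$cc[kk] * leaders[[kk]] - coeffs$mc * position)
    leaders[[kk]] - coeffs$ac[kk] * d
  })
}

#' One position update
#'
#' With probability 1/2 (gate `z < 0.5`) the agent moves to the mean of the
#' four leader candidates; otherwise it is chaotically relocated, each
#' dimension mapped back from its chaotic value: `x_d = lo + mc_d *
#' (hi - lo)`. The result is clipped to bounds.
#'
#' @param position current position vector.
#' @param leaders list of the four leader positions.
#' @param coeffs list with `ac`, `cc` (length-4), `mc` (per-dimension) and
#'   scalar `z` in `[0, 1]`.
#' @param bounds list with `lo` and `hi`.
#' @return Updated, in-bounds position vector.
#' @export
position_update <- function(position, leaders, coeffs, bounds) {
  lo <- rep_len(bounds$lo, length(position))
  hi <- rep_len(bounds$hi, length(position))
  new <- if (coeffs$z < 0.5) {
    cand <- leader_candidates(position, leaders, coeffs)
    (cand[[1L]] + cand[[2L]] + cand[[3L]] + cand[[4L]]) / 4
  } else {
    lo + coeffs$mc * (hi - lo)
  }
  clip(new, lo, hi)
}

# Draw one CoefficientBundle for an agent at iteration itr.
draw_coeffs <- function(position, itr, max_itr, bounds, u) {
  fc <- compute_fc(itr, max_itr)
  rc <- compute_dynamic_coeffs(itr, max_itr, stats::runif(8L))
  ac <- cc <- numeric(4L)
  for (kk in 1:4) {
    acc <- compute_ac_cc(fc, rc[[2L * kk - 1L]], rc[[2L * kk]])
    ac[kk] <- acc$ac
    cc[kk] <- acc$cc
  }
  list(fc = fc, ac = ac, cc = cc,
       mc = compute_mc(position, bounds, u), z = stats::runif(1L))
}

#' Run chimp-optimization prototype generation
#'
#' Initializes a population of agents uniformly within bounds, evaluates each
#' with [eval_agent()], assigns the four fittest as attacker, barrier, chaser
#' and driver, then iterates: per non-leader agent a fresh coefficient bundle
#' is drawn and its position updated via [position_update()]; leaders are
#' replaced only by strictly fitter agents (elitist), so the attacker's
#' fitness never decreases. After `max_iter` iterations the attacker's
#' decoded New-cases are returned.
#'
#' @param train_w weight-space training matrix (`Q` rows).
#' @param train_labels integer 0/1 labels, length `Q`.
#' @param cfg a [coa_config()]; `n_c * y_d` must be strictly smaller than `Q`
#'   (the prototype set must shrink the training data).
#' @return A `prototype_set` (see [decode_agent()]) with attributes
#'   `fitness` (the attacker's final fitness) and `history` (best fitness per
#'   iteration, length `max_iter + 1`).
#' @export
run_coa <- function(train_w, train_labels, cfg) {
  stopifnot(inherits(cfg, "coa_config"))
  train_w <- as.matrix(train_w)
  q <- nrow(train_w)
  if (q < 1L) stopf("empty training set")
  v <- cfg$n_c * cfg$y_d
  if (v >= q) {
    stopf("n_c * y_d = %d New-cases must be < Q = %d training cases", v, q)
  }
  if (ncol(train_w) != cfg$A) {
    stopf("training data has %d weight coordinates; cfg$A = %d",
          ncol(train_w), cfg$A)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lo <- cfg$bounds$lo
  hi <- cfg$bounds$hi
  n <- cfg$population_size
  pop <- matrix(stats::runif(n * cfg$dim, rep(lo, each = n), rep(hi, each = n)),
                nrow = n)
  fit <- vapply(seq_len(n), function(i) {
    eval_agent(pop[i, ], train_w, train_labels, cfg)
  }, numeric(1L))
  # fitness-ordered best four; ties broken by agent index (stable). Leaders
  # are kept as elite copies outside the population: every population agent
  # keeps moving while the leader positions change only by replacement.
  leader_idx <- order(-fit, seq_len(n))[1:4]
  leaders <- lapply(leader_idx, function(i) pop[i, ])
  leader_fit <- fit[leader_idx]
  history <- numeric(cfg$max_iter + 1L)
  history[1L] <- leader_fit[1L]

  for (itr in seq_len(cfg$max_iter)) {
    for (i in seq_len(n)) {
      coeffs <- draw_coeffs(pop[i, ], itr, cfg$max_iter, cfg$bounds, cfg$u)
      pop[i, ] <- position_update(pop[i, ], leaders, coeffs, cfg$bounds)
      fit[i] <- eval_agent(pop[i, ], train_w, train_labels, cfg)
      # elitist leader update: promote only strictly fitter agents
      for (r in 1:4) {
        if (fit[i] > leader_fit[r]) {
          if (r < 4L) {
            leaders[(r + 1L):4L] <- leaders[r:3L]
            leader_fit[(r + 1L):4L] <- leader_fit[r:3L]
          }
          leaders[[r]] <- pop[i, ]
          leader_fit[r] <- fit[i]
          break
        }
      }
    }
    history[itr + 1L] <- leader_fit[1L]
  }
  out <- decode_agent(leaders[[1L]], cfg)
  attr(out, "fitness") <- leader_fit[1L]
  attr(out, "history") <- history
  out
}
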