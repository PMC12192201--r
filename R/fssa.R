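# Fuzzy salp swarm algorithm: a bound-constrained population metaheuristic
# (minimization convention). The run is split into two halves: the first
# half explores with an encircling update around the best-known position
# plus a Gaussian-fuzzy-membership step toward it; the second half is the
# classical salp chain (leader perturbs the food source, followers move to
# pairwise midpoints). Greedy selection keeps a move only when it improves,
# the control parameter c1 decays linearly within [c_min, c_max], and the
# population shrinks linearly from n_max to n_min by discarding the worst
# salps.

#' FSSA configuration
#'
#' @param nMax,nMin maximum / minimum population size (the population
#'   shrinks linearly from `nMax` to `nMin` over the run).
#' @param TMax number of iterations (>= 2).
#' @param cMax,cMin bounds of the control variable c1 (defaults 0.95 /
#'   0.05).
#' @param gfmShape exponent m of the Gaussian fuzzy membership function
#'   (default 2).
#' @param c1Schedule `"linear"` (default: `cMax` decaying to `cMin`) or
#'   `"exp"` (the classical salp decay `2*exp(-(4t/TMax)^2)`).
#' @param explorationPhase run the encircling/fuzzy first half (default
#'   TRUE); FALSE runs the classical salp chain throughout.
#' @param adaptPopulation shrink the population over iterations (default
#'   TRUE).
#' @param resortChain re-sort salps by fitness each iteration before the
#'   chain update (default FALSE: chain order = current array order).
#' @param seed RNG seed.
#' @return A validated config list.
#' @export
fssaConfig <- function(nMax = 30, nMin = 10, TMax = 200, cMax = 0.95,
                       cMin = 0.05, gfmShape = 2, c1Schedule = c("linear", "exp"),
                       explorationPhase = TRUE, adaptPopulation = TRUE,
                       resortChain = FALSE, seed = 1) {
  c1Schedule <- match.arg(c1Schedule)
  if (nMin > nMax) stopf("nMin must be <= nMax")
  if (nMin < 2) stopf("population must keep at least 2 salps")
  if (!(cMin > 0 && cMin < cMax && cMax < 1)) stopf("need 0 < cMin < cMax < 1")
  if (TMax < 2) stopf("TMax must be >= 2")
  list(nMax = as.integer(nMax), nMin = as.integer(nMin), TMax = as.integer(TMax),
       cMax = cMax, cMin = cMin, gfmShape = gfmShape, c1Schedule = c1Schedule,
       explorationPhase = isTRUE(explorationPhase),
       adaptPopulation = isTRUE(adaptPopulation),
       resortChain = isTRUE(resortChain), seed = seed)
}

#' Initialize a salp population uniformly within bounds
#'
#' Positions are `lb + U(0,1) * (ub - lb)` element-wise.
#'
#' @param n population size (>= 2).
#' @param lb,ub numeric(d) bounds with `lb < ub` component-wise.
#' @param seed optional seed (NULL draws from the current RNG state).
#' @return list(positions = n x d matrix, fitness = numeric(n) of NA,
#'   food = NULL, foodFitness = Inf, lb, ub).
#' @export
initializePopulation <- function(n, lb, ub, seed = NULL) {
  if (length(lb) != length(ub)) stopf("lb and ub must have equal length")
  if (any(lb >= ub)) stopf("need lb < ub on every axis")
  if (n < 2) stopf("population size must be >= 2")
  d <- length(lb)
  pos <- withSeed(seed, matrix(runif(n * d), n, d))
  pos <- sweep(sweep(pos, 2, ub - lb, "*"), 2, lb, "+")
  list(positions = pos, fitness = rep(NA_real_, n),
       food = NULL, foodFitness = Inf, lb = lb, ub = ub)
}

#' Classical salp leader decay coefficient
#'
#' `c1(t) = 2 * exp(-(4 t / TMax)^2)`: 2 at t = 0, ~2.3e-7 at t = TMax,
#' strictly decreasing.
#'
#' @param t iteration (0..TMax).
#' @param TMax maximum iterations.
#' @return Scalar coefficient.
#' @export
c1Decay <- function(t, TMax) 2 * exp(-(4 * t / TMax)^2)

#' Leader position update
#'
#' Per dimension j, with fresh `C2, C3 ~ U(0,1)`:
#' `X_j = F_j + c1*((ub_j - lb_j)*C2 + lb_j)` when `C3 >= 0.5`, the minus
#' branch otherwise; clamped to the bounds.
#'
#' @param pop population list with evaluated `food`.
#' @param c1 control coefficient.
#' @return Numeric(d) new leader position.
#' @export
leaderUpdate <- function(pop, c1) {
  if (is.null(pop$food)) stopf("population has no evaluated food source")
  d <- length(pop$food)
  C2 <- runif(d); C3 <- runif(d)
  step <- c1 * ((pop$ub - pop$lb) * C2 + pop$lb)
  x <- ifelse(C3 >= 0.5, pop$food + step, pop$food - step)
  clampBox(x, pop$lb, pop$ub)
}

#' Follower chain update
#'
#' Each follower i >= 2 moves to the midpoint of itself and its
#' predecessor, applied sequentially from i = 2 upward (so each follower
#' chases its predecessor's already-updated position); clamped.
#'
#' @param positions n x d matrix (row 1 = leader, untouched).
#' @param lb,ub bounds.
#' @return Updated matrix.
#' @export
followerUpdate <- function(positions, lb, ub) {
  for (i in seq_len(nrow(positions))[-1])
    positions[i, ] <- clampBox((positions[i, ] + positions[i - 1, ]) / 2, lb, ub)
  positions
}

#' Encircling exploration update
#'
#' Three candidate points around the best-known position, averaged:
#' `x_k = x_best - A_k * |C_k * x_best - x_i|` with `A_k = 2*a*r1 - a`,
#' `C_k = 2*r2` (fresh `r1, r2 ~ U(0,1)` per term and per dimension), where
#' `a(t)` decreases linearly from 2 to 0 over the full run. Candidate =
#' `(x1 + x2 + x3)/3`, clamped.
#'
#' @param xi current position (numeric(d)).
#' @param xbest best-known position.
#' @param t iteration; `a = 2 * (1 - t/TMax)`.
#' @param TMax maximum iterations.
#' @param lb,ub bounds.
#' @return Candidate position.
#' @export
explorationUpdate <- function(xi, xbest, t, TMax, lb, ub) {
  a <- 2 * (1 - t / TMax)
  d <- length(xi)
  acc <- numeric(d)
  for (k in 1:3) {
    A <- 2 * a * runif(d) - a
    C <- 2 * runif(d)
    acc <- acc + (xbest - A * abs(C * xbest - xi))
  }
  clampBox(acc / 3, lb, ub)
}

#' Fuzzy step toward the best position
#'
#' `x <- x + alpha * (x_best - x)` with `alpha` in `[0, 1]`; clamped.
#'
#' @param x,xbest positions.
#' @param alpha step size in `[0, 1]` (from [gfm()] in the optimizer).
#' @param lb,ub bounds.
#' @return Updated position.
#' @export
fuzzyPerturbation <- function(x, xbest, alpha, lb, ub) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must lie in [0, 1]")
  clampBox(x + alpha * (xbest - x), lb, ub)
}

#' Gaussian fuzzy membership function
#'
#' `mu(x) = exp(-1/2 * |(x - c)/s|^m)`: 1 at `x = c`, symmetric, in
#' (0, 1]. The optimizer evaluates it at a candidate's fitness with `c` =
#' population mean fitness and `s` = population fitness SD, so
#' near-average candidates take large steps toward the best.
#'
#' @param x evaluation point.
#' @param c center (mean).
#' @param s spread (> 0).
#' @param m shape exponent (> 0, default 2).
#' @return Membership in (0, 1].
#' @export
gfm <- function(x, c, s, m = 2) {
  if (s <= 0) stopf("spread s must be > 0")
  if (m <= 0) stopf("shape m must be > 0")
  exp(-0.5 * abs((x - c) / s)^m)
}

#' Greedy selection between an incumbent and a candidate
#'
#' The candidate replaces the incumbent iff its fitness is strictly
#' smaller; ties keep the incumbent.
#'
#' @param xOld,fOld incumbent position and fitness.
#' @param xNew,fNew candidate position and fitness.
#' @return list(x, f) of the survivor.
#' @export
greedySelect <- function(xOld, fOld, xNew, fNew) {
  if (fNew < fOld) list(x = xNew, f = fNew) else list(x = xOld, f = fOld)
}

#' Adaptive control parameter schedule
#'
#' Linear decay `c1(t) = cMax - (cMax - cMin) * t / TMax`, always within
#' `[cMin, cMax]`.
#'
#' @param t iteration.
#' @param cfg an [fssaConfig()] list.
#' @return Scalar c1.
#' @export
adaptiveC1 <- function(t, cfg) cfg$cMax - (cfg$cMax - cfg$cMin) * t / cfg$TMax

#' Population size schedule
#'
#' `n(t) = round(nMax + (nMin - nMax) * t / TMax)`; when the size shrinks
#' the optimizer discards the worst-fitness salps.
#'
#' @inheritParams adaptiveC1
#' @return Integer population size.
#' @export
adaptPopulation <- function(t, cfg) {
  as.integer(round(cfg$nMax + (cfg$nMin - cfg$nMax) * t / cfg$TMax))
}

#' Run the fuzzy salp swarm optimizer
#'
#' Minimizes `fitnessFn` over the box `[lb, ub]`. Seeded and fully
#' deterministic given the config.
#'
#' @param fitnessFn function(numeric(d)) -> finite scalar.
#' @param lb,ub bounds.
#' @param cfg an [fssaConfig()] list.
#' @param init optional matrix (or vector) of initial positions inserted as
#'   the first salp(s) (e.g. a known-good parameter vector).
#' @return list(best, bestFitness, trace) where trace is a data.frame
#'   `iter, best_fitness, pop_size, c1`.
#' @export
fssaOptimize <- function(fitnessFn, lb, ub, cfg = fssaConfig(), init = NULL) {
  evalFit <- function(x) {
    f <- fitnessFn(x)
    if (!is.finite(f))
      stopf("fitness function returned a non-finite value at position [%s]",
            paste(format(x, digits = 6), collapse = ", "))
    f
  }
  withSeed(cfg$seed, {
    pop <- initializePopulation(cfg$nMax, lb, ub, seed = NULL)
    if (!is.null(init)) {
      init <- rbind(init)
      ni <- min(nrow(init), cfg$nMax)
      pop$positions[seq_len(ni), ] <- clampBox(init[seq_len(ni), , drop = FALSE],
                                               matrix(lb, ni, length(lb), byrow = TRUE),
                                               matrix(ub, ni, length(ub), byrow = TRUE))
    }
    pop$fitness <- apply(pop$positions, 1, evalFit)
    ibest <- which.min(pop$fitness)
    pop$food <- pop$positions[ibest, ]
    pop$foodFitness <- pop$fitness[ibest]

    trBest <- numeric(cfg$TMax); trSize <- integer(cfg$TMax); trC1 <- numeric(cfg$TMax)
    for (t in seq_len(cfg$TMax)) {
      c1 <- if (cfg$c1Schedule == "linear") adaptiveC1(t, cfg) else c1Decay(t, cfg$TMax)
      n <- nrow(pop$positions)
      if (cfg$explorationPhase && t < cfg$TMax / 2) {
        mf <- mean(pop$fitness)
        sf <- max(sd(pop$fitness), 1e-12)
        for (i in seq_len(n)) {
          cand <- explorationUpdate(pop$positions[i, ], pop$food, t, cfg$TMax, lb, ub)
          fCand <- evalFit(cand)
          alpha <- gfm(fCand, mf, sf, cfg$gfmShape)
          cand2 <- fuzzyPerturbation(cand, pop$food, alpha, lb, ub)
          f2 <- evalFit(cand2)
          keep <- greedySelect(pop$positions[i, ], pop$fitness[i], cand2, f2)
          pop$positions[i, ] <- keep$x; pop$fitness[i] <- keep$f
          if (keep$f < pop$foodFitness) {
            pop$food <- keep$x; pop$foodFitness <- keep$f
          }
        }
      } else {
        if (cfg$resortChain) {
          ord <- order(pop$fitness)
          pop$positions <- pop$positions[ord, , drop = FALSE]
          pop$fitness <- pop$fitness[ord]
        }
        newPos <- pop$positions
        newPos[1, ] <- leaderUpdate(pop, c1)
        newPos <- followerUpdate(newPos, lb, ub)
        for (i in seq_len(n)) {
          fNew <- evalFit(newPos[i, ])
          keep <- greedySelect(pop$positions[i, ], pop$fitness[i], newPos[i, ], fNew)
          pop$positions[i, ] <- keep$x; pop$fitness[i] <- keep$f
          if (keep$f < pop$foodFitness) {
            pop$food <- keep$x; pop$foodFitness <- keep$f
          }
        }
      }
      if (cfg$adaptPopulation) {
        nTarget <- max(adaptPopulation(t, cfg), cfg$nMin)
        if (nTarget < nrow(pop$positions)) {
          keepIdx <- order(pop$fitness)[seq_len(nTarget)]
          keepIdx <- sort(keepIdx)     # preserve chain order of survivors
          pop$positions <- pop$positions[keepIdx, , drop = FALSE]
          pop$fitness <- pop$fitness[keepIdx]
        }
      }
      trBest[t] <- pop$foodFitness; trSize[t] <- nrow(pop$positions); trC1[t] <- c1
    }
    list(best = pop$food, bestFitness = pop$foodFitness,
         trace = data.frame(iter = seq_len(cfg$TMax), best_fitness = trBest,
                            pop_size = trSize, c1 = trC1))
  })
}

#' Refine a trained model's global classifier with FSSA
#'
#' Flattens the global classifier's final linear layer (weights and biases)
#' into the FSSA decision vector, bounded to the current values +/-
#' `radius`. The fitness is the negative validation accuracy with a small
#' cross-entropy tie-break, so minimization maximizes accuracy. The input
#' parameters seed the first salp, which with greedy selection guarantees
#' the returned model's validation accuracy never falls below the input
#' model's. Since only the final layer moves, the penultimate features of
#' each validation bag are computed once up front.
#'
#' @param model a trained [BagModel-class].
#' @param valBags non-empty list of labelled [PatchBag-class].
#' @param cfg an [fssaConfig()] list.
#' @param radius box half-width around the current parameters (default
#'   0.5). `radius = 0` returns the model unchanged.
#' @param threshold hard-call threshold on the positive-class probability.
#' @return list(model, bestFitness, trace, accuracyBefore, accuracyAfter).
#' @export
refineClassifier <- function(model, valBags, cfg = fssaConfig(), radius = 0.5,
                             threshold = 0.5) {
  stopifnot(is(model, "BagModel"))
  if (!length(valBags)) stopf("validation set must be non-empty")
  y <- vapply(valBags, function(b) b@label, integer(1))
  if (anyNA(y)) stopf("all validation bags must be labelled")

  # penultimate features are invariant under final-layer changes
  nFlat <- ncol(model@classifier$fc$W)
  feats <- vapply(valBags, function(b) {
    fw <- fullForward(model, b@patches, training = FALSE)
    fw$caches$cl$flat
  }, numeric(nFlat))

  theta0 <- c(as.numeric(model@classifier$fc$W), model@classifier$fc$b)
  accOf <- function(theta) {
    Wm <- matrix(theta[seq_len(length(theta) - 2)], 2)
    b <- theta[length(theta) - 1:0]
    logits <- Wm %*% feats + b          # 2 x n
    pm <- apply(logits, 2, softmaxProbs)
    calls <- as.integer(pm[2, ] >= threshold)
    acc <- mean(calls == y)
    ce <- -mean(log(pmax(ifelse(y == 1, pm[2, ], pm[1, ]), 1e-300)))
    c(acc = acc, ce = ce)
  }
  fitness <- function(theta) {
    m <- accOf(theta)
    -m["acc"] + 1e-3 * m["ce"] / (1 + m["ce"])
  }
  before <- accOf(theta0)
  if (radius <= 0)
    return(list(model = model, bestFitness = unname(fitness(theta0)),
                trace = NULL, accuracyBefore = unname(before["acc"]),
                accuracyAfter = unname(before["acc"])))
  res <- fssaOptimize(function(th) unname(fitness(th)),
                      lb = theta0 - radius, ub = theta0 + radius,
                      cfg = cfg, init = theta0)
  nW <- length(theta0) - 2
  model@classifier$fc$W <- matrix(res$best[seq_len(nW)], 2)
  model@classifier$fc$b <- res$best[nW + 1:2]
  after <- accOf(res$best)
  list(model = model, bestFitness = res$bestFitness, trace = res$trace,
       accuracyBefore = unname(before["acc"]),
       accuracyAfter = unname(after["acc"]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
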