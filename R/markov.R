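#' Nonhomogeneous Markov model of MEP division outcomes
#'
#' Fits the generation-dependent division-outcome model: each bipotent (MEP)
#' division at generation g results in one of four outcomes
#' (`expansion`, `maintenance_E`, `maintenance_Mk`, `exhaustion`) with
#' probabilities given by a multinomial logit whose linear predictor is
#' linear in log generation,
#' \deqn{\eta_{ij}(g) = \alpha_{ij} + \beta_{ij} \log g,}
#' softmax-normalized over outcomes j for each from-state i (`expansion` is
#' the reference outcome with \eqn{\eta = 0}). The log-generation covariate
#' is the discrete-time analogue of a Weibull log-hazard, which is linear in
#' log time; \eqn{\beta = 0} recovers the homogeneous (exponential-like)
#' chain. Exhaustion is absorbing: it never appears as a from-state, and
#' simulated chains stop there.
#'
#' The from-state of a division is the outcome of the division that created
#' the dividing cell (`"start"` for the plated cell). With
#' `shared = TRUE` a reduced, from-state-independent model is fitted (one
#' \eqn{\alpha, \beta} pair per outcome), embodying the memoryless reading
#' in which the outcome distribution depends on generation only; the two
#' models are likelihood-ratio comparable.
#'
#' Estimation is by maximum likelihood: Newton iterations with analytic
#' gradient and Hessian from zero-initialized parameters (the multinomial
#' logit log-likelihood is concave), convergence declared at gradient norm
#' below `tol`. The covariance matrix is the inverse observed information.
#'
#' @param events data frame with columns `from_state`, `generation`,
#'   `outcome` — one row per uncensored division (see [division_events()]);
#'   censored terminals contribute no row. Alternatively a list of
#'   sequences from [extract_division_sequences()] /
#'   [simulate_outcome_sequences()].
#' @param shared fit the reduced from-state-independent model.
#' @param time_dependent include the \eqn{\beta \log g} terms (set `FALSE`
#'   for the homogeneous null model).
#' @param tol convergence tolerance on the max absolute score.
#' @param max_iter Newton iteration cap.
#' @return an object of class `mep_markov` with methods [print()],
#'   [summary()], [coef()], [vcov()], [logLik()], [predict.mep_markov()] and
#'   [simulate.mep_markov()].
#' @examples
#' ev <- data.frame(from_state = "start", generation = rep(1:5, each = 20),
#'                  outcome = rep(c("expansion", "exhaustion"), 50))
#' fit <- mep_markov(ev, shared = TRUE)
#' predict(fit, generations = 1:5)
#' @export
mep_markov <- function(events, shared = FALSE, time_dependent = TRUE,
                       tol = 1e-8, max_iter = 100L) {
  if (is.list(events) && !is.data.frame(events))
    events <- events_from_sequences(events)
  stopifnot(all(c("from_state", "generation", "outcome") %in% names(events)))
  if (nrow(events) == 0L) stop("no outcome observations to fit")
  outcomes <- c("expansion", "maintenance_E", "maintenance_Mk", "exhaustion")
  bad <- setdiff(unique(events$outcome), outcomes)
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  if (any(events$generation < 1)) stop("generations must be >= 1")

  states <- if (shared) "any"
            else c("start", "expansion", "maintenance_E", "maintenance_Mk")
  from <- if (shared) rep("any", nrow(events)) else events$from_state
  if (!shared) {
    badf <- setdiff(unique(from), states)
    if (length(badf)) stop("unknown from_state(s): ",
                           paste(badf, collapse = ", "))
  }

  # aggregate to (from, g) cells with outcome count vectors
  key <- paste(from, events$generation)
  cells <- lapply(split(seq_len(nrow(events)), key), function(idx) {
    list(from = from[idx[1L]], g = events$generation[idx[1L]],
         y = as.numeric(table(factor(events$outcome[idx],
                                     levels = outcomes))))
  })

  layout <- mk_layout(states, outcomes, time_dependent)
  theta <- numeric(layout$npar)

  ll_grad_hess <- function(theta, want_hess = TRUE) {
    ll <- 0
    grad <- numeric(layout$npar)
    H <- if (want_hess) matrix(0, layout$npar, layout$npar)
    for (cell in cells) {
      p <- mk_probs(theta, layout, cell$from, cell$g)
      n <- sum(cell$y)
      ll <- ll + sum(cell$y * log(pmax(p, 1e-300)))
      x <- if (layout$time_dependent) c(1, log(cell$g)) else 1
      idx <- layout$index[[cell$from]]      # npar-index per non-ref outcome
      resid <- cell$y[-1L] - n * p[-1L]     # non-ref outcomes
      for (j in seq_along(idx)) {
        grad[idx[[j]]] <- grad[idx[[j]]] + resid[j] * x
      }
      if (want_hess) {
        pj <- p[-1L]
        W <- -n * (diag(pj, length(pj)) - tcrossprod(pj))
        XX <- tcrossprod(x)
        for (j in seq_along(idx)) for (k in seq_along(idx)) {
          H[idx[[j]], idx[[k]]] <- H[idx[[j]], idx[[k]]] + W[j, k] * XX
        }
      }
    }
    list(ll = ll, grad = grad, H = H)
  }

  converged <- FALSE; iter <- 0L
  cur <- ll_grad_hess(theta)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    # tiny ridge keeps the direction well-defined when a coefficient is
    # unidentified (e.g. a from-state observed at a single generation)
    step <- tryCatch(solve(cur$H - diag(1e-8, length(theta)), cur$grad),
                     error = function(e) cur$grad / (1 + max(abs(cur$grad))))
    # Newton ascent with step halving (H is negative semidefinite)
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      new <- ll_grad_hess(cand)
      if (new$ll >= cur$ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    theta <- cand; cur <- new
    if (max(abs(theta)) > 20) break  # separation: parameters diverging
  }
  if (max(abs(cur$grad)) < tol) converged <- TRUE

  boundary <- max(abs(theta)) > 12
  if (boundary)
    warning("mep_markov: parameter(s) at boundary (outcome rarely or never ",
            "observed for some from-state); CIs unreliable")
  one_outcome <- length(unique(events$outcome)) == 1L
  if (one_outcome)
    warning("mep_markov: a single outcome class observed (total ",
            "separation); CIs unreliable")

  V <- tryCatch(solve(-cur$H), error = function(e) {
    matrix(NA_real_, layout$npar, layout$npar)
  })
  dimnames(V) <- list(layout$names, layout$names)

  structure(list(
    coefficients = stats::setNames(theta, layout$names),
    vcov = V, logLik = cur$ll, n = nrow(events),
    converged = converged, iterations = iter,
    boundary = boundary, separation = one_outcome,
    shared = shared, time_dependent = time_dependent,
    states = states, outcomes = outcomes, ref = outcomes[1L],
    layout = layout,
    cells = cells), class = "mep_markov")
}

# parameter layout: per from-state, per non-ref outcome, (alpha[, beta])
mk_layout <- function(states, outcomes, time_dependent) {
  nonref <- outcomes[-1L]
  per <- if (time_dependent) 2L else 1L
  names <- character(); index <- list()
  pos <- 0L
  for (s in states) {
    index[[s]] <- list()
    for (j in nonref) {
      idx <- pos + seq_len(per)
      pos <- pos + per
      index[[s]][[j]] <- idx
      names <- c(names,
                 if (time_dependent)
                   paste(s, j, c("alpha", "beta"), sep = ".")
                 else paste(s, j, "alpha", sep = "."))
    }
  }
  list(states = states, outcomes = outcomes, nonref = nonref,
       time_dependent = time_dependent, npar = pos, names = names,
       index = index)
}

mk_probs <- function(theta, layout, from, g) {
  x <- if (layout$time_dependent) c(1, log(g)) else 1
  eta <- c(0, vapply(layout$index[[from]],
                     function(idx) sum(theta[idx] * x), numeric(1)))
  e <- exp(eta - max(eta))
  stats::setNames(e / sum(e), layout$outcomes)
}

#' Outcome probabilities at a given generation
#'
#' @param object a fitted [mep_markov()] model or a parameter object from
#'   [mep_markov_params()].
#' @param generation generation index (>= 1).
#' @param from_state from-state; defaults to the model's first state
#'   (`"start"`, or `"any"` for shared models).
#' @return named probability vector over the four outcomes (sums to 1).
#' @export
transition_probabilities <- function(object, generation,
                                     from_state = object$states[1L]) {
  stopifnot(inherits(object, "mep_markov"))
  if (generation < 1) stop("generation must be >= 1")
  mk_probs(object$coefficients, object$layout, from_state, generation)
}

#' @export
print.mep_markov <- function(x, ...) {
  cat("Nonhomogeneous Markov division-outcome model",
      if (x$shared) "(from-state-independent)" else "(from-state-dependent)",
      "\n")
  cat("  ", x$n, " division events, logLik ", format(x$logLik, digits = 6),
      ", ", length(x$coefficients), " parameters, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.mep_markov <- function(object, ...) object$coefficients

#' @export
vcov.mep_markov <- function(object, ...) object$vcov

#' @export
logLik.mep_markov <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
summary.mep_markov <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, logLik = object$logLik, n = object$n,
                 converged = object$converged, boundary = object$boundary),
            class = "summary.mep_markov")
}

#' @export
print.summary.mep_markov <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat("logLik:", format(x$logLik, digits = 6), " n:", x$n, "\n")
  invisible(x)
}

#' Per-generation outcome probabilities with confidence intervals
#'
#' Point probabilities via the softmax of the fitted linear predictors;
#' 95% (or `level`) intervals either by the delta method propagated through
#' the softmax (default) or by a seeded parametric bootstrap (outcomes
#' redrawn from the fitted probabilities at the observed design, model
#' refitted, percentile intervals).
#'
#' @param object a fitted [mep_markov()].
#' @param generations integer vector, default `1:13`.
#' @param from_state from-state(s) to predict for; default all.
#' @param interval `"delta"`, `"bootstrap"` or `"none"`.
#' @param level confidence level.
#' @param nboot bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @param ... unused.
#' @return data frame with columns `from_state`, `generation`, `outcome`,
#'   `p`, `lo`, `hi`; probabilities sum to 1 within each
#'   (from_state, generation), intervals are clamped to `[0, 1]` and contain
#'   the point estimate.
#' @export
predict.mep_markov <- function(object, generations = 1:13,
                               from_state = object$states,
                               interval = c("delta", "bootstrap", "none"),
                               level = 0.95, nboot = 200L, seed = NULL, ...) {
  interval <- match.arg(interval)
  if (any(generations < 1)) stop("generations must be >= 1")
  grid <- expand.grid(from_state = from_state, generation = generations,
                      stringsAsFactors = FALSE)

  boot <- NULL
  if (interval == "bootstrap")
    boot <- boot_refits(object, nboot = nboot, seed = seed)

  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    i <- grid$from_state[r]; g <- grid$generation[r]
    p <- mk_probs(object$coefficients, object$layout, i, g)
    lo <- hi <- rep(NA_real_, length(p))
    if (interval == "delta" && !anyNA(object$vcov)) {
      J <- prob_jacobian(object, i, g)
      se <- sqrt(pmax(0, diag(J %*% object$vcov %*% t(J))))
      lo <- pmax(0, p - z * se); hi <- pmin(1, p + z * se)
    } else if (interval == "bootstrap") {
      reps <- vapply(boot, function(th)
        mk_probs(th, object$layout, i, g), numeric(length(p)))
      qs <- apply(reps, 1L, stats::quantile,
                  probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
      lo <- pmin(pmax(0, qs[1L, ]), p); hi <- pmax(pmin(1, qs[2L, ]), p)
    }
    data.frame(from_state = i, generation = g,
               outcome = object$outcomes, p = unname(p),
               lo = unname(lo), hi = unname(hi), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# d p(outcome) / d theta at (from-state, generation); rows = outcomes
prob_jacobian <- function(object, from, g) {
  layout <- object$layout
  p <- mk_probs(object$coefficients, layout, from, g)
  x <- if (layout$time_dependent) c(1, log(g)) else 1
  J <- matrix(0, length(p), layout$npar)
  idx <- layout$index[[from]]
  for (j in seq_along(p)) {
    for (k in seq_along(idx)) {   # k over non-ref outcomes
      dk <- as.numeric(j == k + 1L)
      J[j, idx[[k]]] <- p[j] * (dk - p[k + 1L]) * x
    }
  }
  J
}

# parametric bootstrap: redraw outcome counts at the observed design, refit
boot_refits <- function(object, nboot, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nboot), function(b) {
    ev <- do.call(rbind, lapply(object$cells, function(cell) {
      p <- mk_probs(object$coefficients, object$layout, cell$from, cell$g)
      y <- as.vector(stats::rmultinom(1L, size = sum(cell$y), prob = p))
      data.frame(from_state = cell$from, generation = cell$g,
                 outcome = rep(object$outcomes, y), stringsAsFactors = FALSE)
    }))
    fit <- suppressWarnings(mep_markov(ev, shared = object$shared,
                                       time_dependent = object$time_dependent))
    fit$coefficients
  })
}

#' Construct a parameter object without fitting
#'
#' Builds a `mep_markov` object from known coefficients, for simulation,
#' toy computations and parameter-recovery tests. `alpha`/`beta` are named
#' vectors over the non-reference outcomes (`maintenance_E`,
#' `maintenance_Mk`, `exhaustion`) for a shared model, or matrices with one
#' row per from-state (`start`, `expansion`, `maintenance_E`,
#' `maintenance_Mk`) for the full model.
#'
#' @param alpha,beta intercepts and log-generation slopes.
#' @param shared from-state-independent parameterization.
#' @return a `mep_markov` object (no data, no covariance).
#' @export
mep_markov_params <- function(alpha, beta = NULL, shared = TRUE) {
  outcomes <- c("expansion", "maintenance_E", "maintenance_Mk", "exhaustion")
  nonref <- outcomes[-1L]
  states <- if (shared) "any"
            else c("start", "expansion", "maintenance_E", "maintenance_Mk")
  time_dependent <- !is.null(beta)
  layout <- mk_layout(states, outcomes, time_dependent)
  theta <- numeric(layout$npar)
  get <- function(m, s, j) {
    if (shared) m[[j]] else m[s, j]
  }
  for (s in states) for (j in nonref) {
    idx <- layout$index[[s]][[j]]
    theta[idx[1L]] <- get(alpha, s, j)
    if (time_dependent) theta[idx[2L]] <- get(beta, s, j)
  }
  structure(list(
    coefficients = stats::setNames(theta, layout$names),
    vcov = matrix(NA_real_, layout$npar, layout$npar),
    logLik = NA_real_, n = 0L, converged = NA, iterations = 0L,
    boundary = FALSE, separation = FALSE,
    shared = shared, time_dependent = time_dependent,
    states = states, outcomes = outcomes, ref = outcomes[1L],
    layout = layout, cells = list()), class = "mep_markov")
}

#' Simulate division-outcome sequences from the model
#'
#' Draws chains starting at the model's start state and generation 1; each
#' step's outcome is drawn from the model's probabilities at the current
#' (from-state, generation), the from-state moves to the drawn outcome, and
#' the chain stops at exhaustion (absorbing) or is truncated, censored, at
#' `g_max`.
#'
#' @param object a `mep_markov` fit or parameter object.
#' @param n number of sequences.
#' @param seed integer seed.
#' @param g_max truncation generation (default 13).
#' @return list of data frames (`generation`, `from_state`, `outcome`) with
#'   attribute `"censored"`.
#' @export
simulate_outcome_sequences <- function(object, n, seed = NULL, g_max = 13L) {
  stopifnot(inherits(object, "mep_markov"))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(s) {
    from <- "start"; g <- 1L
    gens <- integer(); froms <- character(); outs <- character()
    censored <- TRUE
    while (g <= g_max) {
      lookup <- if (object$shared) "any" else from
      p <- mk_probs(object$coefficients, object$layout, lookup, g)
      o <- sample(object$outcomes, 1L, prob = p)
      # the recorded from-state is the chain state (previous outcome),
      # regardless of whether the generating model distinguishes from-states
      gens <- c(gens, g); froms <- c(froms, from); outs <- c(outs, o)
      if (o == "exhaustion") { censored <- FALSE; break }
      from <- o
      g <- g + 1L
    }
    structure(data.frame(generation = gens, from_state = froms,
                         outcome = outs, stringsAsFactors = FALSE),
              censored = censored)
  })
}

#' @rdname simulate_outcome_sequences
#' @param nsim,... standard [stats::simulate()] arguments.
#' @export
simulate.mep_markov <- function(object, nsim = 1, seed = NULL, ...) {
  args <- list(...)
  g_max <- if (!is.null(args$g_max)) args$g_max else 13L
  simulate_outcome_sequences(object, n = nsim, seed = seed, g_max = g_max)
}

#' Flatten simulated or extracted sequences into an event table
#' @param sequences list of data frames as produced by
#'   [simulate_outcome_sequences()] or [extract_division_sequences()].
#' @return data frame with `from_state`, `generation`, `outcome`.
#' @export
events_from_sequences <- function(sequences) {
  blocks <- lapply(sequences, function(s) {
    if (nrow(s) == 0L) return(NULL)
    if (is.null(s$from_state))
      s$from_state <- c("start", utils::head(s$outcome, -1L))
    s[c("from_state", "generation", "outcome")]
  })
  res <- do.call(rbind, blocks)
  if (is.null(res))
    res <- data.frame(from_state = character(), generation = integer(),
                      outcome = character())
  rownames(res) <- NULL
  res
}

#' Expected first-division exhaustion under a uniform generational-age mix
#'
#' If plated cells are an equal mixture of generational ages `1..G`, the
#' probability that a cell exhausts at its first observed division is the
#' arithmetic mean of the per-generation exhaustion probabilities,
#' \eqn{(1/G) \sum_{g=1}^{G} P(\mathrm{exhaustion} \mid g)}.
#'
#' @param object a `mep_markov` fit or parameter object, or a plain numeric
#'   vector of per-generation exhaustion probabilities (length >= `G`).
#' @param G number of generations in the mixture (default 13).
#' @param from_state from-state row to use (default the start state).
#' @return a single probability.
#' @export
first_division_exhaustion <- function(object, G = 13L,
                                      from_state = NULL) {
  if (is.numeric(object)) {
    if (length(object) < G) stop("need ", G, " per-generation probabilities")
    return(mean(object[seq_len(G)]))
  }
  if (is.null(from_state)) from_state <- object$states[1L]
  mean(vapply(seq_len(G), function(g)
    transition_probabilities(object, g, from_state)[["exhaustion"]],
    numeric(1)))
}

#' Likelihood-ratio test of outcome homogeneity over generations
#'
#' Fits the homogeneous model (no log-generation terms) and the
#' nonhomogeneous model to the same events and compares them by likelihood
#' ratio against a chi-squared reference with as many degrees of freedom as
#' there are generation coefficients.
#'
#' @param events event table as for [mep_markov()].
#' @param shared compare the reduced (from-state-independent) pair.
#' @return an object of class `htest`.
#' @export
homogeneity_test <- function(events, shared = TRUE) {
  fit1 <- suppressWarnings(mep_markov(events, shared = shared,
                                      time_dependent = TRUE))
  fit0 <- suppressWarnings(mep_markov(events, shared = shared,
                                      time_dependent = FALSE))
  lr <- 2 * (fit1$logLik - fit0$logLik)
  df <- length(fit1$coefficients) - length(fit0$coefficients)
  p <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
  structure(list(statistic = c(LR = lr), parameter = c(df = df),
                 p.value = p,
                 method = paste("Likelihood-ratio test of generation",
                                "homogeneity of division outcomes"),
                 data.name = deparse(substitute(events))),
            class = "htest")
}

#' Serialize fitted parameters to structured text (YAML)
#' @param object a `mep_markov` object.
#' @param file output path.
#' @export
write_mep_markov <- function(object, file) {
  yaml::write_yaml(list(
    shared = object$shared, time_dependent = object$time_dependent,
    states = object$states, outcomes = object$outcomes,
    coefficients = as.list(object$coefficients),
    vcov = if (!anyNA(object$vcov)) apply(object$vcov, 1L, as.list),
    logLik = object$logLik, n = object$n,
    converged = object$converged), file)
  invisible(file)
}
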