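#' Configuration for the arithmetic optimization algorithm
#'
#' Settings for the improved arithmetic optimization algorithm (AOA): a
#' population metaheuristic whose exploration moves are MOP-scaled
#' multiplication/division around the incumbent best and whose exploitation
#' moves are addition/subtraction. The improvements over vanilla AOA —
#' tent-chaos population initialization, a nonlinear accelerated function,
#' and per-iteration population mutation — can each be switched off for
#' ablation.
#'
#' @param pop_size Number of candidate solutions (>= 2).
#' @param max_iter Number of iterations T (>= 1).
#' @param lower,upper Per-dimension bounds (equal length, `lower < upper`).
#' @param mu Search control coefficient, conventionally 0.5.
#' @param a_mop Sensitivity exponent of the math optimizer probability.
#' @param moa_min,moa_max Endpoints of the linear accelerated schedule,
#'   both in \[0, 1\].
#' @param schedule `"nonlinear"` uses the accelerated function
#'   `(t/T)^2 * exp(1 - t/T)`; `"linear"` the classic
#'   `Min + t * (Max - Min) / T`.
#' @param a_tent Tent-map parameter, in (0, 1).
#' @param tent_init Use tent-chaos initialization (`FALSE` falls back to
#'   uniform random initialization).
#' @param mutation_on Apply the population mutation strategy.
#' @param mutation_prob Per-candidate, per-iteration probability of
#'   proposing a mutation (greedily accepted).
#' @param eps_div Small constant guarding the division operator.
#' @param integer_dims Integer vector of dimensions that are integer-valued;
#'   these are searched continuously and rounded at evaluation time.
#' @param seed Integer seed; the whole optimization is deterministic given it.
#' @return A list of class `aoa_config`.
#' @export
aoa_config <- function(pop_size = 60, max_iter = 50,
                       lower = c(4, 500), upper = c(10, 3000),
                       mu = 0.5, a_mop = 5, moa_min = 0.2, moa_max = 1,
                       schedule = c("nonlinear", "linear"),
                       a_tent = 0.7, tent_init = TRUE,
                       mutation_on = TRUE, mutation_prob = 0.2,
                       eps_div = 1e-12, integer_dims = integer(),
                       seed = 1L) {
  schedule <- match.arg(schedule)
  if (pop_size < 2) abort("`pop_size` must be >= 2.", class = "aovmd_config_error")
  if (max_iter < 1) abort("`max_iter` must be >= 1.", class = "aovmd_config_error")
  if (length(lower) != length(upper) || any(lower >= upper)) {
    abort("`lower` must be elementwise below `upper`.", class = "aovmd_config_error")
  }
  if (a_tent <= 0 || a_tent >= 1) {
    abort("`a_tent` must lie strictly in (0, 1).", class = "aovmd_config_error")
  }
  if (moa_min < 0 || moa_max > 1 || moa_min > moa_max) {
    abort("need 0 <= moa_min <= moa_max <= 1.", class = "aovmd_config_error")
  }
  if (a_mop <= 0) abort("`a_mop` must be > 0.", class = "aovmd_config_error")
  structure(list(
    pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
    lower = as.numeric(lower), upper = as.numeric(upper),
    mu = mu, a_mop = a_mop, moa_min = moa_min, moa_max = moa_max,
    schedule = schedule, a_tent = a_tent, tent_init = tent_init,
    mutation_on = mutation_on, mutation_prob = mutation_prob,
    eps_div = eps_div, integer_dims = as.integer(integer_dims),
    seed = as.integer(seed)
  ), class = "aoa_config")
}

#' One step of the tent chaotic map
#'
#' Piecewise-linear map on (0, 1): `x / a` below the knee `a`, and
#' `(1 - x) / (1 - a)` above it.
#'
#' @param x Current value(s) in \[0, 1\].
#' @param a_tent Knee parameter in (0, 1).
#' @return Mapped value(s).
#' @export
tent_step <- function(x, a_tent) {
  ifelse(x < a_tent, x / a_tent, (1 - x) / (1 - a_tent))
}

#' Iterate the tent map into a chaotic stream
#'
#' @param n Number of iterates to return.
#' @param a_tent Knee parameter in (0, 1).
#' @param x0 Start value in (0, 1).
#' @param burn_in Iterates discarded before collecting.
#' @return Numeric vector of length `n`, values in (0, 1).
#' @export
tent_stream <- function(n, a_tent, x0, burn_in = 100L) {
  if (a_tent <= 0 || a_tent >= 1) {
    abort("`a_tent` must lie strictly in (0, 1).", class = "aovmd_config_error")
  }
  x <- x0
  out <- numeric(n)
  total <- n + burn_in
  for (i in seq_len(total)) {
    x <- tent_step(x, a_tent)
    # the map's fixed points 0 and 1 would freeze the stream; nudge off them
    if (x <= 0 || x >= 1) x <- abs(x - floor(x)) + 1e-10
    if (i > burn_in) out[i - burn_in] <- x
  }
  out
}

#' Tent-chaos population initialization
#'
#' Seeds one chaotic stream per dimension, skips a burn-in, and maps the
#' iterates affinely into the search bounds.
#'
#' @param cfg An [aoa_config()].
#' @return A `pop_size x dim` matrix of positions, all within bounds.
#' @export
tent_init <- function(cfg) {
  dim <- length(cfg$lower)
  local_rng(cfg$seed)(function() {
    pos <- matrix(0, nrow = cfg$pop_size, ncol = dim)
    for (j in seq_len(dim)) {
      x0 <- runif(1, 0.01, 0.99)
      u <- tent_stream(cfg$pop_size, cfg$a_tent, x0)
      pos[, j] <- cfg$lower[j] + u * (cfg$upper[j] - cfg$lower[j])
    }
    pos
  })
}

#' Accelerated schedule gating explore vs exploit
#'
#' Linear form `Min + t * (Max - Min) / T`, or the nonlinear form
#' `(t/T)^2 * exp(1 - t/T)` which rises more slowly early on (favouring a
#' longer fine-search phase) and reaches 1 at `t = T`.
#'
#' @param t Iteration, in \[0, T\].
#' @param cfg An [aoa_config()].
#' @return Schedule value in \[0, 1\].
#' @export
accel_schedule <- function(t, cfg) {
  if (any(t < 0 | t > cfg$max_iter)) {
    abort("`t` must lie in [0, max_iter].", class = "aovmd_config_error")
  }
  r <- t / cfg$max_iter
  switch(cfg$schedule,
    linear = cfg$moa_min + r * (cfg$moa_max - cfg$moa_min),
    nonlinear = r^2 * exp(1 - r)
  )
}

#' Math optimizer probability
#'
#' Decaying step-size scale `1 - (t/T)^(1/a_mop)`.
#'
#' @inheritParams accel_schedule
#' @return Value in \[0, 1\].
#' @export
math_optimizer_probability <- function(t, cfg) {
  if (any(t < 0 | t > cfg$max_iter)) {
    abort("`t` must lie in [0, max_iter].", class = "aovmd_config_error")
  }
  1 - (t / cfg$max_iter)^(1 / cfg$a_mop)
}

#' Arithmetic position update
#'
#' Exploration moves scale the incumbent best by division or multiplication
#' with the MOP step size; exploitation moves add or subtract the scaled
#' step. Results are clipped to the bounds.
#'
#' @param x_best Incumbent best position.
#' @param phase `"explore"` or `"exploit"`.
#' @param mop Math optimizer probability at the current iteration.
#' @param cfg An [aoa_config()].
#' @param r Per-dimension uniform draws deciding the operator pair
#'   (division vs multiplication, subtraction vs addition); drawn from the
#'   current RNG when omitted.
#' @return New position, within bounds.
#' @export
position_update <- function(x_best, phase = c("explore", "exploit"), mop, cfg,
                            r = NULL) {
  phase <- match.arg(phase)
  dim <- length(x_best)
  if (is.null(r)) r <- runif(dim)
  span <- (cfg$upper - cfg$lower) * cfg$mu + cfg$lower
  new <- if (phase == "explore") {
    ifelse(r < 0.5,
           x_best / (mop + cfg$eps_div) * span,
           x_best * mop * span)
  } else {
    ifelse(r < 0.5,
           x_best - mop * span,
           x_best + mop * span)
  }
  clip_bounds(new, cfg)
}

#' Population mutation move
#'
#' Blends the pull toward the incumbent best with the pull toward a random
#' population member: `r1 * (x_best - x) + (1 - r1) * (x_rand - x)`,
#' clipped to bounds. Interpreted as a proposed new position and accepted
#' greedily by the optimizer.
#'
#' @param x Current position.
#' @param x_best Incumbent best position.
#' @param x_rand A randomly chosen population member.
#' @param r1 Blend weight in \[0, 1\]; drawn when omitted.
#' @param cfg An [aoa_config()].
#' @return Proposed position, within bounds.
#' @export
mutate_position <- function(x, x_best, x_rand, r1 = NULL, cfg) {
  if (is.null(r1)) r1 <- runif(1)
  clip_bounds(r1 * (x_best - x) + (1 - r1) * (x_rand - x), cfg)
}

clip_bounds <- function(x, cfg) {
  pmin(pmax(x, cfg$lower), cfg$upper)
}

round_integer_dims <- function(x, cfg) {
  if (length(cfg$integer_dims)) {
    x[cfg$integer_dims] <- round(x[cfg$integer_dims])
  }
  x
}

cache_key <- function(x, cfg) {
  q <- round(x, 4)
  q <- round_integer_dims(q, cfg)
  paste(format(q, digits = 15), collapse = "|")
}

#' Run the improved arithmetic optimization algorithm
#'
#' Minimizes `objective` over box bounds: tent-chaos initialization, then
#' `max_iter` sweeps in which each candidate moves by an arithmetic operator
#' around the incumbent best (phase gated by a uniform draw against the
#' accelerated schedule), followed by an optional greedily-accepted mutation.
#' Fully deterministic given `cfg$seed`. Fitness values are cached on
#' quantized positions (integer dimensions exact, continuous dimensions to
#' 4 decimals) so repeated evaluations of near-identical candidates are free.
#'
#' @param objective Function of a position vector returning a finite scalar
#'   to minimize. Integer-flagged dimensions are rounded before the call.
#' @param cfg An [aoa_config()].
#' @return An object of class `aoa_fit`: `best_position`, `best_fitness`,
#'   `history` (tibble of per-iteration incumbents), `n_evals`, `config`.
#' @export
#' @examples
#' fit <- aoa_optimize(function(x) sum(x^2),
#'                     aoa_config(pop_size = 20, max_iter = 50,
#'                                lower = c(-10, -10), upper = c(10, 10)))
#' fit$best_fitness
aoa_optimize <- function(objective, cfg = aoa_config()) {
  dim <- length(cfg$lower)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L

  eval_pos <- function(x) {
    key <- cache_key(x, cfg)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- objective(round_integer_dims(x, cfg))
    n_evals <<- n_evals + 1L
    if (!is.finite(val)) val <- NA_real_
    cache[[key]] <- val
    val
  }

  local_rng(cfg$seed)(function() {
    pos <- if (cfg$tent_init) {
      tent_init(cfg)
    } else {
      matrix(runif(cfg$pop_size * dim), cfg$pop_size, dim) %*% diag(cfg$upper - cfg$lower, dim) +
        matrix(cfg$lower, cfg$pop_size, dim, byrow = TRUE)
    }
    fit <- numeric(cfg$pop_size)
    for (i in seq_len(cfg$pop_size)) {
      f <- eval_pos(pos[i, ])
      while (is.na(f)) {
        warn("objective returned a non-finite value; resampling candidate.")
        pos[i, ] <- cfg$lower + runif(dim) * (cfg$upper - cfg$lower)
        f <- eval_pos(pos[i, ])
      }
      fit[i] <- f
    }
    b <- which.min(fit)
    x_best <- pos[b, ]
    f_best <- fit[b]

    hist <- vector("list", cfg$max_iter)
    for (t in seq_len(cfg$max_iter)) {
      moa <- accel_schedule(t, cfg)
      mop <- math_optimizer_probability(t, cfg)
      for (i in seq_len(cfg$pop_size)) {
        r1 <- runif(1)
        phase <- if (r1 < moa) "explore" else "exploit"
        cand <- position_update(x_best, phase, mop, cfg)
        f_cand <- eval_pos(cand)
        if (is.na(f_cand)) {
          warn("objective returned a non-finite value; resampling candidate.")
          cand <- cfg$lower + runif(dim) * (cfg$upper - cfg$lower)
          f_cand <- eval_pos(cand)
          if (is.na(f_cand)) next
        }
        pos[i, ] <- cand
        fit[i] <- f_cand

        if (cfg$mutation_on && runif(1) < cfg$mutation_prob) {
          x_rand <- pos[sample.int(cfg$pop_size, 1L), ]
          prop <- mutate_position(pos[i, ], x_best, x_rand, cfg = cfg)
          f_prop <- eval_pos(prop)
          if (!is.na(f_prop) && f_prop < fit[i]) {
            pos[i, ] <- prop
            fit[i] <- f_prop
          }
        }

        if (fit[i] < f_best) {
          f_best <- fit[i]
          x_best <- pos[i, ]
        }
      }
      hist[[t]] <- c(iteration = t, best_fitness = f_best,
                     stats::setNames(round_integer_dims(x_best, cfg),
                                     paste0("best_x", seq_len(dim))))
    }

    history <- tibble::as_tibble(do.call(rbind, hist))
    structure(list(
      best_position = round_integer_dims(x_best, cfg),
      best_fitness = f_best,
      history = history,
      n_evals = n_evals,
      config = cfg
    ), class = "aoa_fit")
  })
}

#' @export
print.aoa_fit <- function(x, ...) {
  cat(sprintf(
    "<aoa_fit> best fitness %.6g at (%s) after %d iterations (%d evaluations)\n",
    x$best_fitness, paste(signif(x$best_position, 6), collapse = ", "),
    x$config$max_iter, x$n_evals
  ))
  invisible(x)
}

#' @export
tidy.aoa_fit <- function(x, ...) x$history

#' @export
glance.aoa_fit <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    n_iter = x$config$max_iter,
    n_evals = x$n_evals,
    pop_size = x$config$pop_size,
    schedule = x$config$schedule
  )
}

#' @export
autoplot.aoa_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "best fitness") +
    ggplot2::theme_minimal()
}
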