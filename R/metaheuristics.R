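# Swarm search dynamics: canonical inertia-weight PSO, the genetically
# inspired hybrid (GIPSO) that augments each iteration with blend crossover
# against the global best, parameter mutation, and replacement of the worst
# agent with deferred evaluation, plus a minimal real-coded GA baseline.
#
# All stochastic entry points draw from R's global generator; passing `seed`
# calls set.seed() so identical seeds give identical runs.

#' Optimizer configuration
#'
#' Defaults follow the study conditions for hyperparameter tuning
#' (population 6, 8 iterations) and the canonical inertia-weight PSO
#' constants: w annealed linearly from 0.9 to 0.4, cognitive and social
#' factors 2.0, velocity clamped to 10% of each dimension's range.
#'
#' @param pop_size Number of agents (>= 2).
#' @param iterations Number of search iterations T (>= 0).
#' @param w_max,w_min Initial and final inertia weight, `0 < w_min <= w_max`.
#' @param c1,c2 Cognitive and social acceleration factors.
#' @param v_max_fraction Velocity clamp as a fraction of each dimension's range.
#' @param variant One of `"gipso"`, `"pso"`, `"ga"`.
#' @return An `optimizer_config` object.
#' @export
optimizer_config <- function(pop_size = 6L, iterations = 8L,
                             w_max = 0.9, w_min = 0.4,
                             c1 = 2.0, c2 = 2.0, v_max_fraction = 0.1,
                             variant = c("gipso", "pso", "ga")) {
  variant <- match.arg(variant)
  stopifnot(pop_size >= 2, iterations >= 0,
            w_min > 0, w_min <= w_max, v_max_fraction > 0)
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 w_max = w_max, w_min = w_min, c1 = c1, c2 = c2,
                 v_max_fraction = v_max_fraction, variant = variant),
            class = "optimizer_config")
}

#' Genetic-mechanism configuration for GIPSO
#'
#' @param pc Per-parameter probability that the child blends the global best
#'   with the partner agent instead of copying the best (default 0.1).
#' @param md Mutation magnitude factor scaling the uniform draw (default 0.1).
#' @param pm Per-parameter mutation probability (default 0.1).
#' @param half_rnd If `TRUE`, mutation magnitude is `0.5 * rnd` instead of
#'   `md * rnd` (alternative reading of the mutation step; off by default).
#' @return A `gipso_config` object.
#' @export
gipso_config <- function(pc = 0.1, md = 0.1, pm = 0.1, half_rnd = FALSE) {
  stopifnot(pc > 0, pc <= 1, md > 0, md <= 1, pm >= 0, pm <= 1)
  structure(list(pc = pc, md = md, pm = pm, half_rnd = isTRUE(half_rnd)),
            class = "gipso_config")
}

#' Linearly annealed inertia weight
#'
#' `w(t) = w_max - ((w_max - w_min) / T) * t`, so `t = 0` gives the initial
#' weight and `t = T` the final weight.
#'
#' @param t Completed iterations, `0 <= t <= T`.
#' @param config An [optimizer_config()].
#' @return The inertia weight at iteration `t`.
#' @export
inertia_weight <- function(t, config) {
  if (config$iterations == 0) stop("inertia_weight undefined for T = 0")
  stopifnot(t >= 0, t <= config$iterations)
  config$w_max - (config$w_max - config$w_min) / config$iterations * t
}

space_bounds <- function(space) {
  list(lo = vapply(space$specs, `[[`, numeric(1), "lower"),
       hi = vapply(space$specs, `[[`, numeric(1), "upper"))
}

#' Initialize a swarm uniformly within the search box
#'
#' Positions are uniform within bounds; velocities uniform in
#' `[-Vmax, +Vmax]` per dimension; fitnesses are unset until the first
#' evaluation and personal bests start at the initial positions with
#' infinite fitness.
#'
#' @param space A `search_space`.
#' @param config An [optimizer_config()].
#' @param seed Optional integer seed.
#' @return A `swarm_state` object.
#' @export
initialize_swarm <- function(space, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- space_bounds(space)
  vmax <- config$v_max_fraction * (b$hi - b$lo)
  particles <- lapply(seq_len(config$pop_size), function(i) {
    pos <- stats::runif(space$dimension, b$lo, b$hi)
    list(position = pos,
         velocity = stats::runif(space$dimension, -vmax, vmax),
         personal_best = pos,
         personal_best_fitness = Inf,
         fitness = NA_real_)
  })
  structure(list(particles = particles,
                 global_best = NULL, global_best_fitness = Inf,
                 global_best_index = NA_integer_, iteration = 0L),
            class = "swarm_state")
}

evaluate_particle <- function(swarm, i, objective) {
  f <- objective(swarm$particles[[i]]$position)
  swarm$particles[[i]]$fitness <- as.numeric(f)
  if (as.numeric(f) < swarm$particles[[i]]$personal_best_fitness) {
    swarm$particles[[i]]$personal_best <- swarm$particles[[i]]$position
    swarm$particles[[i]]$personal_best_fitness <- as.numeric(f)
  }
  if (as.numeric(f) < swarm$global_best_fitness) {
    swarm$global_best <- swarm$particles[[i]]$position
    swarm$global_best_fitness <- as.numeric(f)
    swarm$global_best_index <- i
  }
  swarm
}

#' One PSO iteration: velocity/position update and re-evaluation
#'
#' Each velocity becomes `w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with
#' `r1, r2` uniform per dimension, clamped to `[-Vmax, +Vmax]`; positions
#' advance by the velocity and are clipped to the box; personal and global
#' bests are refreshed after re-evaluation.
#'
#' @param swarm A `swarm_state` whose global best is set.
#' @param objective Function mapping a position vector to a scalar to minimize.
#' @param t Completed iterations (sets the inertia weight).
#' @param space The `search_space`.
#' @param config An [optimizer_config()].
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(swarm, objective, t, space, config) {
  b <- space_bounds(space)
  vmax <- config$v_max_fraction * (b$hi - b$lo)
  w <- inertia_weight(t, config)
  d <- space$dimension
  for (i in seq_along(swarm$particles)) {
    p <- swarm$particles[[i]]
    r1 <- stats::runif(d)
    r2 <- stats::runif(d)
    v <- w * p$velocity +
      config$c1 * r1 * (p$personal_best - p$position) +
      config$c2 * r2 * (swarm$global_best - p$position)
    v <- pmin(pmax(v, -vmax), vmax)
    swarm$particles[[i]]$velocity <- v
    swarm$particles[[i]]$position <- pmin(pmax(p$position + v, b$lo), b$hi)
    swarm <- evaluate_particle(swarm, i, objective)
  }
  swarm$iteration <- as.integer(t) + 1L
  swarm
}

#' Blend crossover against the best agent
#'
#' For each parameter j, with probability `pc` the child takes the blend
#' `alpha * best_j + (1 - alpha) * other_j` with `alpha ~ U(0, 1)` drawn per
#' parameter; otherwise it copies the best agent's parameter.
#'
#' @param best,other Equal-length numeric parent vectors (`best` is the
#'   incumbent the child defaults to).
#' @param pc Per-parameter blend probability.
#' @param alpha Optional fixed blend factor(s) overriding the uniform draw
#'   (scalar or length of `best`); used for deterministic checks.
#' @return The child vector, within the convex hull of the parents on every
#'   blended dimension.
#' @export
crossover <- function(best, other, pc = 0.1, alpha = NULL) {
  if (length(best) != length(other)) {
    stop("crossover: parents have different lengths")
  }
  d <- length(best)
  blend <- stats::runif(d) < pc
  if (is.null(alpha)) alpha <- stats::runif(d)
  alpha <- rep_len(alpha, d)
  ifelse(blend, alpha * best + (1 - alpha) * other, best)
}

#' Mutate an agent's parameters within bounds
#'
#' Each parameter independently mutates with probability `pm`; when
#' triggered, `rnd ~ U(0, range width)` of that dimension and the parameter
#' moves by `md * rnd` (or `0.5 * rnd` when `half_rnd` is set), the sign
#' chosen uniformly. The result is clipped to the box.
#'
#' @param position Numeric vector within bounds.
#' @param space The `search_space`.
#' @param gcfg A [gipso_config()].
#' @param rnd,sign Optional fixed magnitude draw(s) and sign(s) (`+1`/`-1`)
#'   overriding the random draws; used for deterministic checks.
#' @return The mutated, clipped position.
#' @export
mutate <- function(position, space, gcfg = gipso_config(),
                   rnd = NULL, sign = NULL) {
  check_position(position, space)
  b <- space_bounds(space)
  d <- length(position)
  triggered <- stats::runif(d) < gcfg$pm
  if (is.null(rnd)) rnd <- stats::runif(d, 0, b$hi - b$lo)
  if (is.null(sign)) sign <- ifelse(stats::runif(d) < 0.5, -1, 1)
  rnd <- rep_len(rnd, d)
  sign <- rep_len(sign, d)
  step <- if (gcfg$half_rnd) 0.5 * rnd else gcfg$md * rnd
  out <- ifelse(triggered, position + sign * step, position)
  pmin(pmax(out, b$lo), b$hi)
}

#' Replace the worst agent with a new solution
#'
#' The particle with the maximal current objective value (lowest index on
#' ties) is replaced by the new agent with zero velocity and unset fitness;
#' evaluation of the newcomer is deferred to the next iteration. The stored
#' global best is untouched.
#'
#' @param swarm A `swarm_state` with all current fitnesses known.
#' @param new_position Position vector for the replacement agent.
#' @return The updated `swarm_state`.
#' @export
replace_worst <- function(swarm, new_position) {
  fit <- vapply(swarm$particles, `[[`, numeric(1), "fitness")
  if (anyNA(fit)) stop("replace_worst: all current fitnesses must be known")
  worst <- which.max(fit)
  d <- length(new_position)
  swarm$particles[[worst]] <- list(
    position = new_position,
    velocity = numeric(d),
    personal_best = new_position,
    personal_best_fitness = Inf,
    fitness = NA_real_
  )
  if (identical(worst, swarm$global_best_index)) {
    swarm$global_best_index <- NA_integer_
  }
  swarm
}

gipso_genetic_step <- function(swarm, space, gcfg) {
  n <- length(swarm$particles)
  candidates <- seq_len(n)
  if (!is.na(swarm$global_best_index)) {
    candidates <- setdiff(candidates, swarm$global_best_index)
  }
  partner <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
  child <- crossover(swarm$global_best,
                     swarm$particles[[partner]]$position, pc = gcfg$pc)
  child <- mutate(child, space, gcfg)
  replace_worst(swarm, child)
}

#' Run a metaheuristic search over a box-constrained objective
#'
#' Variant `"pso"` runs the canonical inertia-weight PSO; `"gipso"` adds,
#' after each PSO iteration, a genetically inspired step — blend crossover of
#' the global best with a random other agent, parameter mutation, and
#' replacement of the worst agent by the child, whose evaluation is deferred
#' to the next iteration so both variants spend identical evaluation
#' budgets (`pop_size * (iterations + 1)`). Variant `"ga"` is a real-coded
#' genetic baseline with tournament selection (k = 2), the same blend
#' crossover and mutation operators, and elitism of one.
#'
#' @param objective Function mapping a position (numeric vector inside the
#'   box) to a scalar to be minimized. Attributes set on the returned value
#'   (e.g. a tracked indicator metric) are kept for the best evaluation.
#' @param space A `search_space`.
#' @param config An [optimizer_config()]; `config$variant` picks the method.
#' @param gcfg A [gipso_config()] (used by `"gipso"` and `"ga"`).
#' @param seed Optional integer seed for reproducibility.
#' @return An `optimization_result` with `best_position`, `best_fitness`,
#'   `best_attributes` (attributes of the best objective value, if any),
#'   `trace` (global-best fitness after initialization and each iteration;
#'   non-increasing), `evaluations_used` and `evaluated_positions`.
#' @examples
#' res <- optimize_swarm(benchmark_objective("sphere"), default_space(),
#'                       optimizer_config(variant = "gipso"), seed = 1)
#' res$best_fitness
#' @export
optimize_swarm <- function(objective, space, config = optimizer_config(),
                           gcfg = gipso_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  counter$best <- Inf
  counter$best_attrs <- NULL
  counter$positions <- list()
  wrapped <- function(x) {
    f <- objective(x)
    counter$n <- counter$n + 1L
    counter$positions[[counter$n]] <- x
    if (as.numeric(f) < counter$best) {
      counter$best <- as.numeric(f)
      a <- attributes(f)
      counter$best_attrs <- a[setdiff(names(a), c("names", "dim"))]
    }
    as.numeric(f)
  }

  if (config$variant == "ga") {
    res <- ga_optimize(wrapped, space, config, gcfg)
  } else {
    swarm <- initialize_swarm(space, config)
    for (i in seq_along(swarm$particles)) {
      swarm <- evaluate_particle(swarm, i, wrapped)
    }
    trace <- swarm$global_best_fitness
    if (config$iterations > 0) {
      for (t in seq_len(config$iterations)) {
        swarm <- pso_step(swarm, wrapped, t - 1L, space, config)
        if (config$variant == "gipso") {
          swarm <- gipso_genetic_step(swarm, space, gcfg)
        }
        trace <- c(trace, swarm$global_best_fitness)
      }
    }
    res <- list(best_position = swarm$global_best,
                best_fitness = swarm$global_best_fitness,
                trace = trace)
  }

  structure(list(best_position = res$best_position,
                 best_fitness = res$best_fitness,
                 best_attributes = counter$best_attrs,
                 trace = res$trace,
                 evaluations_used = counter$n,
                 evaluated_positions = do.call(rbind, counter$positions),
                 variant = config$variant),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("%s: best fitness %.6g after %d evaluations\n",
              x$variant, x$best_fitness, x$evaluations_used))
  invisible(x)
}

# Real-coded GA baseline: tournament selection (k = 2), blend crossover,
# per-parameter mutation, elitism of one (the elite keeps its known fitness,
# so the per-generation evaluation budget matches the swarm variants).
ga_optimize <- function(objective, space, config, gcfg) {
  b <- space_bounds(space)
  n <- config$pop_size
  d <- space$dimension
  pop <- lapply(seq_len(n), function(i) stats::runif(d, b$lo, b$hi))
  fit <- vapply(pop, objective, numeric(1))
  best_i <- which.min(fit)
  best_pos <- pop[[best_i]]
  best_fit <- fit[best_i]
  trace <- best_fit
  if (config$iterations > 0) {
    for (t in seq_len(config$iterations)) {
      elite_pos <- pop[[which.min(fit)]]
      elite_fit <- min(fit)
      tournament <- function() {
        ij <- sample.int(n, 2L, replace = TRUE)
        if (fit[ij[1]] <= fit[ij[2]]) ij[1] else ij[2]
      }
      offspring <- lapply(seq_len(n), function(i) {
        a <- tournament()
        bb <- tournament()
        if (fit[bb] < fit[a]) { tmp <- a; a <- bb; bb <- tmp }
        child <- crossover(pop[[a]], pop[[bb]], pc = gcfg$pc)
        mutate(child, space, gcfg)
      })
      ofit <- vapply(offspring, objective, numeric(1))
      worst <- which.max(ofit)
      if (elite_fit < ofit[worst]) {
        offspring[[worst]] <- elite_pos
        ofit[worst] <- elite_fit
      }
      pop <- offspring
      fit <- ofit
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_pos <- pop[[which.min(fit)]]
      }
      trace <- c(trace, best_fit)
    }
  }
  list(best_position = best_pos, best_fitness = best_fit, trace = trace)
}

#' Standard benchmark objectives for optimizer verification
#'
#' `sphere` is `sum(x^2)`; `rastrigin` is
#' `10 * D + sum(x^2 - 10 * cos(2 * pi * x))`. Both have minimum 0 at the
#' origin.
#'
#' @param name `"sphere"` or `"rastrigin"`.
#' @return A function mapping a numeric vector to its objective value.
#' @export
benchmark_objective <- function(name) {
  switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    stop("unknown benchmark objective: ", name)
  )
}

#' A symmetric box for benchmark objectives
#'
#' @param d Dimension.
#' @param half_width Half-width of the symmetric box (default 5.12, the
#'   conventional Rastrigin domain).
#' @return A `search_space` of `d` continuous dimensions on
#'   `[-half_width, half_width]`.
#' @export
benchmark_space <- function(d, half_width = 5.12) {
  search_space(lapply(seq_len(d), function(i) {
    parameter_spec(paste0("x", i), -half_width, half_width)
  }))
}
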