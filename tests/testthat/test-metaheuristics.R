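space1 <- benchmark_space(1, half_width = 10)

make_one_particle_swarm <- function(position, velocity, pbest, pbest_fit,
                                    gbest, gbest_fit) {
  structure(list(
    particles = list(list(position = position, velocity = velocity,
                          personal_best = pbest,
                          personal_best_fitness = pbest_fit,
                          fitness = pbest_fit)),
    global_best = gbest, global_best_fitness = gbest_fit,
    global_best_index = 1L, iteration = 0L), class = "swarm_state")
}

test_that("inertia weight anneals linearly from w_max to w_min", {
  cfg <- optimizer_config(iterations = 8, w_max = 0.9, w_min = 0.4)
  expect_equal(inertia_weight(0, cfg), 0.9)
  expect_equal(inertia_weight(8, cfg), 0.4)
  expect_equal(inertia_weight(4, cfg), 0.65)
  expect_error(inertia_weight(0, optimizer_config(iterations = 0)), "T = 0")
})

test_that("swarm initialization is seed-deterministic and in bounds", {
  sp <- default_space()
  cfg <- optimizer_config(pop_size = 6)
  s1 <- initialize_swarm(sp, cfg, seed = 3)
  s2 <- initialize_swarm(sp, cfg, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1$particles, 6L)
  lo <- vapply(sp$specs, `[[`, numeric(1), "lower")
  hi <- vapply(sp$specs, `[[`, numeric(1), "upper")
  for (p in s1$particles) {
    expect_true(all(p$position >= lo & p$position <= hi))
    expect_true(is.na(p$fitness))
  }
})

test_that("a particle at rest on the consensus point does not move", {
  sw <- make_one_particle_swarm(position = 2, velocity = 0, pbest = 2,
                                pbest_fit = 4, gbest = 2, gbest_fit = 4)
  out <- pso_step(sw, benchmark_objective("sphere"), 0, space1,
                  optimizer_config(pop_size = 2, iterations = 8))
  expect_equal(out$particles[[1]]$velocity, 0)
  expect_equal(out$particles[[1]]$position, 2)
})

test_that("with zero acceleration and unit inertia the velocity persists", {
  cfg <- optimizer_config(pop_size = 2, iterations = 8, w_max = 1, w_min = 1,
                          c1 = 0, c2 = 0)
  sw <- make_one_particle_swarm(position = 0, velocity = 0.5, pbest = 0,
                                pbest_fit = 0, gbest = 0, gbest_fit = 0)
  out <- pso_step(sw, benchmark_objective("sphere"), 0, space1, cfg)
  expect_equal(out$particles[[1]]$velocity, 0.5)
  expect_equal(out$particles[[1]]$position, 0.5)
})

test_that("one velocity update matches the hand-computed substitution", {
  cfg <- optimizer_config(pop_size = 2, iterations = 8, w_max = 0.9,
                          w_min = 0.4, c1 = 2, c2 = 2, v_max_fraction = 0.1)
  x <- 3; v <- 0.2; pb <- 1; gb <- -2
  set.seed(99)
  r1 <- runif(1); r2 <- runif(1)
  w <- 0.9
  v_expect <- w * v + 2 * r1 * (pb - x) + 2 * r2 * (gb - x)
  v_expect <- max(min(v_expect, 2), -2)  # Vmax = 0.1 * 20
  x_expect <- max(min(x + v_expect, 10), -10)
  sw <- make_one_particle_swarm(position = x, velocity = v, pbest = pb,
                                pbest_fit = 1, gbest = gb, gbest_fit = 4)
  set.seed(99)
  out <- pso_step(sw, benchmark_objective("sphere"), 0, space1, cfg)
  expect_equal(out$particles[[1]]$velocity, v_expect)
  expect_equal(out$particles[[1]]$position, x_expect)
  expect_equal(out$particles[[1]]$fitness, x_expect^2)
})

test_that("blend crossover honors its identity cases", {
  expect_equal(crossover(c(1, 2), c(3, 4), pc = 1, alpha = 0.5), c(2, 3))
  expect_equal(crossover(c(1, 2), c(3, 4), pc = 1, alpha = 1), c(1, 2))
  expect_equal(crossover(c(1, 2), c(3, 4), pc = 1, alpha = 0), c(3, 4))
  set.seed(1)
  expect_equal(crossover(c(1, 2), c(3, 4), pc = 0), c(1, 2))
  expect_error(crossover(1:3, 1:2), "length")
})

test_that("blended children stay in the convex hull of their parents", {
  set.seed(21)
  for (i in 1:100) {
    a <- runif(7, -5, 5); b <- runif(7, -5, 5)
    ch <- crossover(a, b, pc = 0.5)
    expect_true(all(ch >= pmin(a, b) - 1e-12 & ch <= pmax(a, b) + 1e-12))
  }
})

test_that("mutation respects trigger probability, magnitude and bounds", {
  sp <- benchmark_space(1, half_width = 0.5)  # range width 1
  gcfg <- gipso_config(pm = 0)
  expect_equal(mutate(0.2, sp, gcfg), 0.2)
  gcfg1 <- gipso_config(pm = 1, md = 0.1)
  expect_equal(mutate(0.2, sp, gcfg1, rnd = 0.5, sign = 1), 0.25)
  expect_equal(mutate(0.2, sp, gcfg1, rnd = 0.5, sign = -1), 0.15)
  sp7 <- default_space()
  lo <- vapply(sp7$specs, `[[`, numeric(1), "lower")
  hi <- vapply(sp7$specs, `[[`, numeric(1), "upper")
  set.seed(5)
  for (i in 1:1000) {
    pos <- runif(7, lo, hi)
    m <- mutate(pos, sp7, gipso_config(pm = 0.5))
    expect_true(all(m >= lo & m <= hi))
  }
})

test_that("the alternative half-magnitude mutation is available", {
  sp <- benchmark_space(1, half_width = 0.5)
  g <- gipso_config(pm = 1, md = 0.1, half_rnd = TRUE)
  expect_equal(mutate(0.1, sp, g, rnd = 0.4, sign = 1), 0.3)
})

test_that("worst replacement picks the maximal fitness, lowest index first", {
  sw <- initialize_swarm(benchmark_space(2), optimizer_config(pop_size = 3),
                         seed = 1)
  fits <- c(0.1, 0.5, 0.9)
  for (i in 1:3) sw$particles[[i]]$fitness <- fits[i]
  sw$global_best <- sw$particles[[1]]$position
  sw$global_best_fitness <- 0.1
  sw$global_best_index <- 1L
  out <- replace_worst(sw, c(0, 0))
  expect_equal(out$particles[[3]]$position, c(0, 0))
  expect_equal(out$particles[[3]]$velocity, c(0, 0))
  expect_true(is.na(out$particles[[3]]$fitness))
  expect_equal(out$global_best_fitness, 0.1)

  for (i in 1:3) sw$particles[[i]]$fitness <- c(0.9, 0.9, 0.1)[i]
  out2 <- replace_worst(sw, c(1, 1))
  expect_equal(out2$particles[[1]]$position, c(1, 1))
  expect_equal(out2$particles[[2]]$fitness, 0.9)
})

test_that("benchmark objectives have their closed-form values", {
  expect_equal(benchmark_objective("sphere")(c(0, 0)), 0)
  expect_equal(benchmark_objective("rastrigin")(rep(0, 7)), 0)
  expect_equal(benchmark_objective("sphere")(c(1, 1)), 2)
  expect_error(benchmark_objective("ackley"), "unknown")
})

test_that("search runs are deterministic under a fixed seed", {
  sp <- benchmark_space(7)
  for (variant in c("pso", "gipso", "ga")) {
    cfg <- optimizer_config(pop_size = 6, iterations = 8, variant = variant)
    r1 <- optimize_swarm(benchmark_objective("rastrigin"), sp, cfg, seed = 17)
    r2 <- optimize_swarm(benchmark_objective("rastrigin"), sp, cfg, seed = 17)
    expect_identical(r1, r2)
  }
})

test_that("a zero-iteration budget returns the best initial agent", {
  sp <- benchmark_space(3)
  cfg <- optimizer_config(pop_size = 5, iterations = 0)
  res <- optimize_swarm(benchmark_objective("sphere"), sp, cfg, seed = 2)
  expect_equal(res$evaluations_used, 5L)
  expect_length(res$trace, 1L)
  expect_equal(res$best_fitness, min(rowSums(res$evaluated_positions^2)))
})

test_that("all variants spend the same evaluation budget and the trace never rises", {
  sp <- benchmark_space(7)
  budgets <- sapply(c("pso", "gipso", "ga"), function(variant) {
    cfg <- optimizer_config(pop_size = 6, iterations = 8, variant = variant)
    res <- optimize_swarm(benchmark_objective("rastrigin"), sp, cfg, seed = 4)
    expect_true(all(diff(res$trace) <= 1e-12))
    lo <- -5.12; hi <- 5.12
    expect_true(all(res$evaluated_positions >= lo & res$evaluated_positions <= hi))
    res$evaluations_used
  })
  expect_equal(unname(budgets), rep(6L * 9L, 3))
})

test_that("the hybrid search solves the sphere at a generous budget", {
  cfg <- optimizer_config(pop_size = 20, iterations = 100, variant = "gipso")
  res <- optimize_swarm(benchmark_objective("sphere"), benchmark_space(7),
                        cfg, seed = 1)
  expect_lt(res$best_fitness, 1e-2)
})
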