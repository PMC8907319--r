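#' BPSO configuration
#'
#' Parameters of the binary particle swarm: defaults are a swarm of 20
#' particles, learning factors c1 = c2 = 2, 100 generations, and a
#' velocity clamp of |v| <= 6 (bounding per-bit set probabilities to the
#' interval `[sigmoid(-6), sigmoid(6)]`, about 0.25%-99.75%). The inertia
#' weight multiplies the previous velocity; 1.0 is the classic binary-PSO
#' choice.
#'
#' @param swarm_size number of particles (>= 2).
#' @param c1,c2 cognitive and social learning factors (>= 0).
#' @param max_generations number of velocity/position updates per run.
#' @param v_max velocity clamp magnitude (> 0).
#' @param inertia_weight velocity memory coefficient in `[0, 1.2]`.
#' @param seed integer base seed for the run's RNG stream.
#' @return Object of class `bpso_config`.
#' @export
bpso_config <- function(swarm_size = 20L, c1 = 2, c2 = 2,
                        max_generations = 100L, v_max = 6,
                        inertia_weight = 1.0, seed = 1L) {
  stopifnot(swarm_size >= 2, c1 >= 0, c2 >= 0, max_generations >= 1,
            v_max > 0, inertia_weight >= 0, inertia_weight <= 1.2)
  structure(list(swarm_size = as.integer(swarm_size), c1 = c1, c2 = c2,
                 max_generations = as.integer(max_generations),
                 v_max = v_max, inertia_weight = inertia_weight,
                 seed = as.integer(seed)),
            class = "bpso_config")
}

#' Sigmoid transfer function
#'
#' Maps a velocity to a bit-set probability: `1 / (1 + exp(-v))`. Strictly
#' increasing, `sigmoid(0) = 0.5`, saturating smoothly for large `|v|`.
#'
#' @param v numeric vector.
#' @return values in (0, 1).
#' @export
sigmoid <- function(v) 1 / (1 + exp(-v))

# One synchronous BPSO generation. `swarm` is a list with matrices
# `position` (particles x bits, 0/1), `velocity`, `pbest` and vector
# `pbest_fitness`. Velocities: v <- w*v + c1*r1*(pbest-x) + c2*r2*(gbest-x),
# clamped to +-v_max; positions resampled through the sigmoid transfer.
# Consumes the current RNG stream; callers seed it.
bpso_step <- function(swarm, gbest_position, cfg) {
  np <- nrow(swarm$position); nb <- ncol(swarm$position)
  if (length(gbest_position) != nb)
    stop("gbest length must match particle bit count", call. = FALSE)
  r1 <- matrix(stats::runif(np * nb), np, nb)
  r2 <- matrix(stats::runif(np * nb), np, nb)
  g <- matrix(gbest_position, np, nb, byrow = TRUE)
  v <- cfg$inertia_weight * swarm$velocity +
    cfg$c1 * r1 * (swarm$pbest - swarm$position) +
    cfg$c2 * r2 * (g - swarm$position)
  v <- pmin(pmax(v, -cfg$v_max), cfg$v_max)
  u <- matrix(stats::runif(np * nb), np, nb)
  swarm$velocity <- v
  swarm$position <- (u < sigmoid(v)) + 0
  swarm
}

#' Run the binary particle swarm optimizer
#'
#' Minimizes `fitness` over bit vectors of length `n_bits`. Positions are
#' initialized Bernoulli(0.5) per bit, velocities uniform on
#' `[-v_max, v_max]`. Personal and global bests update on strict
#' improvement only (ties keep the incumbent), so the recorded convergence
#' curve of global-best fitness is non-increasing. Fully reproducible from
#' `cfg$seed`.
#'
#' @param fitness function taking a 0/1 vector, returning a finite number
#'   or `Inf`; must be defined for every mask including all-zeros.
#' @param n_bits number of bits.
#' @param cfg a [bpso_config()].
#' @return Object of class `bpso_run`: list with `config`, `n_bits`,
#'   `best_position`, `best_fitness`, `convergence` (length
#'   `max_generations` vector of global-best fitness after each
#'   generation).
#' @examples
#' target <- c(1, 0, 1, 1, 0, 0, 1, 0)
#' run <- run_bpso(function(m) sum(m != target), 8, bpso_config(seed = 7))
#' run$best_fitness
#' @export
run_bpso <- function(fitness, n_bits, cfg = bpso_config()) {
  stopifnot(inherits(cfg, "bpso_config"), n_bits >= 1)
  n_bits <- as.integer(n_bits)
  eval_fitness <- function(mask, gen, part) {
    f <- tryCatch(fitness(mask), error = function(e)
      stop(sprintf("fitness failed at generation %d, particle %d: %s",
                   gen, part, conditionMessage(e)), call. = FALSE))
    if (is.na(f)) stop("fitness returned NA", call. = FALSE)
    as.numeric(f)
  }
  with_seed(cfg$seed, {
    pos <- matrix(stats::rbinom(cfg$swarm_size * n_bits, 1L, 0.5),
                  cfg$swarm_size, n_bits)
    vel <- matrix(stats::runif(cfg$swarm_size * n_bits, -cfg$v_max,
                               cfg$v_max),
                  cfg$swarm_size, n_bits)
    fit <- vapply(seq_len(cfg$swarm_size),
                  function(i) eval_fitness(pos[i, ], 0L, i), numeric(1))
    swarm <- list(position = pos, velocity = vel, pbest = pos,
                  pbest_fitness = fit)
    gbest_i <- which.min(fit)
    gbest <- pos[gbest_i, ]
    gbest_fit <- as.numeric(fit[gbest_i])
    convergence <- numeric(cfg$max_generations)
    for (gen in seq_len(cfg$max_generations)) {
      swarm <- bpso_step(swarm, gbest, cfg)
      for (i in seq_len(cfg$swarm_size)) {
        f <- eval_fitness(swarm$position[i, ], gen, i)
        if (f < swarm$pbest_fitness[i]) {       # strict improvement
          swarm$pbest_fitness[i] <- f
          swarm$pbest[i, ] <- swarm$position[i, ]
          if (f < gbest_fit) {
            gbest_fit <- f
            gbest <- swarm$position[i, ]
          }
        }
      }
      convergence[gen] <- gbest_fit
    }
    structure(list(config = cfg, n_bits = n_bits, best_position = gbest,
                   best_fitness = gbest_fit, convergence = convergence),
              class = "bpso_run")
  })
}

#' @export
print.bpso_run <- function(x, ...) {
  cat(sprintf("bpso_run: %d bits, %d generations, best fitness %.6g (%d bits set)\n",
              x$n_bits, x$config$max_generations, x$best_fitness,
              sum(x$best_position)))
  invisible(x)
}

#' Write convergence curves as CSV
#'
#' One row per (run, generation) with the global-best fitness, the data
#' behind a fitness-versus-iteration convergence plot.
#'
#' @param runs a `bpso_run` or list of them.
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
write_convergence_csv <- function(runs, path) {
  if (inherits(runs, "bpso_run")) runs <- list(runs)
  df <- do.call(rbind, lapply(seq_along(runs), function(i)
    data.frame(run = i,
               generation = seq_along(runs[[i]]$convergence),
               best_fitness = runs[[i]]$convergence)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
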