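# Crow search algorithm: a population metaheuristic for bound-constrained
# minimisation. Each crow keeps a memory of the best position it has
# found. Per iteration a crow picks another crow at random and follows it
# toward its memory (step scaled by a uniform draw times the flight
# length); with probability RP the followed crow notices and the follower
# relocates uniformly at random in the box. Candidates outside the box are
# rejected and the crow keeps its previous position. Memories only ever
# improve, so the best memory fitness is monotone non-increasing.

#' Parameters of the crow search algorithm
#'
#' @param dimension Dimension `d` of the search space.
#' @param lower,upper Box bounds, scalars or length-`d` vectors.
#' @param flock_size Number of crows `N` (>= 2).
#' @param flight_length Step-size multiplier `fl` of the follow move.
#' @param awareness_probability Probability `RP` in `[0, 1]` that a
#'   followed crow is aware and the follower relocates randomly (also
#'   called recognizing probability).
#' @param max_iterations Number of iterations after initialisation.
#' @param seed RNG seed used by [csa_run()].
#' @return An object of class `csa_params`.
#' @export
csa_params <- function(dimension, lower = -5, upper = 5, flock_size = 20,
                       flight_length = 2, awareness_probability = 0.1,
                       max_iterations = 500, seed = 1) {
  p <- structure(list(dimension = as.integer(dimension),
                      lower = rep_len(as.numeric(lower), dimension),
                      upper = rep_len(as.numeric(upper), dimension),
                      flock_size = as.integer(flock_size),
                      flight_length = flight_length,
                      awareness_probability = awareness_probability,
                      max_iterations = as.integer(max_iterations),
                      seed = as.integer(seed)),
                 class = "csa_params")
  stopifnot(p$dimension >= 1, p$flock_size >= 2, p$flight_length >= 0,
            p$awareness_probability >= 0, p$awareness_probability <= 1,
            p$max_iterations >= 0, all(p$lower < p$upper))
  p
}

#' Initialise the flock
#'
#' Positions are drawn uniformly in the box; each crow's memory starts at
#' its position and the memory fitness is evaluated once per crow. Uses the
#' current RNG state (seed management belongs to [csa_run()]).
#'
#' @param params A [csa_params()].
#' @param fitness_fn Function mapping a length-`d` numeric vector to a
#'   finite scalar (minimised).
#' @return An object of class `csa_flock`: `positions`, `memories` (N x d
#'   matrices), `memory_fitness`, `iteration`, `evaluations`.
#' @export
csa_initialize <- function(params, fitness_fn) {
  n <- params$flock_size
  d <- params$dimension
  pos <- matrix(stats::runif(n * d, rep(params$lower, each = n),
                             rep(params$upper, each = n)), n, d)
  fit <- apply(pos, 1, fitness_fn)
  if (!all(is.finite(fit))) {
    stopf("csa_initialize: fitness function returned a non-finite value at an initial position")
  }
  structure(list(positions = pos, memories = pos, memory_fitness = fit,
                 iteration = 0L, evaluations = n),
            class = "csa_flock")
}

#' Advance the flock by one iteration
#'
#' For each crow: draw a target crow `j != i` uniformly; if the awareness
#' draw `r_j >= RP` move to `X_i + r_i * fl * (m_j - X_i)` (scalar `r_i`
#' uniform in (0,1)), otherwise relocate uniformly in the box. A candidate
#' outside the box is infeasible: the crow keeps its previous position.
#' Exactly one fitness evaluation is spent per crow per iteration (on the
#' end-of-iteration position), and the memory is updated whenever that
#' value improves on the memorised one. A non-finite fitness value leaves
#' position and memory untouched, with a warning.
#'
#' @param flock A `csa_flock`.
#' @param params A [csa_params()].
#' @param fitness_fn Objective function (minimised).
#' @return The advanced `csa_flock`.
#' @export
csa_step <- function(flock, params, fitness_fn) {
  n <- params$flock_size
  for (i in seq_len(n)) {
    prev <- flock$positions[i, ]
    j <- sample.int(n - 1, 1)
    if (j >= i) j <- j + 1  # target drawn uniformly over the other crows
    if (stats::runif(1) >= params$awareness_probability) {
      ri <- stats::runif(1)
      cand <- flock$positions[i, ] +
        ri * params$flight_length * (flock$memories[j, ] - flock$positions[i, ])
      if (all(cand >= params$lower & cand <= params$upper)) {
        flock$positions[i, ] <- cand
      }
    } else {
      flock$positions[i, ] <- stats::runif(params$dimension, params$lower,
                                           params$upper)
    }
    fx <- fitness_fn(flock$positions[i, ])
    flock$evaluations <- flock$evaluations + 1L
    if (!is.finite(fx)) {
      flock$positions[i, ] <- prev  # candidate infeasible: the crow stays put
      warning(sprintf("csa_step: non-finite fitness for crow %d; position treated as infeasible", i))
      next
    }
    if (fx < flock$memory_fitness[i]) {
      flock$memories[i, ] <- flock$positions[i, ]
      flock$memory_fitness[i] <- fx
    }
  }
  flock$iteration <- flock$iteration + 1L
  flock
}

#' Run the crow search algorithm
#'
#' Seeds the RNG from `params$seed`, initialises the flock and performs
#' exactly `max_iterations` steps. The incumbent is the best memory, whose
#' fitness is monotone non-increasing over iterations; the total number of
#' fitness evaluations is exactly `flock_size * (max_iterations + 1)`.
#'
#' @param params A [csa_params()].
#' @param fitness_fn Objective function (minimised). To maximise, pass the
#'   negated objective.
#' @return An object of class `csa_result`: `best_position`,
#'   `best_fitness`, `fitness_history` (best memory fitness after each
#'   iteration, length `max_iterations + 1` including initialisation),
#'   `evaluations`, and the final `flock`.
#' @examples
#' res <- csa_run(csa_params(2, lower = -10, upper = 10,
#'                           max_iterations = 100, seed = 42),
#'                function(x) sum(x^2))
#' res$best_fitness
#' @export
csa_run <- function(params, fitness_fn) {
  set.seed(params$seed)
  flock <- csa_initialize(params, fitness_fn)
  history <- numeric(params$max_iterations + 1)
  history[1] <- min(flock$memory_fitness)
  for (it in seq_len(params$max_iterations)) {
    flock <- csa_step(flock, params, fitness_fn)
    history[it + 1] <- min(flock$memory_fitness)
  }
  best <- which.min(flock$memory_fitness)
  structure(list(best_position = flock$memories[best, ],
                 best_fitness = flock$memory_fitness[best],
                 fitness_history = history,
                 evaluations = flock$evaluations,
                 flock = flock),
            class = "csa_result")
}

#' @export
print.csa_result <- function(x, ...) {
  cat(sprintf("CSA result: best fitness %.6g after %d evaluations (d = %d)\n",
              x$best_fitness, x$evaluations, length(x$best_position)))
  invisible(x)
}
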