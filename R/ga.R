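# Genetic-algorithm search over binary DMD masks. Fitness of a mask is the
# correlation-gated, accepted-average peak-to-peak photoacoustic amplitude
# (fitness_single / fitness_two_point).

#' Genetic-algorithm configuration
#'
#' Defaults reproduce the study protocol (50 masks per generation, 80
#' generations, 5 acquisitions per mask) with operator settings chosen to
#' converge within that budget on the 576-segment / 7-mode benchmark:
#' linear-rank parent selection, uniform crossover at rate 0.9, a per-bit
#' mutation rate that decays exponentially from 0.02 to 0.002 with time
#' constant 30 generations (high early exploration, fine late refinement),
#' and 2 elite masks copied unchanged.
#'
#' @param population Masks per generation (>= 2, default 50).
#' @param generations Number of generations (default 80).
#' @param crossover_rate Probability a child undergoes uniform crossover
#'   (default 0.9).
#' @param mutation_rate Per-bit flip probability. A single value gives a
#'   constant rate; a length-2 vector `c(start, end)` gives an exponential
#'   decay between them.
#' @param mutation_decay Time constant (generations) of the decay.
#' @param elitism Number of top masks copied unchanged (default 2,
#'   `< population`).
#' @param n_acq Acquisitions averaged per mask evaluation (default 5).
#' @param seed Integer master seed of the optimization.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 50, generations = 80, crossover_rate = 0.9,
                      mutation_rate = c(0.02, 0.002), mutation_decay = 30,
                      elitism = 2, n_acq = 5, seed = 1L) {
  stopifnot(population >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            all(mutation_rate >= 0), all(mutation_rate <= 1),
            length(mutation_rate) %in% c(1L, 2L),
            elitism >= 0, elitism < population, n_acq >= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_decay = mutation_decay,
                 elitism = as.integer(elitism),
                 n_acq = as.integer(n_acq),
                 seed = as.integer(seed)),
            class = "ga_config")
}

mutation_rate_at <- function(cfg, generation) {
  mr <- cfg$mutation_rate
  if (length(mr) == 1L) return(mr)
  (mr[1] - mr[2]) * exp(-generation / cfg$mutation_decay) + mr[2]
}

#' Initial random population
#'
#' Each mask bit is i.i.d. Bernoulli(1/2), matching the random initial
#' masks of the experiment. Deterministic given the seed.
#'
#' @param cfg A [ga_config()].
#' @param n_segments Mask length.
#' @param seed Integer seed (defaults to the config's).
#' @return A `population x n_segments` 0/1 integer matrix, one mask per row.
#' @export
init_population <- function(cfg, n_segments, seed = cfg$seed) {
  stopifnot(inherits(cfg, "ga_config"), n_segments >= 1)
  with_seed(seed, {
    matrix(as.integer(stats::runif(cfg$population * n_segments) < 0.5),
           nrow = cfg$population, ncol = n_segments)
  })
}

#' One generation step
#'
#' Ranks the population by fitness (descending), copies the `elitism` best
#' masks unchanged, and fills the remainder with children of linear-rank
#' selected parents: uniform crossover with probability `crossover_rate`,
#' then per-bit mutation. High-fitness masks are more likely to be selected
#' as parents; ties keep their input order.
#'
#' @param population 0/1 matrix, one mask per row.
#' @param fitnesses One fitness per mask.
#' @param cfg A [ga_config()].
#' @param generation Generation index (drives the mutation-rate schedule).
#' @param seed Integer seed for this step.
#' @return The next-generation 0/1 matrix, ordered so that the previous
#'   generation's elites come first.
#' @export
ga_step <- function(population, fitnesses, cfg, generation = 1L,
                    seed = cfg$seed) {
  stopifnot(inherits(cfg, "ga_config"), is.matrix(population))
  if (length(fitnesses) != nrow(population)) {
    stop("need exactly one fitness per mask", call. = FALSE)
  }
  pop <- cfg$population
  stopifnot(nrow(population) == pop)
  n <- ncol(population)
  ord <- order(fitnesses, decreasing = TRUE)
  ranked <- population[ord, , drop = FALSE]
  # linear rank weights: best rank gets weight pop, worst gets 1
  w <- pop:1
  mut <- mutation_rate_at(cfg, generation)
  with_seed(seed, {
    nxt <- ranked
    for (i in seq(cfg$elitism + 1L, pop)) {
      pa <- sample.int(pop, 2L, prob = w)
      child <- ranked[pa[1L], ]
      if (stats::runif(1) < cfg$crossover_rate) {
        sw <- stats::runif(n) < 0.5
        child[sw] <- ranked[pa[2L], sw]
      }
      fl <- stats::runif(n) < mut
      child[fl] <- 1L - child[fl]
      nxt[i, ] <- child
    }
    nxt
  })
}

#' Run the closed-loop genetic optimization
#'
#' Evaluates every mask of every generation through the full measurement
#' chain (acquisitions, wavelet denoising, correlation gating,
#' accepted-average peak-to-peak), threading the adaptive template through
#' the run, and evolves the population. Fully reproducible given the
#' config seed.
#'
#' @param world A [pa_world()].
#' @param template A [pa_template()] (see [initial_template()]).
#' @param cfg A [ga_config()].
#' @param wavelet_cfg A [wavelet_config()].
#' @return A `pa_history`: data frame `history` (generation, mean_fitness,
#'   best_fitness, best_so_far), `best_mask`, `best_fitness`, the per-
#'   generation `best_masks` list, the final `template`, and the config.
#' @export
run_ga <- function(world, template, cfg = ga_config(),
                   wavelet_cfg = wavelet_config()) {
  stopifnot(inherits(world, "pa_world"), inherits(template, "pa_template"),
            inherits(cfg, "ga_config"))
  n <- world$tm$n_segments
  population <- init_population(cfg, n, seed = derive_seed(cfg$seed, "init"))
  gens <- cfg$generations
  hist <- data.frame(generation = seq_len(gens), mean_fitness = NA_real_,
                     best_fitness = NA_real_, best_so_far = NA_real_)
  best_masks <- vector("list", gens)
  best_fit <- -Inf
  best_mask <- population[1L, ]
  n_eval <- gens * cfg$population * cfg$n_acq
  det_log <- data.frame(generation = integer(n_eval), mask = integer(n_eval),
                        acq = integer(n_eval), gamma = numeric(n_eval),
                        accepted = logical(n_eval), peak_to_peak = numeric(n_eval))
  row0 <- 0L
  for (g in seq_len(gens)) {
    fits <- numeric(cfg$population)
    for (i in seq_len(cfg$population)) {
      ev <- fitness_single(population[i, ], world, template, wavelet_cfg,
                           n_acq = cfg$n_acq,
                           seed = derive_seed(cfg$seed, "eval", (g - 1L) * cfg$population + i))
      fits[i] <- ev$fitness
      template <- ev$template
      rows <- row0 + seq_len(cfg$n_acq)
      det_log$generation[rows] <- g
      det_log$mask[rows] <- i
      det_log$acq[rows] <- seq_len(cfg$n_acq)
      det_log$gamma[rows] <- ev$gammas
      det_log$accepted[rows] <- ev$accepted
      det_log$peak_to_peak[rows] <- ev$p2ps
      row0 <- row0 + cfg$n_acq
    }
    gb <- which.max(fits)
    if (fits[gb] > best_fit) {
      best_fit <- fits[gb]
      best_mask <- population[gb, ]
    }
    hist$mean_fitness[g] <- mean(fits)
    hist$best_fitness[g] <- fits[gb]
    hist$best_so_far[g] <- best_fit
    best_masks[[g]] <- population[gb, ]
    population <- ga_step(population, fits, cfg, generation = g,
                          seed = derive_seed(cfg$seed, "step", g))
  }
  structure(list(history = hist, best_mask = best_mask, best_fitness = best_fit,
                 best_masks = best_masks, template = template, config = cfg,
                 detections = det_log),
            class = "pa_history")
}

#' @export
print.pa_history <- function(x, ...) {
  h <- x$history
  cat(sprintf("<pa_history> %d generations x %d masks; best fitness %.4g (generation %d)\n",
              nrow(h), x$config$population, x$best_fitness,
              which.max(h$best_so_far == max(h$best_so_far))))
  invisible(x)
}

#' Plot the evolution curves
#'
#' @param x A `pa_history`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pa_history <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$best_so_far, type = "l", lwd = 2,
                 xlab = "generation", ylab = "fitness (peak-to-peak)",
                 ylim = range(c(h$mean_fitness, h$best_so_far)), ...)
  graphics::lines(h$generation, h$mean_fitness, lty = 2)
  graphics::legend("bottomright", c("best so far", "generation mean"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}

#' Noise-free fitness of a mask
#'
#' The deterministic peak-to-peak the mask would produce with the noise and
#' clutter switched off: the yardstick used for enhancement measurements
#' (optimized vs. random-mask ensemble).
#'
#' @param mask Binary mask.
#' @param world A [pa_world()].
#' @param window Optional gate `(start, end)`; defaults to the full record.
#' @return The noiseless gated peak-to-peak.
#' @export
noise_free_fitness <- function(mask, world, window = NULL) {
  w0 <- world
  w0$noise <- noise_spec(sigma = 0, clutter_rate = 0)
  tr <- acquire(mask, w0, seed = 0L)
  y <- if (is.null(window)) tr$samples else tr$samples[window_index(tr, window)]
  max(y) - min(y)
}

#' Random-mask baseline fitness
#'
#' Mean noise-free fitness of `n_masks` fresh Bernoulli(1/2) masks on the
#' same transmission matrix: the denominator of the measured enhancement.
#'
#' @param world A [pa_world()].
#' @param n_masks Ensemble size (default 100).
#' @param seed Integer seed.
#' @param window Optional gate passed to [noise_free_fitness()].
#' @return The ensemble-mean noiseless peak-to-peak.
#' @export
random_mask_baseline <- function(world, n_masks = 100, seed = 0L, window = NULL) {
  n <- world$tm$n_segments
  masks <- with_seed(seed, matrix(as.integer(stats::runif(n_masks * n) < 0.5),
                                  nrow = n_masks))
  mean(apply(masks, 1L, noise_free_fitness, world = world, window = window))
}
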