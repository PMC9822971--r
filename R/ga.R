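#' Genetic-algorithm configuration for breakpoint search
#'
#' @param alpha,beta fitness weights for breakpoint parsimony and average
#'   approximate precision; must satisfy alpha, beta >= 0, alpha + beta = 1.
#' @param population_size number of chromosomes.
#' @param generations iteration cap.
#' @param crossover_rate probability of single-point crossover per pairing.
#' @param mutation_rate per-bit flip probability; `NULL` (default) uses 1/n
#'   for chromosome length n.
#' @param tournament_size selection tournament size.
#' @param elitism number of elite copies of the global best re-injected each
#'   generation.
#' @param fitness_target optional early-stop threshold on best fitness.
#' @param seed RNG seed; same seed and inputs give a bit-identical result.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(alpha = 0.5, beta = 0.5, population_size = 50L,
                      generations = 100L, crossover_rate = 0.8,
                      mutation_rate = NULL, tournament_size = 2L,
                      elitism = 1L, fitness_target = NULL, seed = 1L) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12)
    stop_validation("alpha, beta must be non-negative with alpha + beta = 1")
  if (!is_count(population_size) || !is_count(generations) ||
      !is_count(tournament_size) || !is_count(elitism))
    stop_validation("population_size, generations, tournament_size, elitism must be positive integers")
  if (population_size < elitism)
    stop_validation("population_size must be >= elitism")
  structure(list(alpha = alpha, beta = beta,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 fitness_target = fitness_target,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Rough-fuzzy fitness of a discretization scheme
#'
#' `Fitness = alpha * (N_CB - N_DS) / N_CB + beta * eta_bar(scheme)` where
#' N_CB is the candidate count and N_DS the number of selected breakpoints:
#' parsimony (fewer cuts) traded against approximation precision.
#'
#' @param scheme a [discretization_scheme()].
#' @param u a [run_fcm()] result.
#' @param table the decision table.
#' @param alpha,beta non-negative weights summing to 1.
#' @return fitness in `[0, 1]`.
#' @export
scheme_fitness <- function(scheme, u, table, alpha = 0.5, beta = 0.5) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12)
    stop_validation("alpha, beta must be non-negative with alpha + beta = 1")
  n_cb <- scheme$candidates$n
  if (n_cb < 1) stop_validation("scheme has no candidate breakpoints")
  n_ds <- sum(scheme$selected)
  alpha * (n_cb - n_ds) / n_cb + beta * eta_bar(u, table, scheme)
}

#' Genetic-algorithm search for the best discretization scheme
#'
#' Binary chromosomes over the candidate breakpoints (1 = cut selected) are
#' evolved by tournament selection, single-point crossover and per-bit
#' mutation, with elitist re-injection of the global best. The initial
#' population contains the all-zero and all-one chromosomes, so the result
#' is never worse than either limiting scheme. Fitness values are cached by
#' chromosome, since eta_bar dominates the cost.
#'
#' @param table decision table.
#' @param u fuzzy memberships from [run_fcm()].
#' @param candidates candidate breakpoints (default: extracted from `table`).
#' @param config a [ga_config()].
#' @return object of class `ga_result`: `best_scheme`, `best_fitness`,
#'   `eta_bar`, `history` (per-generation best, non-decreasing),
#'   `generations_run`, `stopped_early`, `config`.
#' @export
ga_discretize <- function(table, u, candidates = NULL, config = ga_config()) {
  stopifnot(inherits(table, "decision_table"), inherits(u, "membership_matrix"),
            inherits(config, "ga_config"))
  if (is.null(candidates)) candidates <- extract_candidate_breakpoints(table)
  n <- candidates$n
  if (n < 1) stop_validation("no candidate breakpoints")
  pmut <- config$mutation_rate %||% (1 / n)
  pop_n <- config$population_size

  cache <- new.env(parent = emptyenv())
  fit_of <- function(bits) {
    key <- paste(as.integer(bits), collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- scheme_fitness(discretization_scheme(candidates, bits),
                        u, table, config$alpha, config$beta)
    cache[[key]] <- f
    f
  }

  with_seed(config$seed, {
    pop <- matrix(runif(pop_n * n) < 0.5, nrow = pop_n)
    pop[1, ] <- FALSE                      # empty scheme
    if (pop_n >= 2) pop[2, ] <- TRUE       # all-selected scheme
    fit <- apply(pop, 1, fit_of)
    best_bits <- pop[which.max(fit), ]
    best_fit <- max(fit)
    history <- numeric(0)
    gens <- 0L
    stopped <- FALSE

    for (g in seq_len(config$generations)) {
      gens <- g
      ## tournament selection of parents
      pick <- function() {
        cand <- sample.int(pop_n, config$tournament_size, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      newpop <- matrix(FALSE, pop_n, n)
      for (i in seq(1, pop_n, by = 2)) {
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (n > 1 && runif(1) < config$crossover_rate) {
          cut <- sample.int(n - 1L, 1L)
          c1 <- c(p1[1:cut], p2[(cut + 1L):n])
          c2 <- c(p2[1:cut], p1[(cut + 1L):n])
        } else { c1 <- p1; c2 <- p2 }
        newpop[i, ] <- c1
        if (i + 1L <= pop_n) newpop[i + 1L, ] <- c2
      }
      ## per-bit mutation
      flip <- matrix(runif(pop_n * n) < pmut, pop_n, n)
      newpop <- xor(newpop, flip)
      ## elitism: re-inject the global best
      for (e in seq_len(config$elitism)) newpop[e, ] <- best_bits
      pop <- newpop
      fit <- apply(pop, 1, fit_of)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_bits <- pop[which.max(fit), ]
      }
      history <- c(history, best_fit)
      if (!is.null(config$fitness_target) && best_fit >= config$fitness_target) {
        stopped <- TRUE
        break
      }
    }

    best_scheme <- discretization_scheme(candidates, best_bits)
    structure(list(best_scheme = best_scheme,
                   best_fitness = best_fit,
                   eta_bar = eta_bar(u, table, best_scheme),
                   history = history,
                   generations_run = gens,
                   stopped_early = stopped,
                   config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: %d/%d breakpoints, fitness %.6f (eta_bar %.6f) after %d generations%s\n",
              sum(x$best_scheme$selected), x$best_scheme$candidates$n,
              x$best_fitness, x$eta_bar, x$generations_run,
              if (x$stopped_early) " [early stop]" else ""))
  invisible(x)
}

#' Exhaustive scheme search (oracle for small candidate sets)
#'
#' Enumerates all 2^n schemes; intended for n <= 20.
#'
#' @inheritParams ga_discretize
#' @param alpha,beta fitness weights.
#' @return list with `best_scheme`, `best_fitness`, `fitness` (per scheme).
#' @export
exhaustive_discretize <- function(table, u, candidates = NULL,
                                  alpha = 0.5, beta = 0.5) {
  if (is.null(candidates)) candidates <- extract_candidate_breakpoints(table)
  n <- candidates$n
  if (n > 20) stop_validation("exhaustive search limited to n <= 20 candidates")
  best_f <- -Inf; best_bits <- NULL
  fits <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1L)), 1L))
    f <- scheme_fitness(discretization_scheme(candidates, bits),
                        u, table, alpha, beta)
    fits[code + 1] <- f
    if (f > best_f) { best_f <- f; best_bits <- bits }
  }
  list(best_scheme = discretization_scheme(candidates, best_bits),
       best_fitness = best_f, fitness = fits)
}

#' Apply a discretization scheme to an image
#'
#' Replaces every pixel by a representative of its interval: the 0-based
#' interval `index`, the interval `midpoint` (cut midpoints, with the outer
#' intervals represented by the adjacent cut), or the `interval_mean` -- the
#' mean observed brightness of the interval in a fitting table, rescaled to
#' `[0, 1]` for network input (the default network-facing encoding).
#'
#' @param image numeric matrix/array.
#' @param scheme a [discretization_scheme()].
#' @param encoding one of `"index"`, `"midpoint"`, `"interval_mean"`.
#' @param table fitting decision table, required for `interval_mean`.
#' @param rescale logical; rescale `interval_mean` output to `[0, 1]` using
#'   the table's value range (default TRUE).
#' @return grid of the same shape, constant within equivalence classes.
#' @export
apply_scheme <- function(image, scheme,
                         encoding = c("interval_mean", "index", "midpoint"),
                         table = NULL, rescale = TRUE) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(scheme, "discretization_scheme"))
  dm <- dim(image)
  v <- as.numeric(image)
  idx <- interval_index(v, scheme)
  cuts <- scheme$cuts
  k <- length(cuts)
  out <- switch(encoding,
    index = as.numeric(idx),
    midpoint = {
      if (k == 0) rep(mean(range(v)), length(v)) else {
        reps <- c(cuts[1], if (k > 1) (cuts[-k] + cuts[-1]) / 2, cuts[k])
        reps[idx + 1L]
      }
    },
    interval_mean = {
      if (is.null(table))
        stop_validation("encoding 'interval_mean' requires the fitting table")
      tix <- interval_index(table$brightness, scheme)
      means <- tapply(table$brightness, tix, mean)
      reps <- rep(NA_real_, k + 1L)
      reps[as.integer(names(means)) + 1L] <- as.numeric(means)
      ## intervals unseen in the fitting table: fall back to cut midpoints
      if (anyNA(reps)) {
        mid <- if (k == 0) mean(table$value_range) else
          c(cuts[1], if (k > 1) (cuts[-k] + cuts[-1]) / 2, cuts[k])
        reps[is.na(reps)] <- mid[is.na(reps)]
      }
      val <- reps[idx + 1L]
      if (rescale) {
        vr <- table$value_range
        val <- (val - vr[1]) / (vr[2] - vr[1])
      }
      val
    })
  if (!is.null(dm)) dim(out) <- dm
  out
}
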