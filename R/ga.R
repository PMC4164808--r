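#' Genetic-algorithm settings
#'
#' Defaults follow the optimization settings used for the packaged
#' dataset: chromosome length 36 (6 bits per factor over 6 factors),
#' population 36, crossover probability 0.8, per-bit mutation probability
#' 0.01, 500 generations, elitism 1.
#'
#' @param chromosome_length Total bits per chromosome; must equal
#'   `bits_per_factor * n_factors` at run time.
#' @param population_size Individuals per generation.
#' @param crossover_prob Probability a mating pair undergoes single-point
#'   crossover.
#' @param mutation_prob Per-bit flip probability.
#' @param max_generations Generations to run.
#' @param bits_per_factor Bits encoding each factor (6 bits -> 64 levels).
#' @param elitism Number of best individuals copied unchanged into the
#'   next generation (>= 1 keeps the best-fitness trace non-decreasing).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(chromosome_length = 36, population_size = 36,
                       crossover_prob = 0.8, mutation_prob = 0.01,
                       max_generations = 500, bits_per_factor = 6,
                       elitism = 1, seed = 1) {
  check_that(population_size >= 2, "`population_size` must be >= 2")
  check_that(crossover_prob >= 0 && crossover_prob <= 1 &&
               mutation_prob >= 0 && mutation_prob <= 1,
             "probabilities must lie in [0, 1]")
  check_that(elitism >= 0 && elitism <= population_size,
             "`elitism` must be in [0, population_size]")
  check_that(max_generations >= 1, "`max_generations` must be >= 1")
  structure(list(chromosome_length = chromosome_length,
                 population_size = population_size,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 max_generations = max_generations,
                 bits_per_factor = bits_per_factor,
                 elitism = elitism, seed = seed),
            class = "ga_control")
}

#' Decode a binary chromosome to natural factor settings
#'
#' Each consecutive `bits_per_factor`-bit field (most-significant bit
#' first) is read as an integer `b` in `0 .. 2^bits - 1` and mapped
#' linearly onto the factor's axial range:
#' `low + (high - low) * b / (2^bits - 1)`. The all-zero chromosome
#' decodes to every factor at its low bound, the all-one chromosome to
#' every high bound; decoded settings can never leave the factor box.
#'
#' @param bits A 0/1 vector of length `bits_per_factor * n_factors`, or a
#'   matrix with one chromosome per row.
#' @param factors A factor tibble (see [factor_spec()]).
#' @param bits_per_factor Bits per factor field (default 6).
#' @return A tibble of natural-unit settings, one row per chromosome.
#' @examples
#' decode_chromosome(rep(0, 36), alpha_gal_factors())
#' @export
decode_chromosome <- function(bits, factors, bits_per_factor = 6) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  k <- nrow(factors)
  check_that(ncol(bits) == bits_per_factor * k,
             sprintf("chromosome length %d != %d bits x %d factors",
                     ncol(bits), bits_per_factor, k))
  check_that(all(bits %in% c(0, 1)), "chromosome bits must be 0 or 1")
  denom <- 2^bits_per_factor - 1
  weights <- 2^((bits_per_factor - 1):0)
  nat <- vapply(seq_len(k), function(i) {
    field <- bits[, (i - 1L) * bits_per_factor + seq_len(bits_per_factor),
                  drop = FALSE]
    b <- drop(field %*% weights)
    factors$low[i] + (factors$high[i] - factors$low[i]) * b / denom
  }, numeric(nrow(bits)))
  if (is.null(dim(nat))) nat <- matrix(nat, nrow = 1L)
  as_tibble(as.data.frame(nat), .name_repair = ~ factors$name)
}

#' Fitness of a chromosome under the trained network
#'
#' Decodes the chromosome to natural units, scales the settings with the
#' model's input scaler and evaluates the network forward pass written out
#' from its weights and biases
#' (`output_weights . (2 / (1 + exp(-2 (hidden_weights x + input_bias))) - 1)
#' + output_bias`). The fitness is the scaled network output, an
#' increasing affine image of the predicted activity, so ranking by
#' fitness is ranking by predicted U/mL.
#'
#' @param model An `activity_model` (or a list with `fit$params`,
#'   `scaler_x`, `factors`).
#' @param bits A chromosome 0/1 vector or a matrix of chromosomes (rows).
#' @param bits_per_factor Bits per factor field (default 6).
#' @return Numeric fitness vector (scaled network output, one per row).
#' @export
evaluate_fitness <- function(model, bits, bits_per_factor = 6) {
  nat <- decode_chromosome(bits, model$factors, bits_per_factor)
  xs <- as.matrix(scaler_transform(model$scaler_x, nat))
  ffnn_forward(model$fit$params, xs)
}

#' Maximize predicted activity with a binary genetic algorithm
#'
#' Evolves a population of binary chromosomes encoding fermentation
#' conditions: fitness-proportional (roulette-wheel) selection on
#' min-shifted fitness, single-point crossover with probability
#' `crossover_prob`, per-bit flip mutation with probability
#' `mutation_prob`, and elitism. Every evaluated individual is archived,
#' and the shortlist of the `top_k` best *distinct* decoded conditions is
#' reported alongside the single best.
#'
#' @param model An `activity_model` from [fit_activity_model()].
#' @param control A [ga_control()] list; `chromosome_length` must equal
#'   `bits_per_factor * nrow(model$factors)`.
#' @param top_k Size of the best-conditions shortlist (default 4).
#' @return A `ga_result`: `best_bits`, `best_conditions` (one-row tibble,
#'   natural units), `best_predicted_activity` (U/mL), `best_fitness`
#'   (scaled), `trace` (per-generation best/mean fitness and best-ever
#'   predicted activity), `top_conditions` (tibble of `top_k` distinct
#'   conditions with predicted activity), `control`.
#' @examples
#' \donttest{
#' m <- fit_activity_model(alpha_gal_design(),
#'                         control = lm_control(n_restarts = 2, seed = 7))
#' opt <- ga_evolve(m, ga_control(max_generations = 50, seed = 1))
#' opt$best_predicted_activity
#' }
#' @export
ga_evolve <- function(model, control = ga_control(), top_k = 4) {
  k <- nrow(model$factors)
  bpf <- control$bits_per_factor
  len <- control$chromosome_length
  check_that(len == bpf * k,
             sprintf("chromosome_length %d != bits_per_factor %d x %d factors",
                     len, bpf, k))
  pop_size <- control$population_size
  set.seed(control$seed)

  pop <- matrix(sample(c(0, 1), pop_size * len, replace = TRUE), pop_size, len)
  archive_bits <- list()
  archive_fit <- numeric(0)
  best_bits <- NULL
  best_fit <- -Inf
  trace <- vector("list", control$max_generations)

  for (gen in seq_len(control$max_generations)) {
    fit <- evaluate_fitness(model, pop, bpf)
    archive_bits[[gen]] <- pop
    archive_fit <- c(archive_fit, fit)
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit) {
      best_fit <- fit[gen_best]
      best_bits <- pop[gen_best, ]
    }
    trace[[gen]] <- c(gen, max(fit), mean(fit), best_fit)
    if (gen == control$max_generations) break

    # next generation: elites first, then roulette-selected offspring
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(control$elitism)]
    shifted <- fit - min(fit)
    prob <- if (sum(shifted) > 0) shifted / sum(shifted)
            else rep(1 / pop_size, pop_size)
    n_children <- pop_size - control$elitism
    children <- matrix(0, n_children, len)
    filled <- 0L
    while (filled < n_children) {
      parents <- sample.int(pop_size, 2L, replace = TRUE, prob = prob)
      c1 <- pop[parents[1], ]
      c2 <- pop[parents[2], ]
      if (runif(1) < control$crossover_prob) {
        cut <- sample.int(len - 1L, 1L)
        tail1 <- c1[(cut + 1L):len]
        c1[(cut + 1L):len] <- c2[(cut + 1L):len]
        c2[(cut + 1L):len] <- tail1
      }
      for (child in list(c1, c2)) {
        if (filled >= n_children) break
        flip <- runif(len) < control$mutation_prob
        child[flip] <- 1 - child[flip]
        filled <- filled + 1L
        children[filled, ] <- child
      }
    }
    pop <- rbind(pop[elite_idx, , drop = FALSE], children)
  }

  trace <- as_tibble(as.data.frame(do.call(rbind, trace)),
                     .name_repair = ~ c("generation", "best_fitness",
                                        "mean_fitness", "best_ever_fitness"))
  trace$best_ever_activity <- scaler_inverse(model$scaler_y,
                                             trace$best_ever_fitness)

  all_bits <- do.call(rbind, archive_bits)
  top <- top_conditions(model, all_bits, archive_fit, bpf, top_k)

  structure(
    list(best_bits = best_bits,
         best_conditions = decode_chromosome(best_bits, model$factors, bpf),
         best_fitness = best_fit,
         best_predicted_activity = scaler_inverse(model$scaler_y, best_fit),
         trace = trace,
         top_conditions = top,
         control = control),
    class = "ga_result"
  )
}

# Distinct decoded conditions, best first, across the evaluation archive.
top_conditions <- function(model, bits, fit, bits_per_factor, top_k) {
  ord <- order(fit, decreasing = TRUE)
  # dedupe on the decoded integer fields, not raw bits: two chromosomes with
  # equal fields are the same condition
  nat <- decode_chromosome(bits[ord, , drop = FALSE], model$factors,
                           bits_per_factor)
  keep <- !duplicated(nat)
  idx <- which(keep)[seq_len(min(top_k, sum(keep)))]
  out <- nat[idx, , drop = FALSE]
  out$predicted_U_per_mL <- scaler_inverse(model$scaler_y, fit[ord][idx])
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best predicted activity %.3f U/mL after %d generations\n",
              x$best_predicted_activity, max(x$trace$generation)))
  print(x$top_conditions)
  invisible(x)
}

#' Tidy and summarize a GA run
#'
#' `tidy()` returns the per-generation trace; `glance()` a one-row summary
#' with the best fitness, predicted activity and settings used.
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) x$trace

#' @rdname tidy.ga_result
#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble(generations = max(x$trace$generation),
         population_size = x$control$population_size,
         crossover_prob = x$control$crossover_prob,
         mutation_prob = x$control$mutation_prob,
         best_fitness = x$best_fitness,
         best_predicted_activity = x$best_predicted_activity)
}

#' Plot a GA fitness trace
#'
#' Best-ever predicted activity (U/mL) and per-generation mean fitness
#' across generations.
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_ever_activity)) +
    ggplot2::labs(x = "generation", y = "best predicted activity (U/mL)",
                  title = "GA convergence")
}
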