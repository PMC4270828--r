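# Heuristic search over the 25^6 function combinations: random search and a
# generational genetic algorithm over 30-bit encodings (6 slots x 5 bits,
# each field decoded modulo 25), maximising the pure three-way interaction
# information of (TF1, TF2, enhancer) on a dataset simulated from the
# decoded model.

#' Decode a 30-bit encoding into six function names
#'
#' Each consecutive 5-bit field (least-significant bit first) is read as an
#' integer 0--31 and mapped to a function index modulo 25, so every encoding
#' decodes to a valid model.
#'
#' @param bits Integer/logical vector of 30 bits.
#' @return Character vector of six canonical function names.
#' @export
decode_functions <- function(bits) {
  stopifnot(length(bits) == 30, all(bits %in% c(0, 1)))
  vals <- vapply(0:5, function(s) {
    sum(bits[s * 5 + 1:5] * 2^(0:4))
  }, numeric(1))
  .fn_names[(vals %% 25) + 1]
}

#' Search configuration
#'
#' @param pop_size GA population size `m` (>= 2).
#' @param generations Number of GA generations `l` (>= 1); the search
#'   evaluates at most `m * l` models.
#' @param mutation_rate Per-bit flip probability.
#' @param crossover_rate Probability that an offspring is produced by
#'   uniform crossover of two tournament-selected parents.
#' @param elitism Number of best individuals copied unchanged (with their
#'   realised fitness) into the next generation.
#' @param tournament_size Tournament size for parent selection.
#' @param n_cases,n_controls Case-control sizes of the dataset simulated for
#'   each fitness evaluation.
#' @param prevalence Target disease prevalence for each fitness evaluation.
#' @return A list of class `search_config`.
#' @export
search_config <- function(pop_size = 100, generations = 100,
                          mutation_rate = 1 / 30, crossover_rate = 0.9,
                          elitism = 1, tournament_size = 2,
                          n_cases = 1000, n_controls = 1000,
                          prevalence = 0.1) {
  stopifnot(
    pop_size >= 2, generations >= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    crossover_rate >= 0, crossover_rate <= 1,
    elitism >= 0, elitism <= pop_size, tournament_size >= 1,
    n_cases >= 1, n_controls >= 1, prevalence > 0, prevalence < 1
  )
  structure(
    list(
      pop_size = pop_size, generations = generations,
      mutation_rate = mutation_rate, crossover_rate = crossover_rate,
      elitism = elitism, tournament_size = tournament_size,
      n_cases = n_cases, n_controls = n_controls, prevalence = prevalence
    ),
    class = "search_config"
  )
}

# exact joint over all 3^6 * 5 = 3,645 input combinations, with liability
.model_joint <- function(model) {
  grid <- do.call(expand.grid, lapply(model$loci, function(d) d$value))
  names(grid) <- names(model$loci)
  p <- rep(1, nrow(grid))
  for (nm in names(model$loci)) {
    d <- model$loci[[nm]]
    p <- p * d$prob[match(grid[[nm]], d$value)]
  }
  grid$prob <- p
  grid$liability <- liability(model, grid)
  grid
}

# Case-control sample drawn directly from the exact conditional
# distributions P(genotypes | status) implied by the model and threshold:
# the infinite-population limit of population-then-sample. Used by the
# search fitness, where one dataset is simulated per candidate model.
.sample_exact <- function(model, threshold, n_cases, n_controls) {
  joint <- .model_joint(model)
  case_rows <- joint$liability >= threshold
  draw <- function(rows, n) {
    w <- joint$prob[rows]
    idx <- which(rows)[sample.int(sum(rows), n, replace = TRUE, prob = w)]
    joint[idx, .locus_names[1:6]]
  }
  out <- rbind(draw(case_rows, n_cases), draw(!case_rows, n_controls))
  out$Class <- rep(c(1L, 0L), c(n_cases, n_controls))
  tibble::as_tibble(out)
}

#' Fitness of a function combination
#'
#' Builds the hierarchical model for the six functions, selects the disease
#' threshold at the configured prevalence on the exact liability
#' distribution, simulates a single case-control dataset, and returns the
#' pure three-way interaction information of (TF1, TF2, enhancer). Models
#' whose liability distribution is a single point (no two-class split)
#' receive fitness `-Inf`.
#'
#' @param functions Character vector of six function names.
#' @param config A [search_config()].
#' @param seed Optional integer seed for the simulated dataset.
#' @return A single numeric fitness value (bits), or `-Inf`.
#' @export
search_fitness <- function(functions, config = search_config(), seed = NULL) {
  model <- hierarchy_model(functions)
  ld <- liability_distribution(model)
  if (nrow(ld$dist) < 2) return(-Inf)
  th <- select_threshold(ld$dist, config$prevalence)
  dataset <- with_seed_(
    seed,
    .sample_exact(model, th$threshold, config$n_cases, config$n_controls)
  )
  interaction_information(dataset, c("TF1", "TF2", "enhancer"))$threeway_ig
}

.rank_hof <- function(hof) {
  hof <- dplyr::arrange(hof, dplyr::desc(.data$fitness))
  hof$rank <- seq_len(nrow(hof))
  dplyr::relocate(hof, "rank")
}

.bits_tbl <- function(pop, fitness, generation) {
  fn <- t(vapply(pop, decode_functions, character(6)))
  colnames(fn) <- paste0("f", 1:6)
  out <- tibble::as_tibble(fn)
  out$fitness <- fitness
  out$generation <- generation
  out$encoding <- vapply(pop, paste, character(1), collapse = "")
  out
}

#' Random search over function combinations
#'
#' Draws `n` independent 30-bit encodings, evaluates each with
#' [search_fitness()], and returns the models ranked by fitness.
#'
#' @param n Number of models to evaluate.
#' @param config A [search_config()] (its GA fields are ignored).
#' @param seed Optional integer seed; the full ranking is reproducible.
#' @return A tibble with columns `rank`, `f1`..`f6`, `fitness`, `generation`
#'   (all 1) and `encoding`.
#' @export
random_search <- function(n, config = search_config(), seed = NULL) {
  stopifnot(n >= 1)
  with_seed_(seed, {
    pop <- lapply(seq_len(n), function(i) sample(0:1, 30, replace = TRUE))
    fit <- vapply(pop, function(b) {
      search_fitness(decode_functions(b), config,
                     seed = sample.int(2^31 - 2, 1))
    }, numeric(1))
    .rank_hof(.bits_tbl(pop, fit, 1L))
  })
}

#' Genetic-algorithm search over function combinations
#'
#' Generational GA on 30-bit encodings: tournament selection, uniform
#' crossover, per-bit mutation, and elitism (elite individuals keep their
#' realised fitness, so the best-so-far trace is non-decreasing). Every
#' non-elite offspring is re-evaluated, and the total number of fitness
#' evaluations never exceeds `pop_size * generations`.
#'
#' @param config A [search_config()].
#' @param seed Optional integer seed.
#' @return An object of class `ga_search`: `hall_of_fame` (all evaluated
#'   models ranked by fitness), `trace` (per-generation best and
#'   best-so-far), `n_evaluations` and `config`.
#' @export
ga_search <- function(config = search_config(), seed = NULL) {
  stopifnot(inherits(config, "search_config"))
  m <- config$pop_size
  with_seed_(seed, {
    pop <- lapply(seq_len(m), function(i) sample(0:1, 30, replace = TRUE))
    fit <- vapply(pop, function(b) {
      search_fitness(decode_functions(b), config,
                     seed = sample.int(2^31 - 2, 1))
    }, numeric(1))
    n_eval <- m
    hof <- .bits_tbl(pop, fit, 1L)
    trace <- tibble::tibble(
      generation = 1L, best = max(fit), best_so_far = max(fit)
    )
    select_parent <- function() {
      cand <- sample.int(m, min(config$tournament_size, m))
      cand[which.max(fit[cand])]
    }
    for (gen in seq_len(config$generations - 1)) {
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(config$elitism)]
      new_pop <- pop[elite_idx]
      new_fit <- fit[elite_idx]
      n_new <- m - config$elitism
      if (n_new > 0) {
        children <- lapply(seq_len(n_new), function(i) {
          p1 <- pop[[select_parent()]]
          child <- if (stats::runif(1) < config$crossover_rate) {
            p2 <- pop[[select_parent()]]
            mask <- sample(0:1, 30, replace = TRUE) == 1
            ifelse(mask, p1, p2)
          } else {
            p1
          }
          flip <- stats::runif(30) < config$mutation_rate
          child[flip] <- 1 - child[flip]
          child
        })
        child_fit <- vapply(children, function(b) {
          search_fitness(decode_functions(b), config,
                         seed = sample.int(2^31 - 2, 1))
        }, numeric(1))
        n_eval <- n_eval + n_new
        hof <- dplyr::bind_rows(hof, .bits_tbl(children, child_fit, gen + 1L))
        new_pop <- c(new_pop, children)
        new_fit <- c(new_fit, child_fit)
      }
      pop <- new_pop
      fit <- new_fit
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        generation = gen + 1L, best = max(fit),
        best_so_far = max(max(fit), trace$best_so_far[nrow(trace)])
      ))
    }
    structure(
      list(
        hall_of_fame = .rank_hof(hof), trace = trace,
        n_evaluations = n_eval, config = config
      ),
      class = "ga_search"
    )
  })
}

#' @export
print.ga_search <- function(x, ...) {
  best <- x$hall_of_fame[1, ]
  cat("GA search: ", x$n_evaluations, " fitness evaluations over ",
      max(x$trace$generation), " generations\n", sep = "")
  cat("  best model: ", paste(unlist(best[paste0("f", 1:6)]), collapse = ", "),
      "  (three-way IG ", signif(best$fitness, 4), " bits)\n", sep = "")
  invisible(x)
}

#' @rdname ga_search
#' @param object A `ga_search` object.
#' @param ... Unused.
#' @method autoplot ga_search
#' @export
autoplot.ga_search <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace, c("best", "best_so_far"),
                           names_to = "series", values_to = "fitness")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "three-way IG (bits)",
                  linetype = NULL)
}

#' @rdname ga_search
#' @param x A `ga_search` object.
#' @method tidy ga_search
#' @export
tidy.ga_search <- function(x, ...) x$hall_of_fame

#' @rdname ga_search
#' @method glance ga_search
#' @export
glance.ga_search <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$hall_of_fame$fitness[1],
    n_evaluations = x$n_evaluations,
    generations = max(x$trace$generation),
    pop_size = x$config$pop_size
  )
}
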