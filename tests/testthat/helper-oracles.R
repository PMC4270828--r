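# Independent oracles used across the suite.

# Exhaustive-enumeration oracle for the liability distribution: evaluates
# the chain on all 3^6 * 5 = 3,645 input combinations with their product
# probabilities, independently of the chain-folding implementation.
enumerate_liability <- function(model) {
  grid <- expand.grid(
    TF1 = 0:2, TF2 = 0:2, enhancer = 0:2, promoter = 0:2, coding = 0:2,
    microRNA = 0:2, environment = -2:2
  )
  p <- rep(1, nrow(grid))
  for (nm in names(model$loci)) {
    d <- model$loci[[nm]]
    p <- p * d$prob[match(grid[[nm]], d$value)]
  }
  out <- liability(model, grid)
  agg <- tapply(p, out, sum)
  vals <- as.numeric(names(agg))
  o <- order(vals)
  tibble::tibble(value = vals[o], prob = as.numeric(agg)[o])
}

# Brute-force double-loop plug-in mutual information (bits) over a 2-column
# contingency table, independent of the table/entropy-based implementation.
brute_mi <- function(x, y) {
  xs <- unique(x)
  ys <- unique(y)
  n <- length(x)
  mi <- 0
  for (u in xs) {
    for (v in ys) {
      pxy <- sum(x == u & y == v) / n
      if (pxy > 0) {
        mi <- mi + pxy * log2(pxy / (sum(x == u) / n * sum(y == v) / n))
      }
    }
  }
  mi
}

# a random model drawn uniformly over the 25^6 function combinations
random_model <- function() {
  hierarchy_model(sample(math_functions()$name, 6, replace = TRUE))
}

sim_dataset <- function(model, n_cases = 500, n_controls = 500,
                        pop = 20000, prevalence = 0.1, seed = 1) {
  pop <- simulate_population(model, pop, prevalence = prevalence, seed = seed)
  sample_case_control(pop, n_cases, n_controls, seed = seed + 1L)
}
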