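# Workflow layer: YAML model/run configuration, the three pipeline verbs
# (simulate, search, evaluate) used by the command-line script in
# inst/cli/epistasim.R, and the bundled toy fixtures.

#' Read / write a model specification file
#'
#' A model specification is a small YAML document with the six chain
#' functions, optional per-locus distributions and a target prevalence; the
#' round trip through a file is lossless.
#'
#' @param model A [hierarchy_model()].
#' @param path File path.
#' @param prevalence Optional target prevalence stored with the model.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns a list with `model` and `prevalence`.
#' @export
write_model_config <- function(model, path, prevalence = NULL) {
  stopifnot(inherits(model, "hierarchy_model"))
  spec <- list(
    functions = as.list(model$functions),
    loci = lapply(model$loci, function(d) {
      list(values = as.numeric(d$value), probs = as.numeric(d$prob))
    })
  )
  if (!is.null(prevalence)) spec$prevalence <- prevalence
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$functions)) {
    stop("Model config ", path, ": missing `functions`.", call. = FALSE)
  }
  loci <- if (is.null(spec$loci)) {
    default_loci()
  } else {
    lapply(spec$loci, function(l) discrete_dist(l$values, l$probs))
  }
  list(
    model = hierarchy_model(unlist(spec$functions), loci = loci),
    prevalence = spec$prevalence
  )
}

.validate_run <- function(pop_size, prevalence, n_cases, n_controls,
                          noise_snps, maf_range) {
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("config$prevalence: must be in (0, 1), got ", prevalence,
         call. = FALSE)
  }
  if (pop_size < n_cases + n_controls) {
    stop("config$pop_size: smaller than requested sample.", call. = FALSE)
  }
  if (noise_snps > 0 &&
      (length(maf_range) != 2 || maf_range[1] <= 0 ||
       maf_range[1] > maf_range[2] || maf_range[2] > 0.5)) {
    stop("config$maf_range: must satisfy 0 < low <= high <= 0.5.",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate replicate case-control datasets from a model
#'
#' Runs the full generation workflow: exact liability distribution and
#' threshold, population simulation, case-control sampling, optional noise
#' SNPs, and (optionally) MDR-format files plus a JSON run report holding
#' the per-value liability probabilities, the threshold, the achieved
#' prevalence, the configuration hash and timing. Replicate r uses derived
#' seed `seed + r - 1`, so a logged configuration re-runs byte-identically.
#'
#' @param model A [hierarchy_model()] (or path to a model YAML file).
#' @param pop_size Population size per replicate.
#' @param prevalence Target disease prevalence.
#' @param n_cases,n_controls Sample sizes.
#' @param noise_snps Number of unassociated SNPs to append.
#' @param maf_range Minor-allele-frequency range for noise SNPs.
#' @param replicates Number of datasets.
#' @param seed Integer master seed.
#' @param out Optional output path prefix; writes `<out>_r<k>.txt` datasets
#'   and `<out>_report.json`.
#' @return List with `datasets` (list of tibbles), `report` (list) and
#'   `files` (character, empty when `out` is NULL).
#' @export
run_simulate <- function(model, pop_size = 100000, prevalence = 0.1,
                         n_cases = 1000, n_controls = 1000,
                         noise_snps = 0, maf_range = c(0.05, 0.5),
                         replicates = 1, seed = 1, out = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(model)) model <- read_model_config(model)$model
  stopifnot(inherits(model, "hierarchy_model"), replicates >= 1)
  .validate_run(pop_size, prevalence, n_cases, n_controls, noise_snps,
                maf_range)
  ld <- liability_distribution(model, prevalence = prevalence)
  cfg <- list(
    functions = unname(model$functions), pop_size = pop_size,
    prevalence = prevalence, n_cases = n_cases, n_controls = n_controls,
    noise_snps = noise_snps, maf_range = maf_range,
    replicates = replicates, seed = seed
  )
  datasets <- lapply(seq_len(replicates), function(r) {
    rs <- as.integer(seed) + r - 1L
    pop <- simulate_population(model, pop_size, prevalence = prevalence,
                               seed = rs)
    d <- sample_case_control(pop, n_cases, n_controls, seed = rs + 1L)
    if (noise_snps > 0) {
      d <- add_noise_snps(d, noise_snps, maf_range, seed = rs + 2L)
    }
    d
  })
  files <- character(0)
  if (!is.null(out)) {
    files <- vapply(seq_len(replicates), function(r) {
      f <- paste0(out, "_r", r, ".txt")
      write_mdr(datasets[[r]], f)
      f
    }, character(1))
  }
  report <- list(
    config = cfg,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("epistasim")),
    liability = list(value = ld$dist$value, prob = ld$dist$prob),
    threshold = ld$threshold,
    achieved_prevalence = ld$achieved_prevalence,
    files = files,
    elapsed_sec = proc.time()[["elapsed"]] - t0
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, paste0(out, "_report.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, paste0(out, "_report.json"))
  }
  list(datasets = datasets, report = report, files = files)
}

#' Evaluate a case-control dataset
#'
#' Computes the main-effect, pairwise and pure three-way interaction
#' information of a locus triple, the 3-locus MDR training accuracy, and
#' both permutation tests.
#'
#' @param data A case-control tibble or path to an MDR-format file.
#' @param loci Character vector of three variant names.
#' @param n_perm Permutations per test.
#' @param seed Optional integer seed.
#' @param out Optional path for a JSON report.
#' @return A list with `interaction` (an [interaction_information()]
#'   result), `mdr` (an [mdr()] fit), `p_standard`, `p_epistasis` and
#'   `summary` (a one-row tibble).
#' @export
run_evaluate <- function(data, loci = c("TF1", "TF2", "enhancer"),
                         n_perm = 1000, seed = NULL, out = NULL) {
  if (is.character(data)) data <- read_mdr(data)
  seeds <- derive_seeds(seed, 2)
  ig <- interaction_information(data, loci)
  fit <- mdr(data, loci)
  p_std <- mdr_permutation_test(data, loci, n_perm = n_perm,
                                type = "standard", seed = seeds[[1]])
  p_epi <- mdr_permutation_test(data, loci, n_perm = n_perm,
                                type = "epistasis", seed = seeds[[2]])
  summary <- tibble::tibble(
    ig_main_1 = unname(ig$main_ig[1]),
    ig_main_2 = unname(ig$main_ig[2]),
    ig_main_3 = unname(ig$main_ig[3]),
    ig_threeway = ig$threeway_ig,
    mdr_accuracy = fit$accuracy,
    p_standard = p_std$p.value,
    p_epistasis = p_epi$p.value
  )
  if (!is.null(out)) {
    jsonlite::write_json(
      c(list(loci = loci, n_perm = n_perm, seed = seed), as.list(summary)),
      out, auto_unbox = TRUE, digits = NA
    )
  }
  list(interaction = ig, mdr = fit, p_standard = p_std, p_epistasis = p_epi,
       summary = summary)
}

#' Run a heuristic model search and report a ranked table
#'
#' Runs [random_search()] or [ga_search()] and, for the top-ranked models,
#' also fits a 3-locus MDR on a freshly simulated dataset so the table can
#' be ranked either by three-way interaction information (the fitness) or
#' by classification accuracy.
#'
#' @param method `"ga"` or `"random"`.
#' @param config A [search_config()].
#' @param n Number of models for random search (ignored for the GA).
#' @param top Number of top-ranked models to annotate with MDR accuracy.
#' @param seed Integer master seed.
#' @param out Optional path for a TSV table.
#' @return A tibble: `rank`, `f1`..`f6`, `fitness`, `mdr_accuracy` (NA below
#'   `top`), `generation`, `encoding`.
#' @export
run_search <- function(method = c("ga", "random"), config = search_config(),
                       n = 100, top = 10, seed = 1, out = NULL) {
  method <- match.arg(method)
  seeds <- derive_seeds(seed, 2)
  res <- if (method == "ga") {
    ga_search(config, seed = seeds[[1]])
  } else {
    random_search(n, config, seed = seeds[[1]])
  }
  tbl <- if (inherits(res, "ga_search")) res$hall_of_fame else res
  top <- min(top, nrow(tbl))
  acc_seeds <- derive_seeds(seeds[[2]], max(top, 1))
  tbl$mdr_accuracy <- NA_real_
  for (i in seq_len(top)) {
    fns <- unlist(tbl[i, paste0("f", 1:6)])
    if (!is.finite(tbl$fitness[i])) next
    model <- hierarchy_model(fns)
    th <- select_threshold(liability_distribution(model)$dist,
                           config$prevalence)
    d <- with_seed_(acc_seeds[[i]],
                    .sample_exact(model, th$threshold,
                                  config$n_cases, config$n_controls))
    tbl$mdr_accuracy[i] <- mdr(d, c("TF1", "TF2", "enhancer"))$accuracy
  }
  tbl <- dplyr::relocate(tbl, "mdr_accuracy", .after = "fitness")
  if (!is.null(out)) {
    readr::write_tsv(tbl, out, progress = FALSE)
  }
  tbl
}

#' The eight reference two-function configurations
#'
#' The varied functions occupy the first two chain slots (combining TF1 with
#' the enhancer, then with TF2); the remaining four slots are additive.
#' Models 1--3 are main-effect architectures (addition/multiplication),
#' models 4--8 carry three-way epistatic signal.
#'
#' @return A tibble with columns `model`, `f1`, `f2`.
#' @export
model_catalog <- function() {
  tibble::tibble(
    model = 1:8,
    f1 = c("ADD", "ADD", "MULT", "XOR", "MOD2", "BITX", "BITX", "CHS"),
    f2 = c("ADD", "MULT", "MULT", "XOR", "XOR", "XOR", "MOD2", "BITA")
  )
}

#' @rdname model_catalog
#' @param model Row of [model_catalog()] (1--8).
#' @export
catalog_model <- function(model) {
  row <- model_catalog()[model, ]
  hierarchy_model(c(row$f1, row$f2, "ADD", "ADD", "ADD", "ADD"))
}

#' Noiseless pure-epistasis (parity) fixture
#'
#' Every three-locus genotype combination appears with multiplicity
#' proportional to its Hardy-Weinberg probability (1/2/1 per locus; 64 rows
#' in total) and the class is the parity `(TF1 + TF2 + enhancer) mod 2`.
#' Each single locus and each pair is exactly independent of the class,
#' while the triple determines it: main and pairwise IG are 0 and the pure
#' three-way IG is 1 bit, and MDR separates the classes perfectly.
#'
#' @return A 64-row tibble with columns `TF1`, `TF2`, `enhancer`, `Class`.
#' @export
parity_dataset <- function() {
  g <- expand.grid(TF1 = 0:2, TF2 = 0:2, enhancer = 0:2)
  w <- c(1, 2, 1)
  reps <- w[g$TF1 + 1] * w[g$TF2 + 1] * w[g$enhancer + 1]
  d <- g[rep(seq_len(nrow(g)), reps), ]
  d$Class <- (d$TF1 + d$TF2 + d$enhancer) %% 2L
  tibble::as_tibble(d)
}

#' Bundled toy fixtures
#'
#' Generates the worked fixtures used throughout the tests and examples:
#' the noiseless parity dataset, the eight reference model configurations,
#' and a null dataset whose status is independent of the genotypes by
#' construction.
#'
#' @param seed Integer seed for the null dataset.
#' @param n_null Rows in the null dataset.
#' @return List with `parity`, `models` (tibble) and `null`.
#' @export
make_fixtures <- function(seed = 42, n_null = 200) {
  null <- with_seed_(seed, {
    d <- tibble::tibble(
      TF1 = sample(0:2, n_null, TRUE, prob = c(0.25, 0.5, 0.25)),
      TF2 = sample(0:2, n_null, TRUE, prob = c(0.25, 0.5, 0.25)),
      enhancer = sample(0:2, n_null, TRUE, prob = c(0.25, 0.5, 0.25))
    )
    d$Class <- rep(0:1, length.out = n_null)[sample.int(n_null)]
    d
  })
  list(parity = parity_dataset(), models = model_catalog(), null = null)
}
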