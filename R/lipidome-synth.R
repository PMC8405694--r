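# Synthetic shotgun-lipidome generator.
#
# Emulates the statistical structure of a direct-infusion lipidomics species
# table: class proportions, per-class chain-length and unsaturation
# distributions and multiplicative replicate noise. Ground truth for every
# profile metric is computed from the realized noise-free species table, so
# recovery by the profile functions can be tested exactly at zero noise and
# within stochastic bounds otherwise.

#' Default lipid class proportions
#'
#' Typical exponential-phase yeast whole-cell class proportions for the two
#' strain conditions studied. Storage (TAG, EE) plus mitochondrial-only
#' (PG, CL) classes carry 22 % of the abundance, so plasma-membrane lipids
#' sum to 0.78; within that set DAG is 7.0 % of membrane lipids for
#' `"control"` (empty-vector strain) and 12.34 % for `"fae1_gpat5"` (the
#' elongase/acyltransferase double-expression strain, with PI and PS reduced
#' in compensation).
#'
#' @param strain `"control"` or `"fae1_gpat5"`.
#' @return named numeric vector over the class vocabulary summing to 1.
#' @export
default_class_proportions <- function(strain = c("control", "fae1_gpat5")) {
  strain <- match.arg(strain)
  p <- c(PC = 0.1954, PE = 0.14, PI = 0.13, PS = 0.06, PA = 0.02,
         DAG = 0.0546, TAG = 0.12, EE = 0.06,
         Cer = 0.01, IPC = 0.06, MIPC = 0.04, MIP2C = 0.02,
         CL = 0.02, PG = 0.02,
         LPC = 0.01, LPE = 0.015, LPI = 0.01, LPS = 0.005, LPA = 0.005,
         `CDP-DAG` = 0.005)
  if (strain == "fae1_gpat5") {
    p[["DAG"]] <- 0.0963
    p[["PI"]] <- p[["PI"]] - 0.025
    p[["PS"]] <- p[["PS"]] - 0.0167
  }
  p / sum(p)
}

#' Specify a synthetic lipidome
#'
#' @param class_proportions named fractions over the class vocabulary,
#'   summing to 1 (tolerance 1e-9).
#' @param chain_mean mean total acyl carbons: `NULL` for per-class defaults,
#'   a scalar applied to the two-chain GPL + DAG classes (others keep their
#'   defaults), or a named vector of per-class overrides.
#' @param chain_sd sd of total carbons before rounding to even integers.
#' @param db_mean Poisson mean of total double bonds (truncated at a
#'   chain-dependent maximum).
#' @param n_species_per_class species drawn per class.
#' @param n_replicates replicate measurements.
#' @param abundance_noise_cv coefficient of variation of the multiplicative
#'   lognormal replicate noise (0 gives identical replicates).
#' @param sample_name strain/sample identifier written into the table.
#' @param seed integer RNG seed.
#' @return an object of class `lipidome_spec`.
#' @export
lipidome_spec <- function(class_proportions = default_class_proportions("control"),
                          chain_mean = NULL,
                          chain_sd = 2,
                          db_mean = 1.3,
                          n_species_per_class = 20L,
                          n_replicates = 3L,
                          abundance_noise_cv = 0.1,
                          sample_name = "synthetic",
                          seed = 1L) {
  vocab <- lipid_class_vocabulary()
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% vocab))
    abort2("class_proportions must be named with known lipid classes",
           "validation_error")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    abort2("class proportions must sum to 1", "validation_error")
  if (any(class_proportions < 0))
    abort2("class proportions must be non-negative", "validation_error")
  stopifnot(chain_sd >= 0, db_mean >= 0, n_species_per_class >= 1,
            n_replicates >= 1, abundance_noise_cv >= 0)

  means <- default_chain_means()
  if (!is.null(chain_mean)) {
    if (is.null(names(chain_mean)) && length(chain_mean) == 1L) {
      means[c(gpl_classes(), "DAG")] <- chain_mean
    } else {
      means[names(chain_mean)] <- chain_mean
    }
  }
  structure(list(
    class_proportions = class_proportions,
    chain_means = means, chain_sd = chain_sd, db_mean = db_mean,
    n_species_per_class = as.integer(n_species_per_class),
    n_replicates = as.integer(n_replicates),
    abundance_noise_cv = abundance_noise_cv,
    sample_name = sample_name, seed = as.integer(seed)
  ), class = "lipidome_spec")
}

# clamp to range and round to the nearest even integer
round_even_clamped <- function(x, range) {
  v <- 2L * as.integer(round_half_up(x / 2))
  pmin(pmax(v, range[1L]), range[2L])
}

#' Generate a synthetic lipidome table with ground truth
#'
#' Species per class: total carbons from a discretized normal rounded to even
#' integers within class-plausible ranges; double bonds Poisson, truncated at
#' `floor(carbons / 6)`; within-class abundances Dirichlet (unit
#' concentration) scaled by the class proportion. Replicate abundances
#' multiply the base abundance by lognormal noise of the requested CV. The
#' ground truth is computed from the realized noise-free table.
#'
#' @param spec a [lipidome_spec()].
#' @return list with `table` (a `lipidome_table` data frame: sample,
#'   replicate, lipid_class, total_carbons, total_double_bonds, abundance)
#'   and `truth` (class fractions, mean GPL carbons, mean double bonds per
#'   membrane lipid, shape-class / chain-bin / DAG / PM-FA fractions).
#' @export
generate_lipidome <- function(spec) {
  stopifnot(inherits(spec, "lipidome_spec"))
  set.seed(spec$seed)
  ranges <- class_carbon_ranges()
  classes <- names(spec$class_proportions)[spec$class_proportions > 0]

  species <- do.call(rbind, lapply(classes, function(cl) {
    n <- spec$n_species_per_class
    carbons <- round_even_clamped(
      stats::rnorm(n, spec$chain_means[[cl]], spec$chain_sd), ranges[[cl]])
    db <- pmin(stats::rpois(n, spec$db_mean), carbons %/% 6L)
    w <- stats::rgamma(n, shape = 1)
    base <- spec$class_proportions[[cl]] * w / sum(w)
    d <- data.frame(lipid_class = cl, total_carbons = carbons,
                    total_double_bonds = as.integer(db), base_abundance = base,
                    stringsAsFactors = FALSE)
    # merge duplicate (carbons, db) draws into one species
    agg <- stats::aggregate(base_abundance ~ lipid_class + total_carbons +
                              total_double_bonds, data = d, FUN = sum)
    agg
  }))

  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    noise <- if (spec$abundance_noise_cv > 0) {
      sdlog <- sqrt(log(1 + spec$abundance_noise_cv^2))
      stats::rlnorm(nrow(species), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    data.frame(sample = spec$sample_name, replicate = r,
               lipid_class = species$lipid_class,
               total_carbons = species$total_carbons,
               total_double_bonds = species$total_double_bonds,
               abundance = species$base_abundance * noise,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, reps)
  class(tab) <- c("lipidome_table", "data.frame")

  truth <- lipidome_truth(species)
  list(table = tab, truth = truth, species = species)
}

# ground-truth metrics from the realized noise-free species table
lipidome_truth <- function(species) {
  ab <- species$base_abundance
  cl <- species$lipid_class
  class_fractions <- c(tapply(ab, cl, sum) / sum(ab))

  g <- cl %in% gpl_classes()
  mean_gpl_carbons <- sum(ab[g] * species$total_carbons[g]) / sum(ab[g])

  m <- cl %in% membrane_classes()
  mean_db_membrane <- sum(ab[m] * species$total_double_bonds[m]) / sum(ab[m])

  pm <- cl %in% pm_classes()
  tax <- shape_taxonomy()
  shape_of <- function(x) {
    hits <- names(tax)[vapply(tax, function(v) x %in% v, logical(1))]
    hits[1L]
  }
  shp <- vapply(cl, shape_of, character(1))
  shape_fractions <- c(tapply(ab[pm], shp[pm], sum) / sum(ab[pm]))

  bins <- carbon_bin(species$total_carbons[g], warn = FALSE)
  bin_fractions <- tapply(ab[g], bins, sum) / sum(ab[g])
  bin_fractions <- as.numeric(bin_fractions[c("medium", "long", "very_long")])
  bin_fractions[is.na(bin_fractions)] <- 0
  names(bin_fractions) <- c("medium", "long", "very_long")

  chains <- chains_per_lipid()[cl] * ab
  pm_fa <- sum(chains[pm]) / sum(chains)

  dag_fraction <- sum(ab[pm & cl == "DAG"]) / sum(ab[pm])

  list(class_fractions = class_fractions,
       mean_gpl_carbons = mean_gpl_carbons,
       mean_double_bonds_membrane = mean_db_membrane,
       shape_fractions = shape_fractions,
       chain_bin_fractions = bin_fractions,
       dag_fraction = dag_fraction,
       pm_fa_fraction = pm_fa)
}

#' Write a lipidome table as CSV
#'
#' Columns: `sample, replicate, lipid_class, total_carbons,
#' total_double_bonds, abundance`.
#'
#' @param table a `lipidome_table`.
#' @param path output path.
#' @export
write_lipidome_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
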