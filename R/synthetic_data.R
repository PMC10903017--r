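# Simulators that emulate the statistical structure of the pipeline's inputs:
# protein families diverged from a common ancestor at controlled identity
# (substitutions plus deletion-type indels, kept in the ancestor coordinate
# frame so the alignment is exact by construction), and noisy piecewise-linear
# substrate-depletion / product-formation time courses.

#' Configuration for simulating a diverged protein family
#'
#' @param ancestor_length Ancestor length in residues (> 0).
#' @param n_members Number of derived homologs (>= 2).
#' @param substitution_prob Per-site substitution probability in `[0, 1)`;
#'   substituted sites are drawn uniformly over the 19 alternative residues.
#' @param indel_prob Per-site probability of starting a deletion in `[0, 1)`.
#' @param indel_mean_len Mean deletion length (geometric; >= 1).
#' @param seed Integer seed.
#' @return An object of class `family_sim_config`.
#' @export
family_sim_config <- function(ancestor_length = 500L, n_members = 8L,
                              substitution_prob = 0.05, indel_prob = 0,
                              indel_mean_len = 3, seed = 1L) {
  if (ancestor_length < 1L) stop_input("ancestor_length must be positive")
  if (n_members < 2L) stop_input("n_members must be at least 2")
  for (p in c(substitution_prob, indel_prob))
    if (p < 0 || p >= 1) stop_input("probabilities must lie in [0, 1)")
  if (indel_mean_len < 1) stop_input("indel_mean_len must be >= 1")
  structure(list(ancestor_length = as.integer(ancestor_length),
                 n_members = as.integer(n_members),
                 substitution_prob = substitution_prob,
                 indel_prob = indel_prob, indel_mean_len = indel_mean_len,
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

#' Simulate a family of homologs diverged from a common ancestor
#'
#' The ancestor is drawn uniformly over the 20 residues. Each member is
#' derived independently: every site substitutes with probability
#' `substitution_prob` (uniform over the 19 alternatives) and starts a
#' deletion with probability `indel_prob` (geometric length, mean
#' `indel_mean_len`). Deletions are recorded as gaps in the ancestor frame,
#' so the returned family is already an exact alignment. Insertions are not
#' simulated.
#'
#' @param config A [family_sim_config()].
#' @return A list: `ancestor` (a `protein_seq`) and `family`
#'   (an `aligned_family` in the ancestor coordinate frame).
#' @examples
#' sim <- simulate_family(family_sim_config(ancestor_length = 40,
#'                                          n_members = 4, seed = 7))
#' alignment_ncol(sim$family)
#' @export
simulate_family <- function(config = family_sim_config()) {
  stopifnot(inherits(config, "family_sim_config"))
  L <- config$ancestor_length
  n <- config$n_members
  with_seed(config$seed, {
    anc <- sample(AA_LETTERS, L, replace = TRUE)
    members <- character(n)
    for (i in seq_len(n)) {
      m <- anc
      sub_at <- which(stats::runif(L) < config$substitution_prob)
      for (s in sub_at)
        m[s] <- sample(setdiff(AA_LETTERS, anc[s]), 1L)
      del_start <- which(stats::runif(L) < config$indel_prob)
      for (s in del_start) {
        len <- 1L + stats::rgeom(1L, 1 / config$indel_mean_len)
        m[s:min(L, s + len - 1L)] <- GAP_CHAR
      }
      if (all(m == GAP_CHAR)) m[1L] <- anc[1L]  # keep members degappable
      members[i] <- paste0(m, collapse = "")
    }
    names(members) <- sprintf("hom%02d", seq_len(n))
    list(ancestor = protein_sequence("ancestor",
                                     paste0(anc, collapse = "")),
         family = aligned_family(members, source_format = "aligned-fasta"))
  })
}

#' Configuration for simulating a bioconversion time course
#'
#' @param true_rate Depletion rate in mg/L/h (> 0).
#' @param plateau_time Hour at which the substrate is exhausted and both
#'   curves plateau.
#' @param sampling_times Sampling times in hours (increasing).
#' @param noise_sd Additive Gaussian noise, mg/L (>= 0).
#' @param seed Integer seed.
#' @param substrate,product Compound labels (must be known to `stoich`).
#' @param stoich A [pathway_stoichiometry()] for the product mirror.
#' @return An object of class `kinetics_sim_config`.
#' @export
kinetics_sim_config <- function(true_rate = 25, plateau_time = 4,
                                sampling_times = c(0, 0.5, 1, 1.5, 2, 4, 8,
                                                   24),
                                noise_sd = 0, seed = 1L,
                                substrate = "L-Phe", product = "tCA",
                                stoich = pathway_stoichiometry()) {
  if (true_rate <= 0) stop_input("true_rate must be positive")
  if (plateau_time <= 0) stop_input("plateau_time must be positive")
  if (noise_sd < 0) stop_input("noise_sd must be non-negative")
  if (any(diff(sampling_times) <= 0) || any(sampling_times < 0))
    stop_input("sampling times must be non-negative and increasing")
  structure(list(true_rate = true_rate, plateau_time = plateau_time,
                 sampling_times = sampling_times, noise_sd = noise_sd,
                 seed = as.integer(seed), substrate = substrate,
                 product = product, stoich = stoich),
            class = "kinetics_sim_config")
}

#' Simulate a substrate-depletion / product-formation time-course pair
#'
#' The substrate starts at `true_rate * plateau_time` mg/L, declines linearly
#' at `true_rate` until `plateau_time`, then holds at zero; the product
#' mirrors the consumed substrate under pathway stoichiometry. Independent
#' Gaussian noise (sd `noise_sd`) is added to every sample and concentrations
#' are floored at zero.
#'
#' @param config A [kinetics_sim_config()].
#' @return A list of two `bioconversion_series`: `substrate` and `product`.
#' @examples
#' sim <- simulate_bioconversion(kinetics_sim_config(noise_sd = 0))
#' initial_rate(sim$substrate)  # recovers -true_rate exactly
#' @export
simulate_bioconversion <- function(config = kinetics_sim_config()) {
  stopifnot(inherits(config, "kinetics_sim_config"))
  t <- config$sampling_times
  s0 <- config$true_rate * config$plateau_time
  sub_true <- pmax(0, s0 - config$true_rate * pmin(t, config$plateau_time))
  prod_true <- stoich_convert(s0 - sub_true, config$substrate,
                              config$product, config$stoich)
  with_seed(config$seed, {
    noise <- function(x) pmax(0, x + stats::rnorm(length(x),
                                                  sd = config$noise_sd))
    sub <- if (config$noise_sd > 0) noise(sub_true) else sub_true
    prod <- if (config$noise_sd > 0) noise(prod_true) else prod_true
    list(substrate = bioconversion_series(t, sub, config$substrate),
         product = bioconversion_series(t, prod, config$product))
  })
}
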