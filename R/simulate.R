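#' Default simulation laws for synthetic descriptor sets
#'
#' Returns the generating law per descriptor: log-normal (median, shape
#' `sdlog`) for the continuous descriptors and Poisson (mean, plus an
#' integer shift for aromatic rings) for the count descriptors. The
#' `"positive"` mode emulates the concentrated, right-skewed distributions
#' typical of known algicidal compounds — molecular weight bulk between 200
#' and 500 g/mol, logP peaking around 2-5, fewer than five rotatable bonds,
#' one to two aromatic rings, fewer than five acceptors and at most about two
#' donors. The `"decoy"` mode shifts the medians and inflates the shape
#' parameters, giving the diffuse property spread of a general screening
#' collection.
#'
#' @param mode `"positive"` or `"decoy"`.
#' @return Named list of per-descriptor law parameters.
#' @export
simulation_params <- function(mode = c("positive", "decoy")) {
  mode <- match.arg(mode)
  if (mode == "positive") {
    list(
      mw    = list(law = "lognormal", median = 320, sdlog = 0.35),
      logp  = list(law = "lognormal", median = 3, sdlog = 0.45),
      hba   = list(law = "poisson", mean = 3, shift = 0),
      hbd   = list(law = "poisson", mean = 1, shift = 0),
      nrotb = list(law = "poisson", mean = 3, shift = 0),
      narr  = list(law = "poisson", mean = 0.8, shift = 1)
    )
  } else {
    list(
      mw    = list(law = "lognormal", median = 450, sdlog = 0.8),
      logp  = list(law = "lognormal", median = 5, sdlog = 0.9),
      hba   = list(law = "poisson", mean = 6, shift = 0),
      hbd   = list(law = "poisson", mean = 3, shift = 0),
      nrotb = list(law = "poisson", mean = 7, shift = 0),
      narr  = list(law = "poisson", mean = 3, shift = 0)
    )
  }
}

#' Simulate a synthetic descriptor set
#'
#' Draws `n` descriptor vectors from the per-descriptor laws of
#' [simulation_params()] (or custom laws of the same shape). Continuous
#' descriptors are unimodal and right-skewed; count descriptors are
#' non-negative integers. Identical `n`, `seed` and parameters always
#' reproduce the same table.
#'
#' @param n Number of compounds to simulate (`n >= 0`).
#' @param seed Integer seed.
#' @param mode `"positive"` or `"decoy"`; ignored when `params` is given.
#' @param params Optional law list overriding [simulation_params()].
#' @return A tibble with columns `id`, `mw`, `logp`, `hba`, `hbd`, `nrotb`,
#'   `narr`.
#' @examples
#' simulate_descriptors(5, seed = 42)
#' @export
simulate_descriptors <- function(n, seed = 1,
                                 mode = c("positive", "decoy"),
                                 params = NULL) {
  mode <- match.arg(mode)
  if (is.null(params)) params <- simulation_params(mode)
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  missing_d <- setdiff(qea_descriptors, names(params))
  if (length(missing_d) > 0) {
    stop("params lacks laws for: ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  if (n == 0) {
    cols <- c(list(id = character(0)),
              stats::setNames(rep(list(numeric(0)), 6), qea_descriptors))
    return(tibble::as_tibble(cols))
  }
  draws <- withr::with_seed(seed, {
    lapply(params[qea_descriptors], function(p) draw_law(n, p))
  })
  tibble::as_tibble(c(list(id = sprintf("sim%05d", seq_len(n))), draws))
}

draw_law <- function(n, p) {
  switch(p$law,
    lognormal = {
      if (!is.finite(p$median) || p$median <= 0 || p$sdlog <= 0) {
        stop("lognormal law needs median > 0 and sdlog > 0", call. = FALSE)
      }
      stats::rlnorm(n, meanlog = log(p$median), sdlog = p$sdlog)
    },
    poisson = {
      if (!is.finite(p$mean) || p$mean < 0) {
        stop("poisson law needs mean >= 0", call. = FALSE)
      }
      shift <- p$shift %||% 0
      stats::rpois(n, p$mean) + shift
    },
    stop("unknown law: ", p$law, call. = FALSE)
  )
}

#' Hard-coded panel of simple molecules with hand-checkable descriptors
#'
#' A regression fixture for the descriptor engine: ~20 small hydrocarbons,
#' alcohols, aromatics and simple heteroatom compounds whose molecular
#' weight, H-bond counts, rotatable bonds and aromatic ring counts can be
#' verified by structure inspection.
#'
#' @return A compound tibble ([compound_tbl()]).
#' @export
fixture_smiles <- function() {
  panel <- c(
    methane      = "C",
    ethane       = "CC",
    propane      = "CCC",
    butane       = "CCCC",
    isobutane    = "CC(C)C",
    cyclohexane  = "C1CCCCC1",
    benzene      = "c1ccccc1",
    toluene      = "Cc1ccccc1",
    biphenyl     = "c1ccccc1-c1ccccc1",
    naphthalene  = "c1ccc2ccccc2c1",
    methanol     = "CO",
    ethanol      = "CCO",
    propanol     = "CCCO",
    glycol       = "OCCO",
    phenol       = "Oc1ccccc1",
    acetone      = "CC(C)=O",
    acetic_acid  = "CC(=O)O",
    ethyl_acetate = "CCOC(C)=O",
    dmf          = "CN(C)C=O",
    aniline      = "Nc1ccccc1",
    pyridine     = "c1ccncc1",
    dimethyl_ether = "COC"
  )
  compound_tbl(unname(panel), names(panel))
}
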