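PROFILE_VERSION <- "1.0"

#' Aggregate per-descriptor desirabilities into a QEA score
#'
#' The quantitative estimate of algicide-likeness is the unweighted geometric
#' mean of the per-descriptor desirabilities,
#' \deqn{QEA = \exp\left(\frac{1}{n}\sum_{i=1}^{n} \ln df_i\right),}
#' with the hard zero rule: if any desirability is less than or equal to
#' zero, the score is exactly 0.
#'
#' @param d Numeric vector of desirabilities (length >= 1).
#' @return A single score in \[0, 1\] (assuming each `d <= 1`).
#' @examples
#' aggregate_qea(rep(1, 6))                       # 1
#' aggregate_qea(c(0.5, -0.01, 0.9, 0.9, 0.9, 0.9))  # 0
#' @export
aggregate_qea <- function(d) {
  if (length(d) == 0) stop("empty desirability vector", call. = FALSE)
  if (any(!is.finite(d))) stop("desirabilities must be finite", call. = FALSE)
  if (any(d <= 0)) return(0)
  exp(mean(log(d)))
}

#' Fit a complete QEA profile from a reference compound set
#'
#' Runs the full fitting pipeline on a reference ("positive") set: descriptor
#' calculation (if needed), frequency tables — optimal-width histograms for
#' the continuous descriptors (MW, logP), exact integer tallies for the count
#' descriptors (HBA, HBD, nRotB, nArR) — and a desirability fit per
#' descriptor. Valid compounds are deduplicated by canonical SMILES before
#' fitting so repeated literature entries do not distort the distributions.
#'
#' @param x Either a compound tibble ([read_compounds()]) or a descriptor
#'   table already containing columns `mw, logp, hba, hbd, nrotb, narr`
#'   (e.g. from [compute_descriptors()] or [simulate_descriptors()]).
#' @param candidate_range Bin-count search range passed to
#'   [bin_frequencies()] for MW and logP.
#' @param min_n Minimum number of valid, deduplicated compounds (default 30).
#' @param provenance Optional free-text provenance note stored in the
#'   profile.
#' @return A `qea_profile` object: per-descriptor `qea_desirability` models
#'   plus the descriptor conventions and provenance.
#' @examples
#' prof <- fit_qea_profile(simulate_descriptors(200, seed = 1))
#' @export
fit_qea_profile <- function(x, candidate_range = NULL, min_n = 30,
                            provenance = NULL) {
  desc <- ensure_descriptor_tbl(x, dedupe = TRUE)
  desc <- desc[stats::complete.cases(desc[, qea_descriptors]), , drop = FALSE]
  if (nrow(desc) < min_n) {
    stop("insufficient data: ", nrow(desc), " valid unique compounds, need >= ",
         min_n, call. = FALSE)
  }

  fits <- lapply(qea_descriptors, function(d) {
    vals <- desc[[d]]
    freq <- if (d %in% c("mw", "logp")) {
      bin_frequencies(vals, candidate_range)
    } else {
      pad_discrete_freq(integer_frequencies(vals))
    }
    tryCatch(fit_desirability(freq, d), error = function(e) {
      stop("profile fit failed on descriptor '", d, "': ",
           conditionMessage(e), call. = FALSE)
    })
  })
  names(fits) <- qea_descriptors

  structure(
    list(
      version = PROFILE_VERSION,
      descriptor_conventions = descriptor_conventions(),
      models = fits,
      provenance = provenance %||%
        sprintf("fitted on %d compounds", nrow(desc))
    ),
    class = "qea_profile"
  )
}

# A count descriptor concentrated on few values (e.g. donors of 0-3) can
# tally fewer than the 5 support points the curve fit needs; counts of
# never-observed higher values are genuinely zero, so the tally is extended
# with them until 5 points are available.
pad_discrete_freq <- function(freq) {
  if (nrow(freq) >= 5) return(freq)
  extra <- seq(max(freq$x) + 1, length.out = 5 - nrow(freq))
  new_freq_table(c(freq$x, extra), c(freq$count, rep(0, length(extra))),
                 kind = "discrete")
}

# Accepts a compound tibble (computes descriptors, optionally deduplicated)
# or a ready descriptor table; returns rows with the six descriptor columns.
ensure_descriptor_tbl <- function(x, dedupe = FALSE) {
  if (!is.data.frame(x)) {
    stop("expected a data frame of compounds or descriptors", call. = FALSE)
  }
  if (all(qea_descriptors %in% names(x))) {
    return(dplyr::as_tibble(x))
  }
  check_compound_tbl(x)
  if (dedupe) x <- dedupe_compounds(x)
  compute_descriptors(x)
}

#' Score compounds with a fitted QEA profile
#'
#' Evaluates the six desirability models at each compound's descriptor values
#' (clamped to at most 1) and aggregates them with [aggregate_qea()]. Invalid
#' compounds keep their row with an `NA` score and the failure reason; output
#' order equals input order.
#'
#' @param x Compound tibble or descriptor table (see [fit_qea_profile()]).
#' @param profile A `qea_profile` from [fit_qea_profile()] or
#'   [read_qea_profile()].
#' @return A tibble with the identifiers, the six descriptors, the six
#'   desirabilities (`d_mw`, ..., `d_narr`) and `qea`.
#' @examples
#' sim <- simulate_descriptors(100, seed = 1)
#' prof <- fit_qea_profile(simulate_descriptors(200, seed = 2))
#' qea_score(sim, prof)
#' @export
qea_score <- function(x, profile) {
  check_profile(profile)
  desc <- ensure_descriptor_tbl(x, dedupe = FALSE)

  d_cols <- paste0("d_", qea_descriptors)
  for (i in seq_along(qea_descriptors)) {
    m <- profile$models[[qea_descriptors[i]]]
    v <- desc[[qea_descriptors[i]]]
    desc[[d_cols[i]]] <- pmin(evaluate_desirability(m, v), 1)
  }
  dmat <- as.matrix(desc[, d_cols])
  desc$qea <- apply(dmat, 1, function(row) {
    if (any(!is.finite(row))) return(NA_real_)
    aggregate_qea(row)
  })
  desc
}

check_profile <- function(profile) {
  if (!inherits(profile, "qea_profile")) {
    stop("profile must be a qea_profile object", call. = FALSE)
  }
  if (!setequal(names(profile$models), qea_descriptors)) {
    stop("profile must contain exactly one model per descriptor: ",
         paste(qea_descriptors, collapse = ", "), call. = FALSE)
  }
  current <- descriptor_conventions()
  stored <- unlist(profile$descriptor_conventions)
  if (!identical(unname(stored[names(current)]), unname(current))) {
    stop("profile descriptor conventions do not match this toolkit's; ",
         "refusing to score with mismatched descriptor definitions",
         call. = FALSE)
  }
  invisible(profile)
}

#' Serialise a QEA profile to JSON
#'
#' The profile file is versioned and records the descriptor rule-set
#' identifiers, so a profile can never be scored with mismatched descriptor
#' definitions. Serialisation is deterministic: the same profile always
#' produces byte-identical JSON.
#'
#' @param profile A `qea_profile`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_qea_profile <- function(profile, path) {
  check_profile(profile)
  models <- lapply(profile$models, function(m) {
    list(o = m$o, a = m$a, b = m$b, c = m$c,
         fit_rmse = m$fit_rmse,
         fit_range = m$fit_range,
         bin_width = m$bin_width,
         kind = m$kind, n_total = m$n_total)
  })
  obj <- list(
    version = profile$version,
    descriptor_conventions = as.list(profile$descriptor_conventions),
    models = models,
    provenance = profile$provenance
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(15),
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a QEA profile from JSON
#'
#' @param path Path to a profile written by [write_qea_profile()].
#' @return A `qea_profile` object.
#' @export
read_qea_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$version) || is.null(obj$models)) {
    stop("not a QEA profile file: ", path, call. = FALSE)
  }
  models <- lapply(names(obj$models), function(d) {
    m <- obj$models[[d]]
    structure(
      list(descriptor = d, o = m$o, a = m$a, b = m$b, c = m$c,
           peak_overshoot = max(0, m$o + m$a - 1),
           bin_width = m$bin_width,
           fit_rmse = m$fit_rmse, fit_range = as.numeric(m$fit_range),
           kind = m$kind, n_total = m$n_total),
      class = "qea_desirability"
    )
  })
  names(models) <- names(obj$models)
  profile <- structure(
    list(
      version = obj$version,
      descriptor_conventions = unlist(obj$descriptor_conventions),
      models = models,
      provenance = obj$provenance
    ),
    class = "qea_profile"
  )
  check_profile(profile)
  profile
}

#' @method print qea_profile
#' @export
print.qea_profile <- function(x, ...) {
  cat("<qea_profile> version", x$version, "\n")
  cat("  ", x$provenance, "\n", sep = "")
  for (m in x$models) {
    cat(sprintf("  %-6s o=%.4g a=%.4g b=%.4g c=%.4g (rmse %.3g, %s)\n",
                m$descriptor, m$o, m$a, m$b, m$c, m$fit_rmse, m$kind))
  }
  invisible(x)
}

#' @method tidy qea_profile
#' @export
tidy.qea_profile <- function(x, ...) {
  purrr::map_dfr(x$models, tidy)
}

#' @method glance qea_profile
#' @export
glance.qea_profile <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}

#' Plot the fitted desirability curves of a profile
#'
#' @param object A `qea_profile`.
#' @param ... Unused.
#' @return A ggplot faceted by descriptor.
#' @method autoplot qea_profile
#' @export
autoplot.qea_profile <- function(object, ...) {
  curves <- purrr::map_dfr(object$models, function(m) {
    span <- diff(m$fit_range)
    xs <- seq(m$fit_range[1] - 0.05 * span, m$fit_range[2] + 0.05 * span,
              length.out = 200)
    tibble::tibble(descriptor = m$descriptor, x = xs,
                   desirability = evaluate_desirability(m, xs))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$desirability)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~descriptor, scales = "free_x") +
    ggplot2::labs(x = "descriptor value", y = "desirability") +
    ggplot2::theme_minimal()
}

#' Write a score table to CSV
#'
#' @param scores Tibble from [qea_score()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}
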