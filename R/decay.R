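#' Define an RNA degradation pathway
#'
#' A pathway is a small species graph: RNA species (genomic intervals, so
#' probes can be located on them) connected by first-order reactions.
#' Endonucleolytic cleavage (RNase Y or III) converts a parent into its
#' product fragments; 5'-3' exonucleolytic degradation (RNase J1) and
#' 3'-5' exonucleolytic decay remove a species (optionally leaving a
#' truncated product). All kinetics are first order with rates in 1/minute.
#'
#' @param species data.frame with columns `id`, `start`, `end` (interval on
#'   the transcript, any consistent coordinates) and optionally `synthesis`
#'   (steady-state synthesis rate before the chase; defaults to 1 for
#'   species no reaction produces, 0 otherwise).
#' @param reactions data.frame with columns `type` (`endocleave`,
#'   `exo5to3`, `exo3to5`), `enzyme` (`Y`, `III`, `J1`, or `""` for
#'   enzyme-independent decay), `parent` (species id), `products`
#'   (`;`-separated species ids, possibly empty), `rate` (>= 0, 1/minute).
#' @return list of class `decay_pathway`.
#' @export
decay_pathway <- function(species, reactions) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (anyDuplicated(species$id)) stopf("species ids must be unique")
  if (any(reactions$rate < 0)) stopf("reaction rates must be >= 0")
  prods <- strsplit(ifelse(is.na(reactions$products), "", reactions$products),
                    ";", fixed = TRUE)
  all_named <- c(reactions$parent, unlist(prods))
  unknown <- setdiff(all_named[nzchar(all_named)], species$id)
  if (length(unknown) > 0)
    stopf("reactions reference unknown species: %s", paste(unknown, collapse = ", "))
  # parent -> product graph must be acyclic
  edges <- do.call(rbind, lapply(seq_len(nrow(reactions)), function(i) {
    p <- prods[[i]]
    if (length(p) == 0 || !any(nzchar(p))) return(NULL)
    data.frame(from = reactions$parent[i], to = p[nzchar(p)],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(edges)) {
    remaining <- unique(c(edges$from, edges$to))
    e <- edges
    repeat {
      sinks <- setdiff(remaining, e$from)
      if (length(sinks) == 0) break
      remaining <- setdiff(remaining, sinks)
      e <- e[!(e$to %in% sinks), , drop = FALSE]
      if (nrow(e) == 0) break
    }
    if (nrow(e) > 0) stopf("reaction graph contains a cycle")
  }
  if (is.null(species$synthesis)) {
    produced <- unique(unlist(prods))
    species$synthesis <- ifelse(species$id %in% produced, 0, 1)
  }
  structure(list(species = species, reactions = reactions, products = prods),
            class = "decay_pathway")
}

# first-order rate matrix A (dx/dt = A x), with the depleted enzyme's
# reactions slowed by the scenario's fold reduction
rate_matrix <- function(pathway, depleted = NULL,
                        scenario = depletion_scenario()) {
  ids <- pathway$species$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(pathway$reactions))) {
    k <- pathway$reactions$rate[i]
    if (!is.null(depleted) && identical(pathway$reactions$enzyme[i], depleted))
      k <- k / scenario$fold_reduction
    p <- pathway$reactions$parent[i]
    A[p, p] <- A[p, p] - k
    for (pr in pathway$products[[i]])
      if (nzchar(pr)) A[pr, p] <- A[pr, p] + k
  }
  A
}

# pre-chase steady state: A x + b = 0. Falls back to unit abundance for
# synthesized species when A is singular (e.g. a species with no decay).
steady_state <- function(A, b) {
  x <- tryCatch(solve(-A, b), error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x)) || any(x < 0)) x <- as.numeric(b > 0)
  names(x) <- rownames(A)
  x
}

#' Simulate a rifampicin-chase decay time course
#'
#' At t = 0 transcription initiation is blocked (synthesis set to zero) and
#' species abundances follow the first-order linear kinetics of the
#' pathway graph, solved exactly with the matrix exponential. Under
#' depletion the depleted enzyme's rate constants are divided by the
#' scenario's fold reduction; the initial condition is the (depleted)
#' pre-chase steady state unless `x0` is given. Optional multiplicative
#' log-normal measurement noise.
#'
#' @param pathway a [decay_pathway()].
#' @param scenario a [depletion_scenario()].
#' @param timepoints minutes, starting at 0.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @param depleted enzyme depleted during the chase (`NULL` for wild type).
#' @param x0 optional named initial abundances (overrides the steady state).
#' @param noise_sd sd of log-normal measurement noise (log scale).
#' @return list of class `decay_timecourse`: `time`, `abundance`
#'   (species x time), `pathway`, `depleted`.
#' @export
simulate_decay_timecourse <- function(pathway, scenario = depletion_scenario(),
                                      timepoints = c(0, 2.5, 5, 10, 15),
                                      seed = NULL, depleted = NULL, x0 = NULL,
                                      noise_sd = 0) {
  stopifnot(inherits(pathway, "decay_pathway"))
  if (any(timepoints < 0) || timepoints[1] != 0)
    stopf("timepoints must start at 0")
  A <- rate_matrix(pathway, depleted, scenario)
  ids <- pathway$species$id
  if (is.null(x0)) {
    x0 <- steady_state(A, stats::setNames(pathway$species$synthesis, ids))
  } else {
    x0 <- stats::setNames(as.numeric(x0[ids]), ids)
    if (anyNA(x0)) stopf("x0 must name every species")
  }
  X <- vapply(timepoints, function(t)
    as.numeric(Matrix::expm(A * t) %*% x0), numeric(length(ids)))
  X <- matrix(X, nrow = length(ids), dimnames = list(ids, NULL))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    X <- X * exp(matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X)))
  }
  structure(list(time = timepoints, abundance = X, pathway = pathway,
                 depleted = depleted %||% "none"),
            class = "decay_timecourse")
}

#' Fit an RNA half-life from a chase time course
#'
#' Log-linear least squares of `ln(intensity)` on time; the decay constant
#' is minus the slope and the half-life `ln(2)/k`. Intensities at or below
#' the censoring floor are dropped with a warning. A non-positive fitted
#' decay constant is reported as a stable species (infinite half-life),
#' never as a negative half-life.
#'
#' @param x a `decay_timecourse` (with `species_id`) or a numeric vector of
#'   intensities (with `times`).
#' @param species_id species to fit when `x` is a time course.
#' @param times timepoints (minutes) when `x` is a numeric vector.
#' @param floor censoring floor for intensities (default 0: only
#'   non-positive values are censored).
#' @param conf_level confidence level of the half-life interval.
#' @return list of class `decay_fit`: `k_hat` (1/minute), `half_life`
#'   (minutes; `Inf` when stable), `stable`, `ci` (half-life CI), `r2`,
#'   `n_used`.
#' @export
fit_half_life <- function(x, species_id = NULL, times = NULL, floor = 0,
                          conf_level = 0.95) {
  if (inherits(x, "decay_timecourse")) {
    if (is.null(species_id)) stopf("species_id required for a time course")
    times <- x$time
    y <- x$abundance[species_id, ]
  } else {
    y <- as.numeric(x)
    if (is.null(times)) stopf("'times' required for a numeric series")
  }
  keep <- y > floor
  if (any(!keep)) warnf("censoring %d intensity value(s) at/below the floor", sum(!keep))
  y <- y[keep]; t <- times[keep]
  if (length(y) < 3) stopf("need >= 3 positive timepoints")
  fit <- stats::lm(log(y) ~ t)
  slope <- unname(stats::coef(fit)[2])
  k <- -slope
  # noiseless exponentials fit perfectly; summary()'s warning about that
  # is expected here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(k) || k <= 0) {
    return(structure(list(k_hat = max(k, 0), half_life = Inf, stable = TRUE,
                          ci = c(NA_real_, NA_real_), r2 = r2, n_used = length(y)),
                     class = "decay_fit"))
  }
  ci_slope <- tryCatch(suppressWarnings(stats::confint(fit, "t", level = conf_level)),
                       error = function(e) matrix(NA_real_, 1, 2))
  ci_k <- sort(-as.numeric(ci_slope))
  ci_hl <- rev(log(2) / pmax(ci_k, .Machine$double.eps))
  structure(list(k_hat = k, half_life = log(2) / k, stable = FALSE,
                 ci = ci_hl, r2 = r2, n_used = length(y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$stable) cat("<decay_fit> stable (no measurable decay)\n")
  else cat(sprintf("<decay_fit> half-life %.2f min (k = %.4f/min, r2 = %.3f)\n",
                   x$half_life, x$k_hat, x$r2))
  invisible(x)
}

#' Predict the Northern-blot band pattern at a probe position
#'
#' For wild type and each depletion condition present in the pathway,
#' simulates the rifampicin chase from the condition's pre-chase steady
#' state and reports which probe-overlapping species stay above the
#' detection floor, with half-lives fitted from the post-peak part of each
#' simulated trace.
#'
#' @param pathway a [decay_pathway()].
#' @param scenario a [depletion_scenario()].
#' @param probe_position transcript coordinate the probe hybridizes at.
#' @param timepoints chase sampling grid (minutes).
#' @param detection_floor minimum abundance for a band to be visible.
#' @return data.frame: `condition`, `species`, `visible`, `max_abundance`,
#'   `half_life`, `stable`.
#' @export
predict_band_pattern <- function(pathway, scenario = depletion_scenario(),
                                 probe_position,
                                 timepoints = seq(0, 15, by = 1.25),
                                 detection_floor = 0.05) {
  stopifnot(inherits(pathway, "decay_pathway"))
  sp <- pathway$species
  overlapping <- sp$id[sp$start <= probe_position & probe_position < sp$end]
  if (length(overlapping) == 0) {
    warnf("probe position %s lies outside every species", probe_position)
    return(data.frame(condition = character(), species = character(),
                      visible = logical(), max_abundance = numeric(),
                      half_life = numeric(), stable = logical(),
                      stringsAsFactors = FALSE))
  }
  enzymes <- setdiff(unique(pathway$reactions$enzyme), "")
  conditions <- c("wt", enzymes)
  rows <- list()
  for (cond in conditions) {
    depl <- if (cond == "wt") NULL else cond
    tc <- simulate_decay_timecourse(pathway, scenario, timepoints, depleted = depl)
    for (s in overlapping) {
      trace <- tc$abundance[s, ]
      peak <- which.max(trace)
      hl <- NA_real_; stab <- NA
      if (length(trace) - peak + 1 >= 3 && trace[peak] > 0) {
        f <- suppressWarnings(
          fit_half_life(trace[peak:length(trace)],
                        times = timepoints[peak:length(timepoints)]))
        hl <- f$half_life; stab <- f$stable
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, species = s,
        visible = max(trace) >= detection_floor,
        max_abundance = max(trace), half_life = hl, stable = stab,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify an abundance change as transcriptional or post-transcriptional
#'
#' At steady state, abundance is proportional to synthesis rate times
#' half-life. A fold-change in abundance matched by a comparable
#' fold-change in half-life is post-transcriptional; an abundance change
#' with an essentially unchanged half-life must come from synthesis
#' (transcriptional); intermediate cases - a stabilized transcript whose
#' half-life change cannot explain the accumulation - are `mixed`.
#'
#' @param abundance_fc fold-change in steady-state abundance (> 0).
#' @param halflife_fc fold-change in fitted half-life (> 0).
#' @param tolerance slack factor (default 1.5): post-transcriptional when
#'   `halflife_fc >= abundance_fc / tolerance`; transcriptional when
#'   `halflife_fc <= tolerance` while the abundance change exceeds it.
#' @return one of `"transcriptional"`, `"post_transcriptional"`, `"mixed"`.
#' @export
classify_effect <- function(abundance_fc, halflife_fc, tolerance = 1.5) {
  if (abundance_fc <= 0 || halflife_fc <= 0)
    stopf("fold-changes must be positive")
  if (halflife_fc >= abundance_fc / tolerance) return("post_transcriptional")
  if (halflife_fc <= tolerance) return("transcriptional")
  "mixed"
}
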