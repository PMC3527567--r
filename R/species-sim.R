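#' Define a virtual species by its niche
#'
#' A virtual species responds to one or more environmental layers through
#' either a Gaussian response (an `optimum` and a `breadth`, the classic
#' unimodal niche) or a monotone logistic response (a `midpoint` and a
#' `slope`; negative slopes give declining responses). Per-layer responses
#' multiply into a true suitability in \[0, 1\], so the true range is known
#' exactly and every downstream stage can be checked against it.
#'
#' @param id species identifier.
#' @param responses named list, one element per layer, each a list with
#'   `type = "gaussian"` (`optimum`, `breadth > 0`) or `type = "logistic"`
#'   (`midpoint`, `slope`).
#' @param type habitat-breadth flag: `"S"` (specialist) or `"G"`
#'   (generalist).
#' @param group taxonomic group label (e.g. `"Rodentia"`, `"Chiroptera"`).
#' @param predator_of,competitor_of character vectors of species ids this
#'   species preys on / competes with.
#' @param detectability positive scalar multiplying sampling weights.
#' @return An object of class `nc_species_spec`.
#' @export
species_spec <- function(id, responses, type = c("G", "S"),
                         group = "Rodentia", predator_of = character(),
                         competitor_of = character(), detectability = 1) {
  type <- match.arg(type)
  if (length(responses) < 1 || is.null(names(responses))) {
    abort("at least one named layer response is required",
          class = "nc_config_error")
  }
  for (nm in names(responses)) {
    r <- responses[[nm]]
    r$type <- match.arg(r$type, c("gaussian", "logistic"))
    if (r$type == "gaussian" && (is.null(r$breadth) || r$breadth <= 0)) {
      abort(paste("breadth must be > 0 for layer", nm),
            class = "nc_config_error")
    }
    responses[[nm]] <- r
  }
  structure(list(id = id, responses = responses, type = type, group = group,
                 predator_of = predator_of, competitor_of = competitor_of,
                 detectability = detectability),
            class = "nc_species_spec")
}

#' True suitability of a virtual species on a stack
#'
#' @param spec a [species_spec()].
#' @param env an [env_stack()] containing every layer the species responds
#'   to.
#' @return Numeric matrix in \[0, 1\].
#' @export
true_suitability <- function(spec, env) {
  stopifnot(inherits(spec, "nc_species_spec"), inherits(env, "nc_env_stack"))
  missing <- setdiff(names(spec$responses), env_layer_names(env))
  if (length(missing) > 0) {
    abort(paste("stack lacks layer(s):", paste(missing, collapse = ", ")),
          class = "nc_grid_error")
  }
  suit <- matrix(1, nrow(env$region), ncol(env$region))
  for (nm in names(spec$responses)) {
    r <- spec$responses[[nm]]
    v <- env$layers[[nm]]
    suit <- suit * switch(r$type,
      gaussian = exp(-(v - r$optimum)^2 / (2 * r$breadth^2)),
      logistic = plogis(r$slope * (v - r$midpoint))
    )
  }
  suit
}

#' Known-truth summary for a set of virtual species
#'
#' Evaluates each species' true suitability on the current and future
#' stacks, thresholds it into true occupancy, and records true range areas
#' and the imposed shift (centroid displacement of true occupancy). The
#' result is the ground truth that parameter-recovery tests compare model
#' output against.
#'
#' @param specs list of [species_spec()] objects.
#' @param env_current,env_future [env_stack()] objects for the two periods.
#' @param occupancy_threshold suitability cut-off defining true occupancy.
#' @return A tibble with one row per species and list-columns holding the
#'   suitability grids and [binary_range()] occupancies.
#' @export
truth_set <- function(specs, env_current, env_future,
                      occupancy_threshold = 0.5) {
  rows <- purrr::map(specs, function(sp) {
    s0 <- true_suitability(sp, env_current)
    s1 <- true_suitability(sp, env_future)
    r0 <- binary_range(s0 >= occupancy_threshold, env_current$cell_km,
                       region = env_current$region)
    r1 <- binary_range(s1 >= occupancy_threshold, env_future$cell_km,
                       region = env_future$region)
    shift <- if (sum(r0$cells) > 0 && sum(r1$cells) > 0) {
      centroid_shift(r0, r1)
    } else {
      tibble::tibble(distance_km = NA_real_, bearing_deg = NA_real_,
                     zero_shift = NA)
    }
    tibble::tibble(
      species = sp$id,
      suitability_current = list(s0), suitability_future = list(s1),
      occupancy_current = list(r0), occupancy_future = list(r1),
      area_current = range_area(r0), area_future = range_area(r1),
      shift_km = shift$distance_km, shift_bearing_deg = shift$bearing_deg
    )
  })
  dplyr::bind_rows(rows)
}

#' Regional sampling-bias surface
#'
#' Emulates the uneven recording effort of portal data: cells inside the
#' well-sampled calibration subregion get `strength` times the sampling
#' weight of cells outside it.
#'
#' @param env an [env_stack()].
#' @param strength weight ratio between the well-sampled and under-sampled
#'   subregions (default 10).
#' @return Numeric matrix of non-negative sampling weights.
#' @export
sampling_bias <- function(env, strength = 10) {
  stopifnot(strength >= 0)
  1 + (strength - 1) * env$calibration
}

#' Sample presence-only occurrence records
#'
#' Draws `n` presence records with probability proportional to
#' `true suitability x bias x detectability`, restricted to the region
#' mask. Records carry cell-center coordinates in kilometres and a
#' simulated observation date.
#'
#' @param spec a [species_spec()].
#' @param env an [env_stack()].
#' @param bias non-negative weight matrix (e.g. [sampling_bias()]); `NULL`
#'   for uniform effort.
#' @param n number of records (>= 1).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return A tibble with columns `species`, `x`, `y`, `date`, `status`
#'   (`"raw"`).
#' @export
sample_occurrences <- function(spec, env, bias = NULL, n, seed = 1L) {
  stopifnot(inherits(spec, "nc_species_spec"), n >= 1)
  bias <- bias %||% matrix(1, nrow(env$region), ncol(env$region))
  if (any(bias < 0)) abort("bias must be non-negative",
                           class = "nc_sampling_error")
  w <- true_suitability(spec, env) * bias * spec$detectability
  w[!env$region] <- 0
  if (sum(w) <= 0) abort("all sampling weights are zero",
                         class = "nc_sampling_error")
  nr <- nrow(w); nc <- ncol(w)
  ctr <- cell_centers(nr, nc, env$cell_km)
  with_seed(seed, {
    idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
    row <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    tibble::tibble(
      species = spec$id,
      x = ctr$x[col], y = ctr$y[row],
      date = as.Date("2000-01-01") + sample.int(4018, n, replace = TRUE) - 1L,
      status = "raw"
    )
  })
}

#' Traits table for a set of virtual species
#'
#' @param specs list of [species_spec()] objects.
#' @return A tibble with `species`, `type`, `group`, and list-columns
#'   `predator_of`, `competitor_of`.
#' @export
species_traits <- function(specs) {
  dplyr::bind_rows(purrr::map(specs, function(sp) {
    tibble::tibble(species = sp$id, type = sp$type, group = sp$group,
                   predator_of = list(sp$predator_of),
                   competitor_of = list(sp$competitor_of))
  }))
}

#' A default community of virtual species
#'
#' Builds `n_species` thermal-niche species on a landscape: each responds to
#' the first climate layer with a Gaussian optimum staggered along the
#' north-south gradient (so warming pushes every range poleward), and
#' specialists additionally respond to one vegetation layer. Useful as a
#' ready-made community for examples and pipeline runs.
#'
#' @param config a [landscape_config()].
#' @param n_species number of species.
#' @param breadth niche breadth of the thermal response.
#' @param specialist_frac fraction of species flagged `"S"` and tied to a
#'   vegetation layer.
#' @return List of [species_spec()] objects.
#' @export
default_community <- function(config, n_species = 5, breadth = 0.8,
                              specialist_frac = 0.4) {
  grad <- config$gradient[1]
  purrr::map(seq_len(n_species), function(i) {
    opt <- grad * (0.25 + 0.5 * (i - 1) / max(1, n_species - 1))
    specialist <- i <= round(specialist_frac * n_species)
    responses <- list(bio1 = list(type = "gaussian", optimum = opt,
                                  breadth = breadth))
    if (specialist && config$n_veg > 0) {
      responses$veg1 <- list(type = "logistic", midpoint = grad / 4, slope = 2)
    }
    species_spec(
      id = sprintf("species_%02d", i), responses = responses,
      type = if (specialist) "S" else "G",
      group = if (i %% 5 == 0) "Chiroptera" else "Rodentia"
    )
  })
}
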