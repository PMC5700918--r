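#' Per-step demographic transition probabilities
#'
#' Constant per-step event probabilities filling the transition slots of
#' the lattice model: larval mortality, metamorphosis (immature becomes
#' one female adult in the same cell), adult mortality, and oviposition
#' (a female converts the empty immature slot of her own cell). The
#' shipped defaults are calibration placeholders chosen to keep
#' populations persistent over a 300-step run; they are not measured
#' rates.
#'
#' @param immature_mortality,metamorphosis,adult_mortality,oviposition
#'   probabilities in `[0, 1]` per step (oviposition is per female).
#' @return object of class `transition_rates`.
#' @export
transition_rates <- function(immature_mortality = 0.02,
                             metamorphosis = 0.05,
                             adult_mortality = 0.05,
                             oviposition = 0.30) {
  r <- c(immature_mortality = immature_mortality,
         metamorphosis = metamorphosis,
         adult_mortality = adult_mortality,
         oviposition = oviposition)
  check_prob(r, "transition rates")
  structure(as.list(r), class = "transition_rates")
}

#' Scenario configuration for the lattice model
#'
#' One simulation condition: the landscape (dominant crop plus
#' contamination by the opposite variety), the movement kernels, the
#' demographic rates, the initial population, and the run length. The six
#' study conditions are `a1`/`a2`/`a3` (Bt-dominant, 0/10/20% non-Bt
#' contamination) and `b1`/`b2`/`b3` (non-Bt-dominant, 0/10/20% Bt
#' contamination); see [default_battery()].
#'
#' @param id scenario identifier (e.g. `"a1"`).
#' @param dominant dominant crop, `"BT"` or `"NONBT"`.
#' @param contamination contamination fraction (0, 0.10 or 0.20 in the
#'   study conditions).
#' @param width,height lattice size in cells (default 100 x 100).
#' @param radius_bt,radius_nonbt larval Chebyshev dispersal radii on Bt
#'   (default 3, a 7 x 7 region) and non-Bt (default 1, a 3 x 3 region)
#'   cells.
#' @param adult_radius adult Chebyshev dispersal radius (default 35).
#' @param carrying_capacity maximum female adults per cell (default 10).
#' @param steps time steps per replicate (default 300).
#' @param replicates replicates per scenario (default 50).
#' @param rates a [transition_rates()].
#' @param init_block side of the centred square block of cells initially
#'   occupied by larvae (default 20, i.e. 400 larvae); no initial adults.
#' @param seed master seed for the scenario.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(id = "a1", dominant = c("BT", "NONBT"),
                            contamination = 0, width = 100, height = 100,
                            radius_bt = 3, radius_nonbt = 1,
                            adult_radius = 35, carrying_capacity = 10,
                            steps = 300, replicates = 50,
                            rates = transition_rates(), init_block = 20,
                            seed = 1) {
  dominant <- match.arg(dominant)
  if (radius_bt < 0 || radius_nonbt < 0 || adult_radius < 0)
    abort("radii must be >= 0")
  if (steps < 0 || replicates < 1)
    abort("`steps` must be >= 0 and `replicates` >= 1")
  if (carrying_capacity < 1) abort("`carrying_capacity` must be >= 1")
  if (init_block < 1 || init_block > min(width, height))
    abort("`init_block` must fit inside the lattice")
  stopifnot(inherits(rates, "transition_rates"))
  structure(
    list(id = id, dominant = dominant, contamination = contamination,
         width = as.integer(width), height = as.integer(height),
         radius_bt = as.integer(radius_bt),
         radius_nonbt = as.integer(radius_nonbt),
         adult_radius = as.integer(adult_radius),
         carrying_capacity = as.integer(carrying_capacity),
         steps = as.integer(steps), replicates = as.integer(replicates),
         rates = rates, init_block = as.integer(init_block),
         seed = as.integer(seed)),
    class = "scenario_config")
}

#' The six study scenarios
#'
#' Builds the default battery: resistant larvae on a Bt-dominant landscape
#' with 0/10/20% non-Bt contamination (`a1`-`a3`) and on a
#' non-Bt-dominant landscape with 0/10/20% Bt contamination (`b1`-`b3`),
#' all sharing kernels, rates and run length.
#'
#' @param seed master seed stored in every config.
#' @param ... overrides passed to [scenario_config()] (e.g. `steps`,
#'   `replicates`, `width` for a smoke battery).
#' @return named list of six `scenario_config` objects.
#' @export
default_battery <- function(seed = 1, ...) {
  specs <- list(a1 = c("BT", 0), a2 = c("BT", 0.10), a3 = c("BT", 0.20),
                b1 = c("NONBT", 0), b2 = c("NONBT", 0.10),
                b3 = c("NONBT", 0.20))
  out <- lapply(names(specs), function(id) {
    scenario_config(id = id, dominant = specs[[id]][1],
                    contamination = as.numeric(specs[[id]][2]),
                    seed = seed, ...)
  })
  names(out) <- names(specs)
  out
}

#' One larval dispersal sweep
#'
#' Larvae are processed in random order; each draws one uniform candidate
#' within the Chebyshev ball of its cell's crop-dependent radius and moves
#' iff the destination is empty at that moment (single occupancy). The
#' larva count is conserved.
#'
#' @param larvae 0/1 integer occupancy matrix.
#' @param landscape a [build_landscape()] object.
#' @param radius_bt,radius_nonbt Chebyshev radii by crop.
#' @return updated occupancy matrix.
#' @export
larval_dispersal_step <- function(larvae, landscape, radius_bt = 3,
                                  radius_nonbt = 1) {
  check_grid01(larvae)
  .larval_dispersal_step_cpp(larvae, landscape$crop_bt,
                             as.integer(radius_bt),
                             as.integer(radius_nonbt))
}

#' One adult dispersal sweep
#'
#' Each female (random order) draws one uniform candidate cell within the
#' adult Chebyshev radius and moves iff the destination holds fewer than
#' `carrying_capacity` females. The adult count is conserved.
#'
#' @param adults integer count matrix (0..K per cell).
#' @param radius adult Chebyshev radius (default 35).
#' @param carrying_capacity maximum females per cell (default 10).
#' @return updated count matrix.
#' @export
adult_dispersal_step <- function(adults, radius = 35,
                                 carrying_capacity = 10) {
  if (any(adults < 0) || any(adults > carrying_capacity))
    abort("adult counts must lie in [0, carrying_capacity]")
  .adult_dispersal_step_cpp(adults, as.integer(radius),
                            as.integer(carrying_capacity))
}

#' One demographic transition sweep
#'
#' Applies, in order: immature mortality, metamorphosis (the immature cell
#' empties; one female is added to the same cell if below the carrying
#' capacity), adult mortality, and oviposition (each female converts the
#' empty immature slot of her own cell with the oviposition probability;
#' at most one egg per cell per step).
#'
#' @param larvae 0/1 occupancy matrix.
#' @param adults adult count matrix.
#' @param rates a [transition_rates()].
#' @param carrying_capacity maximum females per cell.
#' @return list with updated `larvae` and `adults`.
#' @export
transition_step <- function(larvae, adults, rates = transition_rates(),
                            carrying_capacity = 10) {
  check_grid01(larvae)
  stopifnot(inherits(rates, "transition_rates"))
  .transition_step_cpp(larvae, adults, rates$immature_mortality,
                       rates$metamorphosis, rates$adult_mortality,
                       rates$oviposition, as.integer(carrying_capacity))
}

check_grid01 <- function(larvae) {
  if (!all(larvae %in% c(0L, 1L)))
    abort("larval grid must contain only 0/1 occupancy values")
  invisible(larvae)
}

#' Mean distance of larvae to the centre of their distribution
#'
#' The centroid is the arithmetic mean of the occupied-cell coordinates;
#' the endpoint is the mean Euclidean distance of occupied cells to that
#' centroid, in cell units.
#'
#' @param larvae 0/1 occupancy matrix with at least one larva.
#' @return mean distance (cell units).
#' @export
mean_distance_to_centre <- function(larvae) {
  pts <- which(larvae == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0) abort("no larvae on the grid")
  centroid <- colMeans(pts)
  mean(sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2))
}

#' Larval density of the lattice
#'
#' @param larvae 0/1 occupancy matrix.
#' @param landscape optional [build_landscape()] (only its cell count is
#'   used; defaults to the grid's own dimensions).
#' @return occupied cells divided by total cells, in `[0, 1]`.
#' @export
larval_density <- function(larvae, landscape = NULL) {
  total <- if (is.null(landscape)) length(larvae)
           else landscape$width * landscape$height
  sum(larvae == 1L) / total
}

# internal: initial grids for a scenario
init_population <- function(config, landscape) {
  larvae <- matrix(0L, config$height, config$width)
  half <- config$init_block
  r0 <- floor((config$height - half) / 2) + 1L
  c0 <- floor((config$width - half) / 2) + 1L
  larvae[r0:(r0 + half - 1L), c0:(c0 + half - 1L)] <- 1L
  adults <- matrix(0L, config$height, config$width)
  list(larvae = larvae, adults = adults)
}

#' Run one replicate of a scenario
#'
#' Seeds the RNG, builds the landscape, initializes the population (a
#' centred block of larvae, no adults) and iterates
#' transition -> larval dispersal -> adult dispersal for `config$steps`
#' steps, then measures the endpoints. A replicate whose population is
#' extinct at the final step is flagged by a missing `mean_distance` and
#' zero density.
#'
#' @param config a [scenario_config()].
#' @param seed replicate seed (defaults to the config's master seed).
#' @param trajectory if `TRUE`, also record per-step larva and adult
#'   totals.
#' @return one-row data.frame with columns `scenario`, `seed`,
#'   `mean_distance`, `larval_density`, `final_larvae`, `final_adults`
#'   (plus a `trajectory` attribute when requested).
#' @export
run_replicate <- function(config, seed = config$seed, trajectory = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  land <- build_landscape(config$width, config$height, config$dominant,
                          config$contamination)
  st <- init_population(config, land)
  traj <- if (trajectory)
    data.frame(step = integer(), larvae = integer(), adults = integer())
  for (s in seq_len(config$steps)) {
    st <- transition_step(st$larvae, st$adults, config$rates,
                          config$carrying_capacity)
    st$larvae <- larval_dispersal_step(st$larvae, land, config$radius_bt,
                                       config$radius_nonbt)
    st$adults <- adult_dispersal_step(st$adults, config$adult_radius,
                                      config$carrying_capacity)
    if (trajectory)
      traj <- rbind(traj, data.frame(step = s, larvae = sum(st$larvae),
                                     adults = sum(st$adults)))
  }
  n_larvae <- sum(st$larvae)
  out <- data.frame(
    scenario = config$id, seed = seed,
    mean_distance = if (n_larvae > 0) mean_distance_to_centre(st$larvae)
                    else NA_real_,
    larval_density = larval_density(st$larvae, land),
    final_larvae = n_larvae, final_adults = sum(st$adults),
    stringsAsFactors = FALSE)
  if (trajectory) attr(out, "trajectory") <- traj
  out
}

#' Run a scenario battery with Tukey-Kramer comparisons
#'
#' Runs every configured scenario for its number of replicates (child
#' seeds derived deterministically from `seed`) and compares the
#' mean-distance and larval-density endpoints across scenarios with the
#' Tukey-Kramer test.
#'
#' @param configs named list of [scenario_config()]s, e.g.
#'   [default_battery()].
#' @param seed master seed for replicate seed derivation.
#' @param alpha significance level for the comparisons (default 0.05).
#' @return object of class `battery_result`: list with `results`
#'   (replicate rows: scenario, replicate, seed, mean_distance,
#'   larval_density, final_larvae, final_adults) and `tukey` (a list with
#'   `mean_distance` and `larval_density` elements, each a `tukey_cmp`).
#' @export
run_battery <- function(configs, seed = 1, alpha = 0.05) {
  stopifnot(length(configs) >= 1)
  reps <- vapply(configs, function(cf) cf$replicates, integer(1))
  seeds <- derive_seeds(seed, sum(reps))
  rows <- vector("list", sum(reps))
  k <- 0L
  for (cf in configs) {
    for (r in seq_len(cf$replicates)) {
      k <- k + 1L
      row <- run_replicate(cf, seed = seeds[k])
      row$replicate <- r
      rows[[k]] <- row
    }
  }
  results <- do.call(rbind, rows)
  results <- results[c("scenario", "replicate", "seed", "mean_distance",
                       "larval_density", "final_larvae", "final_adults")]
  tukey <- lapply(c(mean_distance = "mean_distance",
                    larval_density = "larval_density"), function(v) {
    dat <- results[!is.na(results[[v]]), c("scenario", v)]
    if (length(unique(dat$scenario)) < 2) return(NULL)
    fit <- lm(stats::reformulate("scenario", response = v), data = dat)
    tukey_pairwise(fit, "scenario", alpha = alpha)
  })
  structure(list(results = results, tukey = tukey, alpha = alpha),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat(sprintf("Scenario battery: %d replicate rows, %d scenarios\n",
              nrow(x$results), length(unique(x$results$scenario))))
  agg <- stats::aggregate(
    cbind(mean_distance, larval_density) ~ scenario,
    data = x$results, FUN = mean, na.action = stats::na.omit)
  print(agg, row.names = FALSE)
  for (v in names(x$tukey)) {
    if (is.null(x$tukey[[v]])) next
    cat(sprintf("\nTukey-Kramer letters (%s):\n", v))
    print(x$tukey[[v]]$letters, row.names = FALSE)
  }
  invisible(x)
}
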