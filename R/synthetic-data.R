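#' Generate a synthetic host-acceptance bioassay table
#'
#' Draws one record per block x strain x variety x exposure interval. The
#' five larval fates of each plant's released neonates (on-plant fed,
#' on-plant not fed, off-plant fed, off-plant not fed, unrecovered) are
#' drawn as a single multinomial, which makes the count-conservation
#' identity exact by construction. The category probabilities come from
#' the fate chain: recovered-alive with the strain's logistic-in-time
#' survival probability, then on/off plant, then fed/not-fed;
#' "unrecovered" jointly absorbs death and escape, so survival means
#' recovered alive.
#'
#' @param design a [bioassay_design()].
#' @param params a [bioassay_params()].
#' @param seed optional integer seed; identical seeds give identical
#'   tables.
#' @return data.frame with columns `block`, `strain`, `variety`,
#'   `interval_h`, `released`, `on_fed`, `on_notfed`, `off_fed`,
#'   `off_notfed`, `unrecovered`.
#' @examples
#' tab <- generate_bioassay(bioassay_design(), bioassay_params(), seed = 1)
#' nrow(tab) # 4 blocks x 2 strains x 2 varieties x 4 intervals = 64
#' @export
generate_bioassay <- function(design, params = bioassay_params(),
                              seed = NULL) {
  stopifnot(inherits(design, "bioassay_design"),
            inherits(params, "bioassay_params"))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(block = seq_len(design$n_blocks),
                      strain = design$strains,
                      variety = design$varieties,
                      interval_h = design$intervals_h,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$block, grid$strain, grid$variety,
                     grid$interval_h), , drop = FALSE]
  n <- nrow(grid)
  counts <- matrix(0L, n, 5)
  for (k in seq_len(n)) {
    p_alive <- survival_probability(params, grid$strain[k], grid$interval_h[k])
    p_on <- lookup2(params$on_plant_prob, grid$strain[k],
                    grid$interval_h[k], "on_plant_prob")
    p_fed_on <- lookup2(params$fed_given_on_prob, grid$strain[k],
                        grid$variety[k], "fed_given_on_prob")
    p_fed_off <- lookup2(params$fed_given_off_prob, grid$strain[k],
                         grid$variety[k], "fed_given_off_prob")
    probs <- c(on_fed = p_alive * p_on * p_fed_on,
               on_notfed = p_alive * p_on * (1 - p_fed_on),
               off_fed = p_alive * (1 - p_on) * p_fed_off,
               off_notfed = p_alive * (1 - p_on) * (1 - p_fed_off),
               unrecovered = 1 - p_alive)
    counts[k, ] <- as.integer(rmultinom(1, design$larvae_per_plant, probs))
  }
  out <- data.frame(grid, released = design$larvae_per_plant,
                    on_fed = counts[, 1], on_notfed = counts[, 2],
                    off_fed = counts[, 3], off_notfed = counts[, 4],
                    unrecovered = counts[, 5],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Default video-tracking group means
#'
#' Mean movement endpoints per strain x variety group for
#' [generate_tracks()]. The distance pattern encodes the key contrast of
#' the tracking assay: Cry1F-resistant neonates on non-Bt cotton move about
#' one third of the distance they move on Bt cotton (sedentary behaviour
#' in the absence of toxin exposure), while the susceptible strain moves
#' comparably on both varieties. Velocity and mobility-period means are
#' invented on the same qualitative pattern.
#'
#' @return data.frame with columns `strain`, `variety`, `distance_cm`,
#'   `velocity_cm_s`, `mobility_s`.
#' @export
default_track_means <- function() {
  data.frame(
    strain = c("SS", "SS", "RR", "RR"),
    variety = c("BT_WS", "NONBT", "BT_WS", "NONBT"),
    distance_cm = c(90, 75, 90, 30),
    velocity_cm_s = c(0.060, 0.055, 0.060, 0.045),
    mobility_s = c(1100, 1000, 1100, 800),
    stringsAsFactors = FALSE)
}

#' Generate synthetic video-tracking endpoints
#'
#' Draws per-larva movement endpoints (distance moved in cm, mean velocity
#' in cm/s, continuous mobility period in s) with log-normal noise around
#' group means, giving the positive support and right skew typical of
#' movement data. The log-normal is mean-parameterized: the expected value
#' of each endpoint equals its group mean for any dispersion, and as
#' `dispersion -> 0` every record equals its group mean.
#'
#' @param n_per_group larvae per strain x variety group.
#' @param group_means data.frame as [default_track_means()].
#' @param dispersion log-scale standard deviation of the noise
#'   (default 0.3).
#' @param seed optional integer seed.
#' @return data.frame with one row per larva and columns `strain`,
#'   `variety`, `distance_cm`, `velocity_cm_s`, `mobility_s`.
#' @export
generate_tracks <- function(n_per_group, group_means = default_track_means(),
                            dispersion = 0.3, seed = NULL) {
  if (n_per_group < 1) abort("`n_per_group` must be >= 1")
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  vars <- c("distance_cm", "velocity_cm_s", "mobility_s")
  if (!all(c("strain", "variety", vars) %in% names(group_means)))
    abort("`group_means` must have columns strain, variety, ",
          paste(vars, collapse = ", "))
  if (any(as.matrix(group_means[vars]) <= 0))
    abort("all group means must be positive")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(group_means)), function(g) {
    draws <- sapply(vars, function(v) {
      m <- group_means[[v]][g]
      if (dispersion == 0) rep(m, n_per_group)
      else rlnorm(n_per_group, meanlog = log(m) - dispersion^2 / 2,
                  sdlog = dispersion)
    })
    draws <- matrix(draws, nrow = n_per_group,
                    dimnames = list(NULL, vars))
    data.frame(strain = group_means$strain[g],
               variety = group_means$variety[g], draws,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
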