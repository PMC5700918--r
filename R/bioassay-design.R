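#' Factorial bioassay design
#'
#' Describes the randomized-block factorial host-acceptance bioassay:
#' blocks x strains x cotton varieties x exposure-time intervals, with a
#' fixed number of neonates released per plant. The default mirrors the
#' two-variety assay (susceptible and Cry1F-resistant strains on WideStrike
#' Bt cotton and its non-Bt isoline, inspected 6/12/18/24 h after
#' infestation, 20 neonates per plant). Pass three varieties (adding
#' `"BT_TL"`, TwinLink) for the resistant-strain assay.
#'
#' @param n_blocks number of complete blocks (default 4).
#' @param strains character vector of strain labels; `"SS"` (susceptible)
#'   and/or `"RR"` (Cry1F-resistant).
#' @param varieties character vector of variety labels among `"BT_WS"`
#'   (WideStrike), `"BT_TL"` (TwinLink), `"NONBT"` (non-Bt isoline).
#' @param intervals_h strictly increasing exposure times in hours.
#' @param larvae_per_plant neonates released on each plant (default 20).
#' @return an object of class `bioassay_design`.
#' @export
bioassay_design <- function(n_blocks = 4,
                            strains = c("SS", "RR"),
                            varieties = c("BT_WS", "NONBT"),
                            intervals_h = c(6, 12, 18, 24),
                            larvae_per_plant = 20) {
  if (n_blocks < 1 || larvae_per_plant < 1)
    abort("`n_blocks` and `larvae_per_plant` must be positive counts")
  if (length(strains) == 0 || length(varieties) == 0 || length(intervals_h) == 0)
    abort("empty design: strains, varieties and intervals must be non-empty")
  if (anyDuplicated(strains) || anyDuplicated(varieties) ||
      anyDuplicated(intervals_h))
    abort("strain, variety and interval labels must be unique")
  if (is.unsorted(intervals_h, strictly = TRUE))
    abort("`intervals_h` must be strictly increasing")
  structure(
    list(n_blocks = as.integer(n_blocks), strains = strains,
         varieties = varieties, intervals_h = as.numeric(intervals_h),
         larvae_per_plant = as.integer(larvae_per_plant)),
    class = "bioassay_design")
}

#' Probability parameters of the synthetic bioassay
#'
#' Parameters of the per-larva fate chain used by [generate_bioassay()]:
#' a larva is first recovered alive with the logistic-in-time survival
#' probability of its strain, then found on or off the plant, then
#' classified as having fed or not. Defaults reproduce the marginal
#' structure of the source assay: the survival logits are the fitted
#' logistic-regression models for the susceptible
#' (`2.7690 - 0.1470 t`) and Cry1F-resistant (`1.1089 - 0.0483 t`)
#' strains, and the on-plant probabilities are the observed mean
#' percentages of larvae found on plants per strain and interval.
#' Feeding probabilities have no printed source values; the defaults
#' encode the qualitative pattern (more feeding on-plant than off-plant,
#' higher on-plant feeding for the resistant strain on Bt cotton,
#' more post-feeding dispersal on non-Bt cotton).
#'
#' @param survival_logit named list per strain of `c(b0, b1)`: intercept
#'   (logit units) and slope (logit units per hour) of survival over time.
#' @param on_plant_prob matrix (strain x interval) of probabilities that a
#'   recovered larva is found on the plant; column names are the exposure
#'   times in hours.
#' @param fed_given_on_prob,fed_given_off_prob matrices (strain x variety)
#'   of feeding probabilities conditional on being found on/off the plant.
#' @param survival_prob optional matrix (strain x interval) of survival
#'   probabilities overriding the logistic model, e.g. to set a free
#'   unrecovered fraction per interval.
#' @return an object of class `bioassay_params`.
#' @export
bioassay_params <- function(
    survival_logit = list(SS = c(b0 = 2.7690, b1 = -0.1470),
                          RR = c(b0 = 1.1089, b1 = -0.0483)),
    on_plant_prob = default_on_plant_prob(),
    fed_given_on_prob = default_fed_prob("on"),
    fed_given_off_prob = default_fed_prob("off"),
    survival_prob = NULL) {
  for (s in names(survival_logit)) {
    b <- survival_logit[[s]]
    if (length(b) != 2 || anyNA(b))
      abort("each `survival_logit` entry must be c(b0, b1)")
  }
  check_prob(on_plant_prob, "on_plant_prob")
  check_prob(fed_given_on_prob, "fed_given_on_prob")
  check_prob(fed_given_off_prob, "fed_given_off_prob")
  if (!is.null(survival_prob)) check_prob(survival_prob, "survival_prob")
  structure(
    list(survival_logit = survival_logit, on_plant_prob = on_plant_prob,
         fed_given_on_prob = fed_given_on_prob,
         fed_given_off_prob = fed_given_off_prob,
         survival_prob = survival_prob),
    class = "bioassay_params")
}

#' Default on-plant probabilities (strain x interval)
#'
#' Observed mean percentages of neonates found on the plant per strain and
#' exposure interval, expressed as probabilities.
#'
#' @return matrix with rows `SS`, `RR` and columns `6`, `12`, `18`, `24`.
#' @export
default_on_plant_prob <- function() {
  m <- rbind(SS = c(64.83, 59.00, 33.50, 47.98),
             RR = c(62.68, 65.80, 75.80, 73.38)) / 100
  colnames(m) <- c("6", "12", "18", "24")
  m
}

#' Default feeding probabilities (strain x variety)
#'
#' Invented defaults (no printed source values) encoding the qualitative
#' feeding pattern; see [bioassay_params()].
#'
#' @param where `"on"` for feeding conditional on being found on the plant,
#'   `"off"` for feeding conditional on being found off the plant.
#' @return matrix with rows `SS`, `RR` and columns `BT_WS`, `BT_TL`, `NONBT`.
#' @export
default_fed_prob <- function(where = c("on", "off")) {
  where <- match.arg(where)
  m <- if (where == "on") {
    rbind(SS = c(0.55, 0.55, 0.75), RR = c(0.80, 0.80, 0.80))
  } else {
    rbind(SS = c(0.35, 0.35, 0.55), RR = c(0.35, 0.35, 0.55))
  }
  colnames(m) <- c("BT_WS", "BT_TL", "NONBT")
  m
}

# internal: look up a strain x key matrix entry with clear errors
lookup2 <- function(m, strain, key, what) {
  if (!strain %in% rownames(m))
    abort(sprintf("`%s` has no row for strain '%s'", what, strain))
  if (!as.character(key) %in% colnames(m))
    abort(sprintf("`%s` has no column for '%s'", what, key))
  m[strain, as.character(key)]
}

# internal: survival probability for one strain at exposure time t
survival_probability <- function(params, strain, t_h) {
  if (!is.null(params$survival_prob))
    return(lookup2(params$survival_prob, strain, t_h, "survival_prob"))
  b <- params$survival_logit[[strain]]
  if (is.null(b))
    abort(sprintf("`survival_logit` has no entry for strain '%s'", strain))
  stats::plogis(b[["b0"]] + b[["b1"]] * t_h)
}
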