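#' Quasi-binomial logistic regression of survival on exposure time
#'
#' Fits recovered-alive/released against exposure time with a logit link
#' and quasi-binomial variance, the standard model for overdispersed
#' binomial bioassay data. Returns the intercept `b0` (logit units) and
#' slope `b1` (logit units per hour), with standard errors scaled by the
#' quasi-likelihood dispersion estimate.
#'
#' @param records bioassay table (see [generate_bioassay()]).
#' @param strain optional strain label to subset to before fitting.
#' @return object of class `logistic_fit`: list with elements `strain`,
#'   `b0`, `b1`, `se` (named vector), `dispersion`, `deviance`,
#'   `confint` (95% Wald intervals on the dispersion-scaled SEs),
#'   `separation` flag and the underlying `glm` fit.
#' @examples
#' tab <- generate_bioassay(bioassay_design(n_blocks = 50), seed = 1)
#' fit_survival_logistic(tab, strain = "SS")
#' @export
fit_survival_logistic <- function(records, strain = NULL) {
  validate_bioassay(records)
  if (!is.null(strain)) {
    records <- records[records$strain == strain, , drop = FALSE]
    if (nrow(records) == 0)
      abort(sprintf("no records for strain '%s'", strain))
  }
  alive <- records$released - records$unrecovered
  t_h <- records$interval_h
  if (length(unique(t_h)) < 2)
    abort("need >= 2 distinct exposure times to fit a slope")
  fit <- glm(cbind(alive, records$released - alive) ~ t_h,
             family = quasibinomial())
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))   # vcov already scaled by dispersion
  separation <- any(!is.finite(cf)) || any(abs(cf) > 20)
  if (separation)
    warning("possible complete separation: infinite or extreme ",
            "coefficients; estimates are unreliable", call. = FALSE)
  zc <- qnorm(0.975)
  ci <- cbind(lower = cf - zc * se, upper = cf + zc * se)
  rownames(ci) <- c("b0", "b1")
  structure(
    list(strain = strain, b0 = unname(cf[1]), b1 = unname(cf[2]),
         se = c(b0 = unname(se[1]), b1 = unname(se[2])),
         dispersion = summary(fit)$dispersion,
         deviance = fit$deviance, confint = ci,
         separation = separation, fit = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Quasi-binomial logistic survival regression",
      if (!is.null(x$strain)) sprintf("(strain %s)", x$strain), "\n")
  cat(sprintf("  logit(survival) = %.4f %+.4f * time_h\n", x$b0, x$b1))
  cat(sprintf("  SE: b0 %.4f, b1 %.4f; dispersion %.3f\n",
              x$se["b0"], x$se["b1"], x$dispersion))
  if (x$separation) cat("  WARNING: separation suspected\n")
  invisible(x)
}

#' Predicted survival from a logistic fit
#'
#' @param object a `logistic_fit`.
#' @param t_h exposure times (hours).
#' @param ... unused.
#' @return predicted survival probabilities in (0, 1).
#' @export
predict.logistic_fit <- function(object, t_h, ...) {
  stats::plogis(object$b0 + object$b1 * t_h)
}

#' Half-normal residual plot coordinates with a simulated envelope
#'
#' Goodness-of-fit diagnostic for a binomial-type GLM: sorted absolute
#' deviance residuals against half-normal quantiles, with a simulated
#' envelope obtained by re-drawing binomial responses from the fitted
#' probabilities and refitting. Returned as data, not a rendered figure.
#'
#' @param fit a `logistic_fit` or a binomial/quasi-binomial `glm` whose
#'   response is a two-column success/failure matrix.
#' @param nsim number of simulations for the envelope (default 99).
#' @param level envelope coverage taken as the simulation-wise
#'   `(1-level)/2` and `1-(1-level)/2` quantiles (default 0.95).
#' @return data.frame with columns `index`, `quantile` (half-normal),
#'   `observed`, `lower`, `upper`.
#' @export
halfnormal_envelope <- function(fit, nsim = 99, level = 0.95) {
  g <- if (inherits(fit, "logistic_fit")) fit$fit else fit
  if (!inherits(g, "glm")) abort("`fit` must be a glm or logistic_fit")
  y <- g$y # proportion scale for binomial matrix response
  w <- g$prior.weights
  n <- length(y)
  obs <- sort(abs(residuals(g, type = "deviance")))
  p_hat <- g$fitted.values
  X <- stats::model.matrix(g)
  fam <- binomial()
  sims <- matrix(NA_real_, nsim, n)
  for (s in seq_len(nsim)) {
    succ <- rbinom(n, size = w, prob = p_hat)
    sim_fit <- suppressWarnings(
      stats::glm.fit(X, succ / w, weights = w, family = fam))
    mu <- sim_fit$fitted.values
    d <- fam$dev.resids(succ / w, mu, w)
    sims[s, ] <- sort(sqrt(pmax(d, 0)))
  }
  alpha <- (1 - level) / 2
  data.frame(
    index = seq_len(n),
    quantile = qnorm((seq_len(n) + n - 1 / 8) / (2 * n + 1 / 2)),
    observed = obs,
    lower = apply(sims, 2, quantile, probs = alpha),
    upper = apply(sims, 2, quantile, probs = 1 - alpha))
}
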