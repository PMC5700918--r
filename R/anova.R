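#' Factorial ANOVA after a Box-Cox transformation
#'
#' Estimates the Box-Cox power parameter by profile log-likelihood on a
#' grid, transforms the response, fits the factorial linear model by least
#' squares, and returns the sequential analysis-of-variance effect table
#' (effect, df, F, P) together with the chosen lambda. Proportions equal
#' to zero can be lifted with a small `offset` (0.5 divided by the count
#' denominator is the usual choice) so the power transform is defined.
#'
#' @param data data.frame holding the response and the design factors,
#'   e.g. a [compute_metrics()] table.
#' @param response name of the response column (must be positive after the
#'   offset is applied).
#' @param rhs right-hand side of the model formula, default
#'   `~ block + variety * strain * interval_h`; non-numeric terms are
#'   coerced to factors, and `block` and `interval_h` are treated as
#'   factors as in a randomized-block factorial analysis.
#' @param lambda fixed Box-Cox lambda, or `NULL` (default) to estimate it
#'   on the grid `seq(-2, 2, 0.01)` by profile log-likelihood. `lambda = 1`
#'   is an affine transform, so the F statistics equal those of the
#'   untransformed analysis.
#' @param offset value added to zero responses before transforming
#'   (default `NULL`: none).
#' @return object of class `anova_fit`: list with `table` (data.frame:
#'   effect, df, F, P), `lambda`, `offset`, the fitted `lm` in `fit`, and
#'   the transformed data in `data`.
#' @export
boxcox_anova <- function(data, response,
                         rhs = ~ block + variety * strain * interval_h,
                         lambda = NULL, offset = NULL) {
  if (!response %in% names(data))
    abort(sprintf("no column '%s' in `data`", response))
  y <- data[[response]]
  if (anyNA(y)) {
    keep <- !is.na(y)
    data <- data[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (!is.null(offset)) y[y == 0] <- y[y == 0] + offset
  if (any(y <= 0))
    abort("response must be strictly positive for the Box-Cox transform; ",
          "use the `offset` argument to lift zero proportions")
  vars <- all.vars(rhs)
  missing <- setdiff(vars, names(data))
  if (length(missing))
    abort("model terms not in `data`: ", paste(missing, collapse = ", "))
  for (v in vars) data[[v]] <- factor(data[[v]])
  data$.y <- y
  form <- stats::update.formula(rhs, .y ~ .)
  if (is.null(lambda)) {
    bc <- MASS::boxcox(form, data = data, lambda = seq(-2, 2, 0.01),
                       plotit = FALSE)
    lambda <- bc$x[which.max(bc$y)]
  }
  data$.y <- boxcox_transform(y, lambda)
  fit <- lm(form, data = data)
  av <- anova(fit)
  eff <- rownames(av)
  keep <- eff != "Residuals"
  tab <- data.frame(effect = eff[keep], df = av$Df[keep],
                    F = av$`F value`[keep], P = av$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  structure(list(table = tab, lambda = lambda, offset = offset,
                 df_residual = fit$df.residual, fit = fit, data = data),
            class = "anova_fit")
}

#' Box-Cox power transform
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` at `lambda = 0`.
#'
#' @param y positive numeric vector.
#' @param lambda power parameter.
#' @return transformed vector.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) abort("`y` must be strictly positive")
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("Box-Cox ANOVA (lambda = %.2f)\n", x$lambda))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey / Tukey-Kramer pairwise comparisons with letter display
#'
#' Compares all level means of one factor (or the cell means of an
#' interaction) of a fitted linear model using the studentized-range
#' distribution. Unequal group sizes use the Tukey-Kramer standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))`. A compact letter display is built by
#' insert-and-absorb: groups sharing a letter are not significantly
#' different at `alpha`; groups are ordered by descending mean and ties
#' broken in that order.
#'
#' @param fit an `anova_fit`, or an `lm`.
#' @param term character vector of factor names whose cells to compare
#'   (one name for a main effect, several for interaction cells).
#' @param alpha significance level for the letter display (default 0.05).
#' @return object of class `tukey_cmp`: list with `comparisons`
#'   (data.frame: group1, group2, diff, se, q, p_adj) and `letters`
#'   (data.frame: group, n, mean, letters).
#' @export
tukey_pairwise <- function(fit, term, alpha = 0.05) {
  lmfit <- if (inherits(fit, "anova_fit")) fit$fit else fit
  if (!inherits(lmfit, "lm")) abort("`fit` must be an lm or anova_fit")
  mf <- model.frame(lmfit)
  y <- stats::model.response(mf)
  missing <- setdiff(term, names(mf))
  if (length(missing))
    abort("term not in the model frame: ", paste(missing, collapse = ", "))
  g <- interaction(mf[term], sep = ":", drop = TRUE)
  if (nlevels(g) < 2) abort("need >= 2 groups to compare")
  mse <- sum(residuals(lmfit)^2) / lmfit$df.residual
  dfe <- lmfit$df.residual
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  k <- nlevels(g)
  pairs <- utils::combn(levels(g), 2)
  cmp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    stringsAsFactors = FALSE)
  cmp$diff <- as.numeric(means[cmp$group1] - means[cmp$group2])
  cmp$se <- as.numeric(sqrt(mse / 2 *
                              (1 / ns[cmp$group1] + 1 / ns[cmp$group2])))
  cmp$q <- abs(cmp$diff) / cmp$se
  cmp$p_adj <- ptukey(cmp$q, nmeans = k, df = dfe, lower.tail = FALSE)
  rownames(cmp) <- NULL
  sig <- cmp$p_adj < alpha
  letters_df <- compact_letters(levels(g)[order(-means)],
                                cmp[sig, c("group1", "group2")])
  letters_df <- letters_df[match(levels(g), letters_df$group), ]
  letters_df$n <- as.integer(ns[letters_df$group])
  letters_df$mean <- as.numeric(means[letters_df$group])
  rownames(letters_df) <- NULL
  structure(list(comparisons = cmp,
                 letters = letters_df[c("group", "n", "mean", "letters")],
                 alpha = alpha, mse = mse, df = dfe),
            class = "tukey_cmp")
}

# internal: insert-and-absorb compact letter display.
# `order` gives the groups (already sorted, e.g. by descending mean);
# `sig_pairs` is a 2-column data.frame of significantly different pairs.
compact_letters <- function(ord, sig_pairs) {
  differ <- function(a, b) {
    any((sig_pairs$group1 == a & sig_pairs$group2 == b) |
        (sig_pairs$group1 == b & sig_pairs$group2 == a))
  }
  # start with one column containing all groups; split (insert) whenever a
  # column holds a significantly different pair, then absorb duplicates
  cols <- list(ord)
  repeat {
    split_done <- FALSE
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      bad <- NULL
      for (i in seq_along(col)) {
        for (j in seq_len(i - 1L)) {
          if (differ(col[i], col[j])) { bad <- c(j, i); break }
        }
        if (!is.null(bad)) break
      }
      if (!is.null(bad)) {
        c1 <- col[-bad[2]]
        c2 <- col[-bad[1]]
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
        # absorb: drop columns contained in another
        keep <- rep(TRUE, length(cols))
        for (a in seq_along(cols)) {
          for (b in seq_along(cols)) {
            if (a != b && keep[a] && keep[b] &&
                all(cols[[a]] %in% cols[[b]]) &&
                (length(cols[[a]]) < length(cols[[b]]) || a > b))
              keep[a] <- FALSE
          }
        }
        cols <- cols[keep]
        split_done <- TRUE
        break
      }
    }
    if (!split_done) break
  }
  # order columns by the position of their first group, letter them
  first <- vapply(cols, function(cl) min(match(cl, ord)), numeric(1))
  cols <- cols[order(first)]
  lett <- vapply(ord, function(gp) {
    paste0(letters[which(vapply(cols, function(cl) gp %in% cl, logical(1)))],
           collapse = "")
  }, character(1))
  data.frame(group = ord, letters = unname(lett),
             stringsAsFactors = FALSE)
}

#' @export
print.tukey_cmp <- function(x, ...) {
  cat(sprintf("Tukey-Kramer comparisons (alpha = %.2f)\n", x$alpha))
  print(x$letters, row.names = FALSE)
  invisible(x)
}

#' Analyse video-tracking endpoints
#'
#' Fits a strain x variety factorial ANOVA for each movement endpoint
#' (distance moved, mean velocity, continuous mobility period) and builds
#' Tukey letter displays over the strain:variety cells. The endpoints are
#' analysed untransformed (`lambda = 1`) by default.
#'
#' @param tracks track table as from [generate_tracks()].
#' @param lambda Box-Cox lambda passed to [boxcox_anova()] (default 1).
#' @param alpha significance level for letters.
#' @return named list per endpoint, each with elements `anova`
#'   (an `anova_fit`) and `tukey` (a `tukey_cmp`).
#' @export
analyze_tracks <- function(tracks, lambda = 1, alpha = 0.05) {
  vars <- c("distance_cm", "velocity_cm_s", "mobility_s")
  missing <- setdiff(c("strain", "variety", vars), names(tracks))
  if (length(missing))
    abort("track table missing columns: ", paste(missing, collapse = ", "))
  out <- lapply(vars, function(v) {
    af <- boxcox_anova(tracks, v, rhs = ~ strain * variety, lambda = lambda)
    list(anova = af,
         tukey = tukey_pairwise(af, c("strain", "variety"), alpha = alpha))
  })
  names(out) <- vars
  out
}
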