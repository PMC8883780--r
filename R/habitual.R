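#' Box-Cox transform and its inverse
#'
#' The habitual-intake model works on a Box-Cox-transformed scale on which
#' daily intakes are approximately normal: g(y) = ((y + shift)^lambda - 1) /
#' lambda, or log(y + shift) at lambda = 0. The shift admits observed zeros.
#'
#' @param y original-scale values (>= 0)
#' @param lambda Box-Cox exponent (0 = log)
#' @param shift non-negative shift applied before transforming
#' @return transformed values
#' @keywords internal
box_cox <- function(y, lambda, shift = 0) {
  ys <- y + shift
  if (any(ys <= 0)) stop("non-positive value after shift", call. = FALSE)
  if (lambda == 0) log(ys) else (ys^lambda - 1) / lambda
}

# Inverse of the transform WITHOUT the shift subtraction; arguments outside
# the transform's domain (lambda*z + 1 < 0) are clipped to the boundary.
box_cox_inv_raw <- function(z, lambda) {
  if (lambda == 0) return(exp(z))
  pmax(lambda * z + 1, 0)^(1 / lambda)
}

#' Select a Box-Cox transform for pooled daily intakes
#'
#' Chooses lambda from the fixed grid 0, 0.1, ..., 1 maximising the Box-Cox
#' profile log-likelihood of the pooled daily values. The shift is 0 when all
#' values are positive, otherwise half the smallest positive value (so zero
#' intakes remain representable on the log scale).
#'
#' @param daily_values numeric vector of daily intakes (>= 20 positive values
#'   required)
#' @return list with \code{lambda}, \code{shift} (a transform spec)
#' @export
select_transform <- function(daily_values) {
  y <- daily_values[!is.na(daily_values)]
  pos <- y[y > 0]
  if (length(pos) == 0L) stop("all daily values are zero", call. = FALSE)
  if (length(pos) < 20L) {
    stop("need at least 20 positive daily values to select a transform",
         call. = FALSE)
  }
  shift <- if (all(y > 0)) 0 else min(pos) / 2
  grid <- seq(0, 1, by = 0.1)
  n <- length(y)
  ll <- vapply(grid, function(lam) {
    z <- box_cox(y, lam, shift)
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (lam - 1) * sum(log(y + shift))
  }, numeric(1))
  list(lambda = grid[which.max(ll)], shift = shift)
}

#' Method-of-moments variance components for repeated daily intakes
#'
#' Separates the variance of transformed daily intakes into a between-person
#' and a within-person (day-to-day) component. For the balanced 2-day design
#' the estimators are exact closed forms: sigma2_within is the mean over
#' persons of (d1 - d2)^2 / 2, and sigma2_between is the sample variance of
#' person means minus sigma2_within / 2, floored at zero. Persons with
#' unequal numbers of days (>= 2 each) are handled by the pooled-within
#' generalisation.
#'
#' @param person_day data.frame with columns \code{participant_id} and
#'   \code{value} (transformed-scale daily intakes), one row per person-day
#' @return list with \code{mu} (grand mean of person means),
#'   \code{sigma2_between}, \code{sigma2_within}, and the per-person table
#'   \code{person} (\code{participant_id}, \code{mean}, \code{n_days})
#' @export
fit_variance_components <- function(person_day) {
  pd <- as.data.frame(person_day, stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "value") %in% names(pd)))
  ids <- unique(pd$participant_id)
  if (length(ids) < 2L) stop("need at least 2 persons", call. = FALSE)
  f <- factor(pd$participant_id, levels = ids)
  n_i <- as.integer(table(f))
  if (any(n_i < 2L)) {
    stop("every person needs at least 2 daily values", call. = FALSE)
  }
  m_i <- as.numeric(tapply(pd$value, f, mean))
  ss_within <- sum((pd$value - m_i[as.integer(f)])^2)
  sigma2_within <- ss_within / sum(n_i - 1L)
  sigma2_between <- max(0, stats::var(m_i) - sigma2_within * mean(1 / n_i))
  list(mu = mean(m_i),
       sigma2_between = sigma2_between,
       sigma2_within = sigma2_within,
       person = data.frame(participant_id = ids, mean = m_i, n_days = n_i,
                           stringsAsFactors = FALSE))
}

#' Shrink person means toward the population mean
#'
#' The habitual value of person i on the transformed scale is estimated by
#' contracting the observed person mean toward the grand mean:
#' t_i = mu + c_i (m_i - mu), with
#' c_i = sqrt(sigma2_between / (sigma2_between + sigma2_within / n_i)).
#' The square-root factor matches the spread of the shrunken values to the
#' between-person standard deviation, which is what distribution (percentile
#' and fraction-below) estimation needs. When sigma2_between is 0 all
#' habitual values collapse to mu.
#'
#' @param components output of \code{\link{fit_variance_components}}
#' @param person_means transformed-scale person means; defaults to the means
#'   stored in \code{components}
#' @param n_days number of days per person (scalar or vector); defaults to
#'   those stored in \code{components}
#' @return transformed-scale habitual values
#' @export
shrink_person_means <- function(components,
                                person_means = components$person$mean,
                                n_days = components$person$n_days) {
  s2b <- components$sigma2_between
  s2w <- components$sigma2_within
  if (s2b == 0) return(rep(components$mu, length(person_means)))
  c_i <- sqrt(s2b / (s2b + s2w / n_days))
  components$mu + c_i * (person_means - components$mu)
}

# E[f(e)] for e ~ N(0, sd^2) by n-point Gauss-Hermite quadrature.
gauss_hermite_expectation <- function(f, sd, n_points = 9L) {
  gh <- pracma::gaussHermite(n_points)
  nodes <- sqrt(2) * sd * gh$x
  vals <- vapply(nodes, f, numeric(length(f(0))))
  if (is.matrix(vals)) {
    as.numeric(vals %*% gh$w) / sqrt(pi)
  } else {
    sum(gh$w * vals) / sqrt(pi)
  }
}

#' Bias-corrected back-transformation of habitual values
#'
#' Maps transformed-scale habitual values back to the original intake scale.
#' A plain inverse transform would be biased because the original-scale mean
#' of a person's daily intakes involves the within-person noise; the
#' corrected value is the expectation of the inverse transform over that
#' noise, habitual_i = E[g^-1(t_i + e)] with e ~ N(0, sigma2_within),
#' evaluated by 9-point Gauss-Hermite quadrature. Inverse-transform arguments
#' outside the Box-Cox domain are clipped to the boundary; the shift is
#' subtracted afterwards and the result floored at 0. At lambda = 0 the
#' integral has the lognormal-mean closed form exp(t_i + sigma2_within / 2) -
#' shift, which the quadrature reproduces.
#'
#' @param transform list with \code{lambda}, \code{shift}
#'   (\code{\link{select_transform}})
#' @param components output of \code{\link{fit_variance_components}}
#' @param t_values transformed-scale habitual values
#'   (\code{\link{shrink_person_means}})
#' @param n_points Gauss-Hermite order; default 9
#' @return original-scale habitual values (>= 0)
#' @export
back_transform_habitual <- function(transform, components, t_values,
                                    n_points = 9L) {
  sd_w <- sqrt(components$sigma2_within)
  if (sd_w == 0) {
    raw <- box_cox_inv_raw(t_values, transform$lambda)
  } else {
    gh <- pracma::gaussHermite(n_points)
    nodes <- sqrt(2) * sd_w * gh$x
    w <- gh$w / sqrt(pi)
    raw <- vapply(t_values, function(t) {
      sum(w * box_cox_inv_raw(t + nodes, transform$lambda))
    }, numeric(1))
  }
  pmax(raw - transform$shift, 0)
}

#' Estimate the habitual-intake distribution from repeated daily intakes
#'
#' The full one-part pipeline: select a Box-Cox transform from the pooled
#' daily values, estimate between- and within-person variance components on
#' the transformed scale, shrink person means toward the grand mean to remove
#' the within-person variance inflation, and back-transform with bias
#' correction. Deterministic given its input.
#'
#' @param daily data.frame with columns \code{participant_id}, \code{value}
#'   (original-scale daily intakes; 2 or more days per person)
#' @param weights per-person analysis weights: either NULL (uniform), or a
#'   data.frame \code{participant_id}, \code{analysis_weight}
#' @param body_weight_kg optional data.frame \code{participant_id},
#'   \code{body_weight_kg}, carried for per-kg cut-off evaluation
#' @return object of class \code{habitual_distribution}: list with
#'   \code{person} (data.frame participant_id, person_mean, habitual,
#'   analysis_weight, and body_weight_kg when supplied), \code{transform},
#'   \code{components}
#' @export
estimate_habitual_distribution <- function(daily, weights = NULL,
                                           body_weight_kg = NULL) {
  daily <- as.data.frame(daily, stringsAsFactors = FALSE)
  transform <- select_transform(daily$value)
  td <- daily
  td$value <- box_cox(daily$value, transform$lambda, transform$shift)
  components <- fit_variance_components(td)
  t_hab <- shrink_person_means(components)
  habitual <- back_transform_habitual(transform, components, t_hab)

  person <- components$person
  orig_means <- tapply(daily$value,
                       factor(daily$participant_id,
                              levels = person$participant_id), mean)
  out <- data.frame(participant_id = person$participant_id,
                    person_mean = as.numeric(orig_means),
                    habitual = habitual,
                    stringsAsFactors = FALSE)
  out$analysis_weight <- if (is.null(weights)) {
    1
  } else {
    w <- weights$analysis_weight[match(out$participant_id,
                                       weights$participant_id)]
    if (anyNA(w) || any(w <= 0)) {
      stop("missing or non-positive analysis weight", call. = FALSE)
    }
    w
  }
  if (!is.null(body_weight_kg)) {
    out$body_weight_kg <- body_weight_kg$body_weight_kg[
      match(out$participant_id, body_weight_kg$participant_id)]
  }
  structure(list(person = out, transform = transform,
                 components = components),
            class = "habitual_distribution")
}

#' @export
print.habitual_distribution <- function(x, ...) {
  w <- x$person$analysis_weight / sum(x$person$analysis_weight)
  cat("<habitual_distribution> ", nrow(x$person), " persons; lambda = ",
      x$transform$lambda, ", shift = ", signif(x$transform$shift, 4),
      "\n  sigma2_between = ", signif(x$components$sigma2_between, 5),
      ", sigma2_within = ", signif(x$components$sigma2_within, 5),
      "\n  weighted mean habitual = ", signif(sum(w * x$person$habitual), 5),
      "\n", sep = "")
  invisible(x)
}

#' Weighted fraction of the population below a habitual-intake cut-off
#'
#' With \code{per_kg = FALSE} (default) habitual values are daily amounts
#' (e.g. g protein/d) and each person's value is divided by body weight
#' before comparison with the cut-off; with \code{per_kg = TRUE} the habitual
#' values are already per kg and are compared directly.
#'
#' @param distribution a \code{habitual_distribution}
#' @param cutoff cut-off, in g/kg BW/d (default mode) or the habitual value's
#'   own units (\code{per_kg = TRUE})
#' @param per_kg are the habitual values already per kg body weight?
#' @return analysis-weighted proportion strictly below the cut-off, in [0, 1]
#' @export
fraction_below <- function(distribution, cutoff, per_kg = FALSE) {
  p <- distribution$person
  val <- if (per_kg) {
    p$habitual
  } else {
    if (is.null(p$body_weight_kg) || anyNA(p$body_weight_kg)) {
      stop("body weights required to evaluate a per-kg cut-off",
           call. = FALSE)
    }
    p$habitual / p$body_weight_kg
  }
  w <- p$analysis_weight / sum(p$analysis_weight)
  sum(w * as.numeric(val < cutoff))
}

#' Weighted percentiles of the habitual-intake distribution
#'
#' @param distribution a \code{habitual_distribution}
#' @param probs probabilities; default the 1st-99th percentiles
#' @return named numeric vector of weighted quantiles
#' @export
habitual_percentiles <- function(distribution, probs = (1:99) / 100) {
  p <- distribution$person
  ord <- order(p$habitual)
  x <- p$habitual[ord]
  w <- p$analysis_weight[ord] / sum(p$analysis_weight)
  cw <- cumsum(w) - w / 2          # midpoint rule for weighted quantiles
  q <- stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
  names(q) <- paste0("p", probs * 100)
  q
}
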