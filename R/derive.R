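#' Derived total-genetic-value (co)variances
#'
#' Applies the genetic-group identities draw-wise over the posterior:
#' Var(u_f) = Var(a_f) + g_f^2 Var(q), Var(u_m) analogously, and
#' cov(u_f, u_m) = cov(a_f, a_m) + g_f g_m Var(q), with Var(q) a plug-in
#' constant computed across phenotyped individuals. Each retained draw is
#' transformed, never the posterior means. The inequality
#' Var(u) >= Var(a) and the sign law
#' sign(cov_u - cov_a) = sign(g_f g_m Var(q)) are checked on every draw.
#'
#' @param fit an \code{epp_fit} (or any object with a \code{draws} matrix
#'   containing columns \code{var_af}, \code{var_am}, \code{cov_afam},
#'   \code{g_f}, \code{g_m}).
#' @param var_q nonnegative plug-in variance of q (defaults to the value
#'   stored in the fit's design).
#' @return object of class \code{epp_derived} with a draw matrix of
#'   \code{var_uf}, \code{var_um}, \code{cov_ufum} and attribute
#'   \code{var_q}.
#' @export
derive_u_covariances <- function(fit, var_q = fit$design$q$var_q) {
  if (is.null(var_q) || is.na(var_q)) stop("var_q is required")
  if (var_q < 0) stop("var_q must be nonnegative")
  d <- fit$draws
  var_uf <- d[, "var_af"] + d[, "g_f"]^2 * var_q
  var_um <- d[, "var_am"] + d[, "g_m"]^2 * var_q
  cov_ufum <- d[, "cov_afam"] + d[, "g_f"] * d[, "g_m"] * var_q
  stopifnot(all(var_uf >= d[, "var_af"]), all(var_um >= d[, "var_am"]))
  stopifnot(all(sign(round(cov_ufum - d[, "cov_afam"], 12)) ==
                  sign(round(d[, "g_f"] * d[, "g_m"] * var_q, 12))))
  structure(list(draws = cbind(var_uf = var_uf, var_um = var_um,
                               cov_ufum = cov_ufum),
                 var_q = var_q, source = d),
            class = "epp_derived")
}

#' Total additive genetic variances of the emergent trait
#'
#' Draw-wise totals for the joint brood-level trait:
#' Var(a_T) = Var(a_f) + 2 cov(a_f, a_m) + Var(a_m), the analogous
#' Var(u_T) over total genetic values, and their difference, which obeys
#' Var(u_T) - Var(a_T) = (g_f + g_m)^2 Var(q) >= 0 identically (verified on
#' every draw).
#'
#' @param derived an \code{epp_derived} from [derive_u_covariances()].
#' @return the input with draw columns \code{var_aT}, \code{var_uT},
#'   \code{delta_varT} appended.
#' @export
derive_totals <- function(derived) {
  stopifnot(inherits(derived, "epp_derived"))
  d <- derived$source
  u <- derived$draws
  var_aT <- d[, "var_af"] + 2 * d[, "cov_afam"] + d[, "var_am"]
  var_uT <- u[, "var_uf"] + 2 * u[, "cov_ufum"] + u[, "var_um"]
  delta <- var_uT - var_aT
  ident <- (d[, "g_f"] + d[, "g_m"])^2 * derived$var_q
  stopifnot(max(abs(delta - ident)) < 1e-8, all(delta > -1e-12))
  derived$draws <- cbind(u, var_aT = var_aT, var_uT = var_uT,
                         delta_varT = delta)
  derived
}

#' Cross-sex correlations and latent-scale heritabilities
#'
#' Draw-wise: cor(a_f, a_m) = cov / sqrt(Var(a_f) Var(a_m)) (same for u),
#' and per-sex heritability = additive genetic variance divided by the sum
#' of all estimated variance components (both sexes' additive variances,
#' permanent individual, pair, year, and residual). Optionally the logit
#' link variance pi^2/3 is added to the denominator.
#'
#' @param derived an \code{epp_derived} from [derive_totals()].
#' @param include_link_variance add pi^2/3 to the heritability denominator.
#' @return the input with \code{cor_afam}, \code{cor_ufum}, \code{h2_f},
#'   \code{h2_m} appended; draws with a zero variance (ratio undefined) are
#'   dropped with a reported count in attribute \code{n_skipped}.
#' @export
derive_correlations_and_h2 <- function(derived, include_link_variance = FALSE) {
  stopifnot(inherits(derived, "epp_derived"))
  d <- derived$source
  u <- derived$draws
  den_a <- d[, "var_af"] * d[, "var_am"]
  den_u <- u[, "var_uf"] * u[, "var_um"]
  ok <- den_a > 0 & den_u > 0
  n_skip <- sum(!ok)
  if (n_skip)
    message(n_skip, " draw(s) with zero variance skipped in ratio transforms")
  cor_afam <- d[ok, "cov_afam"] / sqrt(den_a[ok])
  cor_ufum <- u[ok, "cov_ufum"] / sqrt(den_u[ok])
  stopifnot(all(abs(cor_afam) <= 1 + 1e-12), all(abs(cor_ufum) <= 1 + 1e-12))
  vsum <- d[, "var_af"] + d[, "var_am"] + d[, "var_pe_f"] + d[, "var_pe_m"] +
    d[, "var_pair"] + d[, "var_year"] + d[, "var_residual"]
  if (include_link_variance) vsum <- vsum + pi^2 / 3
  derived$draws <- cbind(u[ok, , drop = FALSE],
                         cor_afam = cor_afam, cor_ufum = cor_ufum,
                         h2_f = d[ok, "var_af"] / vsum[ok],
                         h2_m = d[ok, "var_am"] / vsum[ok])
  derived$source <- d[ok, , drop = FALSE]
  attr(derived, "n_skipped") <- n_skip
  derived
}

#' Derive all posterior quantities
#'
#' Convenience wrapper chaining [derive_u_covariances()], [derive_totals()],
#' and [derive_correlations_and_h2()].
#'
#' @inheritParams derive_u_covariances
#' @inheritParams derive_correlations_and_h2
#' @return \code{epp_derived} with the full draw matrix.
#' @export
derive_all <- function(fit, var_q = fit$design$q$var_q,
                       include_link_variance = FALSE) {
  derive_correlations_and_h2(derive_totals(derive_u_covariances(fit, var_q)),
                             include_link_variance)
}

#' Mean of a logit-normal distribution
#'
#' E[logit^-1(eta + e)] with e ~ N(0, sigma2), by Gauss-Hermite quadrature.
#'
#' @param eta latent mean(s).
#' @param sigma2 latent variance(s), recycled against eta.
#' @param nodes number of quadrature nodes (>= 20 recommended).
#' @return expected probabilities, same length as eta.
#' @export
logit_normal_mean <- function(eta, sigma2, nodes = 30L) {
  stopifnot(all(sigma2 >= 0), nodes >= 2L)
  gh <- pracma::gaussHermite(nodes)
  k <- max(length(eta), length(sigma2))
  eta <- rep_len(eta, k)
  sigma2 <- rep_len(sigma2, k)
  vapply(seq_len(k), function(i)
    sum(gh$w * plogis(eta[i] + sqrt(2 * sigma2[i]) * gh$x)) / sqrt(pi),
    numeric(1))
}

#' Back-transform latent effects to the observed phenotypic scale
#'
#' For each posterior draw and each scenario (a group coefficient q, a year,
#' and a male age), computes the latent mean
#' eta = intercept + beta_year (year - baseline) + beta_age age +
#' (g_f + g_m) q and the expected extra-pair paternity rate
#' E[logit^-1(eta + e)] integrating over the brood-level latent residual
#' e ~ N(0, var_residual) by Gauss-Hermite quadrature. Comparing scenarios
#' with different q quantifies the phenotypic-scale effect of immigrant
#' ancestry.
#'
#' @param fit an \code{epp_fit}.
#' @param scenarios data frame with columns \code{q_value}, \code{year},
#'   \code{male_age} (one row per scenario).
#' @param baseline_year centering year (defaults to the fitted design's).
#' @param nodes Gauss-Hermite nodes.
#' @param integrate_over additional variance components to marginalize over
#'   (\code{"residual"} only by default; \code{"all"} adds the genetic,
#'   permanent, pair, and year variances).
#' @return matrix of rate draws, one column per scenario.
#' @export
back_transform <- function(fit, scenarios,
                           baseline_year = fit$design$baseline_year,
                           nodes = 30L,
                           integrate_over = c("residual", "all")) {
  integrate_over <- match.arg(integrate_over)
  scenarios <- as.data.frame(scenarios)
  stopifnot(all(c("q_value", "year", "male_age") %in% names(scenarios)),
            all(is.finite(as.matrix(scenarios[c("q_value", "year",
                                                "male_age")]))))
  d <- fit$draws
  out <- matrix(NA_real_, nrow(d), nrow(scenarios))
  sig2 <- d[, "var_residual"]
  if (integrate_over == "all")
    sig2 <- sig2 + d[, "var_af"] + d[, "var_am"] + 2 * d[, "cov_afam"] +
      d[, "var_pe_f"] + d[, "var_pe_m"] + d[, "var_pair"] + d[, "var_year"]
  for (s in seq_len(nrow(scenarios))) {
    eta <- d[, "intercept"] +
      d[, "beta_year"] * (scenarios$year[s] - baseline_year) +
      d[, "beta_age"] * scenarios$male_age[s] +
      (d[, "g_f"] + d[, "g_m"]) * scenarios$q_value[s]
    out[, s] <- logit_normal_mean(eta, sig2, nodes)
  }
  colnames(out) <- paste0("q_", scenarios$q_value)
  out
}
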