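#' Validate and normalize brood records
#'
#' @param broods data frame with columns \code{brood_id}, \code{year},
#'   \code{female_id}, \code{male_id}, \code{male_age}, \code{n_offspring},
#'   \code{n_epo}.
#' @param ped optional pedigree for sex consistency checks.
#' @return validated data frame.
#' @export
validate_broods <- function(broods, ped = NULL) {
  need <- c("brood_id", "year", "female_id", "male_id", "male_age",
            "n_offspring", "n_epo")
  miss <- setdiff(need, names(broods))
  if (length(miss))
    stop("brood table is missing column(s): ", paste(miss, collapse = ", "))
  broods$female_id <- as.character(broods$female_id)
  broods$male_id <- as.character(broods$male_id)
  if (any(broods$n_offspring < 1L))
    stop("broods with n_offspring < 1 are not valid observations")
  if (any(broods$n_epo < 0L | broods$n_epo > broods$n_offspring))
    stop("n_epo must lie in [0, n_offspring]")
  if (!is.null(ped)) {
    sex <- setNames(ped$sex, ped$id)
    unk <- setdiff(c(broods$female_id, broods$male_id), ped$id)
    if (length(unk))
      stop("brood parent(s) absent from pedigree: ",
           paste(head(unk, 5L), collapse = ", "))
    if (any(sex[broods$female_id] == "M", na.rm = TRUE) ||
        any(sex[broods$male_id] == "F", na.rm = TRUE))
      stop("brood sex roles conflict with pedigree sexes")
    both <- intersect(broods$female_id, broods$male_id)
    if (length(both))
      stop("individual(s) phenotyped in both sex roles: ",
           paste(head(both, 5L), collapse = ", "))
  }
  broods
}

#' Build animal-model design matrices
#'
#' Assembles the fixed design (intercept, female q, male q, centered year,
#' male age) and sparse incidence matrices linking each brood to its female's
#' and male's additive genetic effects (bivariate, over the full pedigree in
#' A-inverse order), permanent female and male effects, social-pair effects,
#' and year effects, plus a brood-level identity block for the latent
#' residual.
#'
#' @param ped pedigree (pruned; defines the A-inverse order).
#' @param q result of [compute_q()] (or any list with \code{q}, \code{var_q}).
#' @param broods validated brood records.
#' @param baseline_year year at which the year covariate is centered
#'   (default: first phenotype year).
#' @return object of class \code{epp_design}.
#' @export
build_design <- function(ped, q, broods, baseline_year = min(broods$year)) {
  broods <- validate_broods(broods, ped)
  n <- nrow(ped)
  nb <- nrow(broods)
  idx <- setNames(seq_len(n), ped$id)
  if (any(!c(broods$female_id, broods$male_id) %in% names(q$q)))
    stop("genetic-group coefficients missing for some brood parents")

  X <- cbind(intercept = 1,
             g_f = unname(q$q[broods$female_id]),
             g_m = unname(q$q[broods$male_id]),
             beta_year = broods$year - baseline_year,
             beta_age = broods$male_age)

  fi <- unname(idx[broods$female_id])
  mi <- unname(idx[broods$male_id])
  ## bivariate animal block: columns 1..n are a_f, n+1..2n are a_m
  Z_a <- Matrix::sparseMatrix(
    i = rep(seq_len(nb), 2L), j = c(fi, n + mi), x = 1,
    dims = c(nb, 2L * n))
  fl <- factor(broods$female_id)
  ml <- factor(broods$male_id)
  pl <- factor(paste(broods$female_id, broods$male_id, sep = "_"))
  yl <- factor(broods$year)
  inc <- function(f) Matrix::sparseMatrix(
    i = seq_len(nb), j = as.integer(f), x = 1,
    dims = c(nb, nlevels(f)))
  structure(list(
    X = X, Z_a = Z_a,
    Z_pe_f = inc(fl), Z_pe_m = inc(ml), Z_pair = inc(pl), Z_year = inc(yl),
    levels = list(pe_f = levels(fl), pe_m = levels(ml), pair = levels(pl),
                  year = levels(yl)),
    ped = ped, q = q, broods = broods, baseline_year = baseline_year,
    n_ped = n, n_brood = nb), class = "epp_design")
}

#' Default priors
#'
#' Conventional weakly informative defaults: independent zero-mean normal
#' priors with large variance on fixed effects; an inverse-Wishart prior on
#' the 2x2 latent-scale genetic covariance matrix G; inverse-gamma priors
#' (shape nu/2, rate nu V/2) on each scalar variance component.
#'
#' @param fixed_var prior variance of fixed effects.
#' @param G_nu,G_scale inverse-Wishart degrees of freedom and 2x2 scale
#'   matrix for G.
#' @param nu,V inverse-gamma hyperparameters for scalar variances.
#' @return object of class \code{epp_priors}.
#' @export
default_priors <- function(fixed_var = 1e8, G_nu = 2, G_scale = diag(2),
                           nu = 1, V = 1) {
  stopifnot(fixed_var > 0, G_nu > 1, all(eigen(G_scale)$values > 0),
            nu > 0, V > 0)
  structure(list(fixed_var = fixed_var, G_nu = G_nu, G_scale = G_scale,
                 ig_shape = nu / 2, ig_rate = nu * V / 2),
            class = "epp_priors")
}

## scalar variance blocks in sampling order
SCALAR_BLOCKS <- c("pe_f", "pe_m", "pair", "year")

#' Fit the genetic-groups animal model by MCMC
#'
#' Gibbs sampler for the brood-level binomial animal model on the latent
#' logit scale. The binomial likelihood is handled by Polya-Gamma
#' augmentation of the brood counts (each brood's offspring share one linear
#' predictor that includes a brood-level residual, giving additive latent
#' overdispersion). All location effects (fixed effects, bivariate animal
#' effects with precision kronecker(G^-1, A^-1), permanent individual, pair,
#' year, and brood residual effects) are updated in one sparse joint
#' Gaussian draw; G is updated from its conditional inverse-Wishart and the
#' scalar variances from conditional inverse-gammas.
#'
#' With \code{family = "gaussian"} the sampler runs an identity-link
#' reduction: the response \code{y} (per brood) is Gaussian with residual
#' variance \code{var_residual}, the brood residual block is dropped, and
#' the same machinery applies; this mode exists for validating the sampler
#' against conjugate results.
#'
#' @param design an [build_design()] result.
#' @param priors an [default_priors()] result.
#' @param chain list with \code{n_iter}, \code{burn_in}, \code{thin},
#'   \code{seed} (seed is mandatory).
#' @param family \code{"binomial"} (default) or \code{"gaussian"}.
#' @param save_animal_draws retain the per-individual additive genetic draws
#'   (needed by [predict_genetic_values()]).
#' @param include_random random-effect blocks to include; dropping blocks
#'   (e.g. everything, for a fixed-effects-only conjugate reduction) reports
#'   \code{NA} for the corresponding variance components.
#' @param gaussian_y numeric response for the Gaussian reduction.
#' @param fix_residual optional fixed residual variance (Gaussian mode).
#' @param verbose print progress every 1,000 iterations.
#' @return object of class \code{epp_fit}: \code{draws} (retained samples by
#'   parameter), optional \code{a_draws}, \code{a_mean}, chain metadata and
#'   autocorrelation diagnostics.
#' @export
fit_mcmc <- function(design, priors = default_priors(),
                     chain = list(n_iter = 13000L, burn_in = 3000L,
                                  thin = 5L, seed = 1L),
                     family = c("binomial", "gaussian"),
                     save_animal_draws = TRUE,
                     include_random = c("animal", SCALAR_BLOCKS),
                     gaussian_y = NULL, fix_residual = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(design, "epp_design"), inherits(priors, "epp_priors"))
  family <- match.arg(family)
  bad_blocks <- setdiff(include_random, c("animal", SCALAR_BLOCKS))
  if (length(bad_blocks))
    stop("unknown random-effect block(s): ", paste(bad_blocks, collapse = ", "))
  if (is.null(chain$seed)) stop("chain$seed is mandatory")
  set.seed(chain$seed)
  n_iter <- as.integer(chain$n_iter)
  burn_in <- as.integer(chain$burn_in)
  thin <- max(1L, as.integer(chain$thin))

  nb <- design$n_brood
  np <- design$n_ped
  nf <- ncol(design$X)
  use_animal <- "animal" %in% include_random
  sc_use <- intersect(SCALAR_BLOCKS, include_random)
  use_resid_block <- family == "binomial"
  if (!use_animal) save_animal_draws <- FALSE
  Ainv <- if (use_animal) compute_A_inverse(design$ped)$Ainv else NULL

  parts <- list(fixed = methods::as(design$X, "CsparseMatrix"))
  if (use_animal) parts$animal <- design$Z_a
  for (bn in sc_use) parts[[bn]] <- design[[paste0("Z_", bn)]]
  if (use_resid_block) parts$resid <- Matrix::Diagonal(nb)
  dims <- vapply(parts, ncol, integer(1))
  p <- sum(dims)
  offs <- cumsum(c(0L, dims))
  idx_of <- setNames(lapply(seq_along(parts), function(k)
    (offs[k] + 1L):offs[k + 1L]), names(parts))
  i_fix <- idx_of$fixed
  i_a <- idx_of$animal
  i_e <- idx_of$resid

  W <- do.call(cbind, unname(parts))
  Wt <- Matrix::t(W)

  y <- design$broods$n_epo
  ntr <- design$broods$n_offspring
  if (family == "gaussian") {
    if (is.null(gaussian_y)) stop("gaussian_y required for gaussian family")
    y <- gaussian_y
  }

  ## state; start G with nonzero covariance so the sparsity pattern of
  ## kronecker(G^-1, A^-1) includes the cross-sex coupling from the first
  ## symbolic analysis
  G <- matrix(c(1, 0.25, 0.25, 1), 2, 2)
  sig <- setNames(rep(1, length(SCALAR_BLOCKS)), SCALAR_BLOCKS)
  sig_e <- if (is.null(fix_residual)) 1 else fix_residual
  theta <- numeric(p)

  n_keep <- (n_iter - burn_in) %/% thin
  if (n_keep < 1L) stop("chain settings leave no retained draws")
  par_names <- c("intercept", "g_f", "g_m", "beta_year", "beta_age",
                 "var_af", "var_am", "cov_afam",
                 "var_pe_f", "var_pe_m", "var_pair", "var_year",
                 "var_residual")
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  a_draws <- if (save_animal_draws)
    matrix(NA_real_, n_keep, 2L * np) else NULL

  prior_fix <- rep(1 / priors$fixed_var, nf)
  ch <- NULL
  kept <- 0L

  for (it in seq_len(n_iter)) {
    eta <- as.numeric(W %*% theta)

    if (family == "binomial") {
      omega <- rpg(as.integer(ntr), eta)
      omega <- pmax(omega, 1e-10)
      kappa <- y - ntr / 2
    } else {
      omega <- rep(1 / sig_e, nb)
      kappa <- y / sig_e
    }

    ## joint location update
    prior_diag <- numeric(p)
    prior_diag[i_fix] <- prior_fix
    for (bn in sc_use) prior_diag[idx_of[[bn]]] <- 1 / sig[bn]
    if (use_resid_block) prior_diag[i_e] <- 1 / sig_e
    Q <- Matrix::crossprod(W * sqrt(omega)) + Matrix::Diagonal(x = prior_diag)
    if (use_animal) {
      Ginv <- chol2inv(chol(G))
      P_a <- Matrix::kronecker(Ginv, Ainv)
      Q <- Q + Matrix::bdiag(Matrix::Diagonal(nf, 0), P_a,
                             Matrix::Diagonal(p - nf - 2L * np, 0))
    }
    Q <- Matrix::forceSymmetric(Q)
    b <- as.numeric(Wt %*% kappa)
    if (is.null(ch)) {
      ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE, super = TRUE)
    } else {
      ## re-analyse if the nonzero pattern drifted (e.g. an exactly zero
      ## covariance draw); never accept a silently broken factor
      ch <- tryCatch(Matrix::update(ch, Q), error = function(e)
        Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE, super = TRUE))
    }
    mu <- as.numeric(Matrix::solve(ch, b, system = "A"))
    z <- rnorm(p)
    v <- Matrix::solve(ch, z, system = "Lt")
    theta <- mu + as.numeric(Matrix::solve(ch, v, system = "Pt"))
    if (!all(is.finite(theta)))
      stop("divergent chain at iteration ", it,
           ": non-finite location draw (G = [",
           paste(signif(G, 4), collapse = ", "),
           "], residual variance = ", signif(sig_e, 4), ")")

    ## G | a  ~ IW(nu0 + n_ped, Psi0 + M' Ainv M)
    if (use_animal) {
      M <- cbind(theta[i_a[seq_len(np)]], theta[i_a[np + seq_len(np)]])
      S <- as.matrix(Matrix::crossprod(M, Ainv %*% M))
      S <- (S + t(S)) / 2
      G <- riwish(priors$G_nu + np, priors$G_scale + S)
    }

    ## scalar variances
    for (bn in sc_use) {
      xb <- theta[idx_of[[bn]]]
      sig[bn] <- 1 / rgamma(1, priors$ig_shape + length(xb) / 2,
                            priors$ig_rate + sum(xb^2) / 2)
    }
    if (use_resid_block) {
      e <- theta[i_e]
      sig_e <- 1 / rgamma(1, priors$ig_shape + nb / 2,
                          priors$ig_rate + sum(e^2) / 2)
    } else if (is.null(fix_residual)) {
      e <- y - as.numeric(W %*% theta)
      sig_e <- 1 / rgamma(1, priors$ig_shape + nb / 2,
                          priors$ig_rate + sum(e^2) / 2)
    }

    if (verbose && it %% 1000L == 0L)
      message(sprintf("iter %d / %d  var_af=%.3f var_am=%.3f resid=%.3f",
                      it, n_iter, G[1, 1], G[2, 2], sig_e))

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      gv <- if (use_animal) c(G[1, 1], G[2, 2], G[1, 2]) else rep(NA_real_, 3)
      sv <- ifelse(SCALAR_BLOCKS %in% sc_use, sig[SCALAR_BLOCKS], NA_real_)
      draws[kept, ] <- c(theta[i_fix], gv, sv, sig_e)
      if (save_animal_draws) a_draws[kept, ] <- theta[i_a]
    }
  }

  ac <- apply(draws, 2, lag1_autocorr)
  if (any(ac >= 0.05, na.rm = TRUE))
    warning("lag-1 autocorrelation >= 0.05 after thinning for: ",
            paste(names(ac)[which(ac >= 0.05)], collapse = ", "),
            "; consider a longer chain or heavier thinning")
  a_mean <- if (save_animal_draws) {
    am <- colMeans(a_draws)
    matrix(am, np, 2, dimnames = list(design$ped$id, c("a_f", "a_m")))
  } else NULL
  structure(list(draws = draws, a_draws = a_draws, a_mean = a_mean,
                 autocorr = ac, design = design, priors = priors,
                 chain = list(n_iter = n_iter, burn_in = burn_in,
                              thin = thin, seed = chain$seed,
                              n_retained = n_keep),
                 family = family),
            class = "epp_fit")
}

## inverse-Wishart draw via base rWishart; guards against numerically
## non-positive-definite scale by a tiny ridge, never silent NaN
riwish <- function(df, S) {
  Sinv <- tryCatch(chol2inv(chol(S)),
                   error = function(e) chol2inv(chol(S + diag(1e-8, nrow(S)))))
  Sinv <- (Sinv + t(Sinv)) / 2
  Wd <- rWishart(1, df, Sinv)[, , 1]
  out <- chol2inv(chol(Wd))
  (out + t(out)) / 2
}

lag1_autocorr <- function(x) {
  if (anyNA(x)) return(NA_real_)
  if (sd(x) == 0) return(0)
  acf(x, lag.max = 1L, plot = FALSE, demean = TRUE)$acf[2L]
}

#' Thin retained draws further
#'
#' @param fit an \code{epp_fit}.
#' @param by keep every \code{by}-th retained draw.
#' @return the fit with thinned draws (and animal draws, if stored).
#' @export
thin_fit <- function(fit, by = 2L) {
  keep <- seq(1L, nrow(fit$draws), by = by)
  fit$draws <- fit$draws[keep, , drop = FALSE]
  if (!is.null(fit$a_draws)) {
    fit$a_draws <- fit$a_draws[keep, , drop = FALSE]
    fit$a_mean <- matrix(colMeans(fit$a_draws), fit$design$n_ped, 2,
                         dimnames = dimnames(fit$a_mean))
  }
  fit$autocorr <- apply(fit$draws, 2, lag1_autocorr)
  fit$chain$thin <- fit$chain$thin * by
  fit$chain$n_retained <- length(keep)
  fit
}

#' Posterior predictions of breeding values and total genetic values
#'
#' Computes draw-wise total additive genetic values u = a + g q for each
#' pedigree individual and sex-specific liability, and returns posterior
#' means (plus the draw-wise identity inputs for downstream checks).
#'
#' @param fit an \code{epp_fit} with retained animal draws.
#' @param q [compute_q()] result covering the pedigree.
#' @param ids optional subset of individual ids.
#' @return data frame with posterior mean \code{a_f}, \code{a_m},
#'   \code{u_f}, \code{u_m} and \code{q} per individual.
#' @export
predict_genetic_values <- function(fit, q = fit$design$q, ids = NULL) {
  if (is.null(fit$a_draws))
    stop("fit does not retain animal draws; refit with save_animal_draws = TRUE")
  ped_ids <- fit$design$ped$id
  if (is.null(ids)) ids <- ped_ids
  if (any(!ids %in% ped_ids)) stop("unknown individual id(s)")
  if (any(!ids %in% names(q$q))) stop("individual(s) lacking q")
  np <- fit$design$n_ped
  pos <- match(ids, ped_ids)
  qv <- q$q[ids]
  af <- fit$a_draws[, pos, drop = FALSE]
  am <- fit$a_draws[, np + pos, drop = FALSE]
  uf <- af + outer(fit$draws[, "g_f"], qv)
  um <- am + outer(fit$draws[, "g_m"], qv)
  data.frame(id = ids, q = unname(qv),
             a_f = colMeans(af), a_m = colMeans(am),
             u_f = colMeans(uf), u_m = colMeans(um),
             row.names = NULL, stringsAsFactors = FALSE)
}
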