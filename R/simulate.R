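#' Simulation configuration
#'
#' Defines the generative conditions for the synthetic island population:
#' overlapping generations, monogamous social pairing, occasional parentless
#' immigrants, broods of 1-4 offspring, and a brood-level binomial extra-pair
#' paternity phenotype driven by female and male latent liabilities with
#' cross-sex genetic covariance and immigrant group-mean shifts. Defaults
#' emulate a multi-decade island study: ~25 breeding pairs, ~1 immigrant per
#' year, roughly 1,200 broods and 300 phenotyped individuals of each sex over
#' 25 years, with latent-scale truth values matching the fitted-model scale.
#'
#' @param n_years number of breeding seasons.
#' @param n_founder_pairs founder pairs in year one.
#' @param max_pairs carrying capacity in breeding pairs per year.
#' @param immigrants_per_year Poisson mean number of new immigrants per year.
#' @param adult_survival annual adult survival probability.
#' @param mean_broods_per_pair Poisson mean broods per pair-year (truncated
#'   at >= 1, capped at \code{max_broods_per_pair}).
#' @param max_broods_per_pair maximum broods per pair-year.
#' @param brood_size_min,brood_size_max uniform range of offspring per brood.
#' @param intercept latent-scale intercept.
#' @param g_f,g_m immigrant genetic-group effects on female and male latent
#'   liability.
#' @param beta_year,beta_age fixed regressions on year (since first season)
#'   and male age (years).
#' @param var_af,var_am,cov_afam additive genetic (co)variances of the two
#'   sex-specific latent liabilities.
#' @param var_pe_f,var_pe_m,var_pair,var_year,var_residual permanent female,
#'   permanent male, social-pair, year, and brood-level residual variances.
#' @param seed integer RNG seed (mandatory for reproducible datasets; may be
#'   \code{NULL} to use the current RNG state).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_years = 25L,
                       n_founder_pairs = 10L,
                       max_pairs = 25L,
                       immigrants_per_year = 1,
                       adult_survival = 0.5,
                       mean_broods_per_pair = 2,
                       max_broods_per_pair = 3L,
                       brood_size_min = 1L,
                       brood_size_max = 4L,
                       intercept = -0.67,
                       g_f = -1.17,
                       g_m = -1.55,
                       beta_year = 0.05,
                       beta_age = -0.19,
                       var_af = 1.26,
                       var_am = 0.47,
                       cov_afam = -0.37,
                       var_pe_f = 0.1,
                       var_pe_m = 0.1,
                       var_pair = 0.1,
                       var_year = 0.1,
                       var_residual = 3.58,
                       seed = NULL) {
  cfg <- as.list(environment())
  cfg$G <- matrix(c(var_af, cov_afam, cov_afam, var_am), 2, 2,
                  dimnames = list(c("f", "m"), c("f", "m")))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  vars <- c("var_af", "var_am", "var_pe_f", "var_pe_m", "var_pair",
            "var_year", "var_residual")
  for (v in vars)
    if (cfg[[v]] < 0) stop(v, " must be nonnegative")
  if (cfg$cov_afam^2 > cfg$var_af * cfg$var_am + 1e-12)
    stop("G is not positive semidefinite: cov^2 > var_af * var_am")
  if (cfg$brood_size_min < 1L || cfg$brood_size_max < cfg$brood_size_min)
    stop("invalid brood size range")
  if (cfg$immigrants_per_year < 0) stop("immigrants_per_year must be >= 0")
  if (cfg$mean_broods_per_pair <= 0) stop("mean_broods_per_pair must be > 0")
  invisible(cfg)
}

## draw n bivariate normals with covariance scale * G (G possibly singular)
rbvn <- function(n, G, scale = 1) {
  ev <- eigen(G, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  R <- ev$vectors %*% diag(sqrt(lam), 2)
  z <- matrix(rnorm(2 * n), n, 2)
  sqrt(scale) * (z %*% t(R))
}

## sample() without the scalar-vector surprise
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

## Poisson truncated at >= 1 and capped
rtpois <- function(n, lambda, cap) {
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- 0L
    while (k == 0L) k <- rpois(1L, lambda)
    out[i] <- min(k, cap)
  }
  out
}

#' Simulate a full dataset with known truth
#'
#' Runs the coupled island-population engine: each year, surviving adults,
#' newly arrived immigrants, and locally recruited juveniles form monogamous
#' social pairs; each pair produces 1-3 broods of 1-4 offspring; the number
#' of extra-pair offspring per brood is binomial with a logit-scale liability
#' composed of fixed effects, the pair's additive genetic values, permanent
#' individual, pair, year, and brood-residual effects. Extra-pair offspring
#' are assigned a random extra-pair genetic sire, so the realized pedigree is
#' itself a product of the simulated phenotypes. Breeding values follow the
#' infinitesimal model: founders and immigrants draw from N(0, G) (immigrant
#' group-mean shifts are carried entirely by g * q), and offspring draw the
#' parental midpoint plus a Mendelian deviation with covariance
#' 0.5 * G * (1 - (F_dam + F_sire) / 2).
#'
#' @param cfg a [sim_config()].
#' @return object of class \code{sim_dataset}: list with \code{pedigree},
#'   \code{broods} (data frame), and \code{truth} (per-individual \code{a},
#'   \code{u}, \code{q}, inbreeding, effect draws, and the generative
#'   config).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  G <- cfg$G

  nmax <- 2L * cfg$n_founder_pairs +
    ceiling(4 * cfg$immigrants_per_year * cfg$n_years) + 100L +
    cfg$n_years * cfg$max_pairs * cfg$max_broods_per_pair * cfg$brood_size_max
  id <- character(nmax); dam <- integer(nmax); sire <- integer(nmax)
  sex <- character(nmax); cohort <- integer(nmax); immigrant <- logical(nmax)
  a <- matrix(NA_real_, nmax, 2); q <- numeric(nmax); Fcoef <- numeric(nmax)
  pe <- numeric(nmax)
  n <- 0L

  phi_memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { t <- i; i <- j; j <- t }
    key <- paste0(i, "_", j)
    val <- phi_memo[[key]]
    if (!is.null(val)) return(val)
    val <- if (i == j) 0.5 * (1 + 0.5 * phi(dam[i], sire[i]))
           else 0.5 * (phi(dam[i], j) + phi(sire[i], j))
    phi_memo[[key]] <- val
    val
  }

  new_ind <- function(dam_i, sire_i, sx, coh, imm, a_val, q_val) {
    n <<- n + 1L
    id[n] <<- as.character(n)
    dam[n] <<- dam_i; sire[n] <<- sire_i
    sex[n] <<- sx; cohort[n] <<- coh; immigrant[n] <<- imm
    a[n, ] <<- a_val; q[n] <<- q_val
    Fcoef[n] <<- 0.5 * phi(dam_i, sire_i)
    pe[n] <<- rnorm(1, 0, sqrt(if (sx == "F") cfg$var_pe_f else cfg$var_pe_m))
    n
  }

  ## founders (founder genetic group, q = 0)
  fem <- integer(0); mal <- integer(0)
  for (k in seq_len(cfg$n_founder_pairs)) {
    af <- rbvn(2, G)
    fem <- c(fem, new_ind(0L, 0L, "F", 0L, FALSE, af[1, ], 0))
    mal <- c(mal, new_ind(0L, 0L, "M", 0L, FALSE, af[2, ], 0))
  }

  pair_eff <- new.env(hash = TRUE, parent = emptyenv())
  broods <- list()
  year_effects <- rnorm(cfg$n_years, 0, sqrt(cfg$var_year))
  brood_no <- 0L

  for (t in seq_len(cfg$n_years)) {
    if (t > 1L) {
      ## adult survival
      fem <- fem[runif(length(fem)) < cfg$adult_survival]
      mal <- mal[runif(length(mal)) < cfg$adult_survival]
      ## immigrants: parentless, flagged, q = 1, age 1 on arrival
      n_imm <- rpois(1L, cfg$immigrants_per_year)
      if (n_imm > 0L) {
        ai <- rbvn(n_imm, G)
        for (k in seq_len(n_imm)) {
          sx <- if (runif(1) < 0.5) "F" else "M"
          i <- new_ind(0L, 0L, sx, t - 1L, TRUE, ai[k, ], 1)
          if (sx == "F") fem <- c(fem, i) else mal <- c(mal, i)
        }
      }
      ## recruit last year's offspring to fill vacancies
      juv <- which(cohort[seq_len(n)] == t - 1L & !immigrant[seq_len(n)] &
                     dam[seq_len(n)] > 0L)
      juv <- juv[!(juv %in% c(fem, mal))]
      juv <- resample(juv)
      need_f <- cfg$max_pairs - length(fem)
      need_m <- cfg$max_pairs - length(mal)
      jf <- juv[sex[juv] == "F"]; jm <- juv[sex[juv] == "M"]
      if (need_f > 0L && length(jf)) fem <- c(fem, head(jf, need_f))
      if (need_m > 0L && length(jm)) mal <- c(mal, head(jm, need_m))
    }
    np <- min(length(fem), length(mal), cfg$max_pairs)
    if (np == 0L)
      stop("population went extinct in year ", t,
           "; increase n_founder_pairs or adult_survival")
    pf <- resample(fem, np); pm <- resample(mal, np)

    for (p in seq_len(np)) {
      f <- pf[p]; m <- pm[p]
      pkey <- paste0(f, "_", m)
      if (is.null(pair_eff[[pkey]]))
        pair_eff[[pkey]] <- rnorm(1, 0, sqrt(cfg$var_pair))
      nb <- rtpois(1L, cfg$mean_broods_per_pair, cfg$max_broods_per_pair)
      age_m <- t - cohort[m]
      for (b in seq_len(nb)) {
        size <- resample(cfg$brood_size_min:cfg$brood_size_max, 1L)
        eta <- cfg$intercept + cfg$beta_year * (t - 1L) +
          cfg$beta_age * age_m +
          cfg$g_f * q[f] + cfg$g_m * q[m] + a[f, 1] + a[m, 2] +
          pe[f] + pe[m] + pair_eff[[pkey]] + year_effects[t] +
          rnorm(1, 0, sqrt(cfg$var_residual))
        n_epo <- rbinom(1L, size, plogis(eta))
        brood_no <- brood_no + 1L
        ## genetic sires: extra-pair offspring get a random other paired male
        other <- pm[pm != m]
        for (o in seq_len(size)) {
          gsire <- if (o <= n_epo && length(other))
            resample(other, 1L)
          else m
          Fd <- Fcoef[f]; Fs <- Fcoef[gsire]
          seg <- rbvn(1, G, scale = 0.5 * (1 - (Fd + Fs) / 2))
          new_ind(f, gsire, if (runif(1) < 0.5) "F" else "M", t, FALSE,
                  0.5 * (a[f, ] + a[gsire, ]) + seg[1, ],
                  0.5 * (q[f] + q[gsire]))
        }
        broods[[brood_no]] <- data.frame(
          brood_id = paste0("B", brood_no), year = t, female_id = id[f],
          male_id = id[m], male_age = age_m, n_offspring = size,
          n_epo = n_epo, stringsAsFactors = FALSE)
      }
    }
  }

  keep <- seq_len(n)
  ped <- as_pedigree(data.frame(
    id = id[keep],
    dam = ifelse(dam[keep] > 0L, as.character(dam[keep]), NA_character_),
    sire = ifelse(sire[keep] > 0L, as.character(sire[keep]), NA_character_),
    sex = sex[keep], cohort = cohort[keep], immigrant = immigrant[keep],
    stringsAsFactors = FALSE))
  broods <- do.call(rbind, broods)
  amat <- a[keep, , drop = FALSE]
  rownames(amat) <- id[keep]
  colnames(amat) <- c("a_f", "a_m")
  qv <- setNames(q[keep], id[keep])
  u <- amat + cbind(cfg$g_f * qv, cfg$g_m * qv)
  colnames(u) <- c("u_f", "u_m")
  phen <- unique(c(broods$female_id, broods$male_id))
  qp <- qv[phen]
  truth <- list(a = amat, u = u, q = qv,
                inbreeding = setNames(Fcoef[keep], id[keep]),
                pe = setNames(pe[keep], id[keep]),
                year_effects = year_effects,
                phenotyped = phen,
                var_q = mean((qp - mean(qp))^2),
                cfg = cfg)
  structure(list(pedigree = ped, broods = broods, truth = truth),
            class = "sim_dataset")
}

#' Simulate an island pedigree
#'
#' Convenience wrapper returning only the pedigree from the coupled engine in
#' [simulate_dataset()] (the pedigree is not independent of the phenotypes:
#' extra-pair offspring get extra-pair genetic sires).
#'
#' @param cfg a [sim_config()].
#' @return a \code{pedigree}.
#' @export
simulate_pedigree <- function(cfg) simulate_dataset(cfg)$pedigree

#' Simulate breeding values down a fixed pedigree
#'
#' Standalone infinitesimal-model gene dropping of the bivariate breeding
#' values (female liability, male liability) along an arbitrary validated
#' pedigree. Parentless individuals (founders and immigrants) draw from
#' N(0, G); others draw the parental midpoint plus a Mendelian-segregation
#' deviation with covariance 0.5 * G * (1 - (F_dam + F_sire) / 2) (or the
#' one-known-parent analogue). Total additive genetic values are
#' u = a + g * q per sex, with q from the immigrant phantom groups.
#'
#' @param ped pedigree.
#' @param cfg a [sim_config()] supplying G, g_f, g_m (the demographic fields
#'   are ignored).
#' @return list with matrices \code{a}, \code{u}, vector \code{q}, and
#'   \code{inbreeding}.
#' @export
simulate_breeding_values <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  G <- cfg$G
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  Fc <- inbreeding_coefficients(ped)
  a <- matrix(NA_real_, n, 2, dimnames = list(ped$id, c("a_f", "a_m")))
  for (i in seq_len(n)) {
    d <- ped$dam[i]; s <- ped$sire[i]
    if (is.na(d) && is.na(s)) {
      a[i, ] <- rbvn(1, G)
    } else if (is.na(s)) {
      di <- idx[[d]]
      a[i, ] <- 0.5 * a[di, ] + rbvn(1, G, 0.75 - 0.25 * Fc[di])
    } else if (is.na(d)) {
      si <- idx[[s]]
      a[i, ] <- 0.5 * a[si, ] + rbvn(1, G, 0.75 - 0.25 * Fc[si])
    } else {
      di <- idx[[d]]; si <- idx[[s]]
      a[i, ] <- 0.5 * (a[di, ] + a[si, ]) +
        rbvn(1, G, 0.5 * (1 - (Fc[di] + Fc[si]) / 2))
    }
  }
  groups <- assign_genetic_groups(ped)
  qc <- compute_q(ped, groups)
  u <- a + cbind(cfg$g_f * qc$q, cfg$g_m * qc$q)
  colnames(u) <- c("u_f", "u_m")
  list(a = a, u = u, q = qc$q, inbreeding = Fc)
}

#' Simulate brood phenotypes on a fixed pedigree
#'
#' Draws brood-level binomial extra-pair paternity counts given latent truth
#' values, without altering the pedigree (for resampling phenotypes over a
#' fixed relatedness structure). If no brood skeleton is supplied, a simple
#' one is built: each year, up to \code{max_pairs} random male-female pairs
#' among individuals aged >= 1, with brood numbers and sizes drawn as in the
#' full engine.
#'
#' @param ped pedigree.
#' @param truth list with matrices/vectors \code{a} and \code{q} as returned
#'   by [simulate_breeding_values()].
#' @param cfg a [sim_config()].
#' @param skeleton optional data frame (\code{brood_id}, \code{year},
#'   \code{female_id}, \code{male_id}, \code{male_age}, \code{n_offspring});
#'   \code{n_epo} is (re)drawn.
#' @return data frame of brood records.
#' @export
simulate_phenotypes <- function(ped, truth, cfg, skeleton = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(skeleton)) {
    rows <- list(); bn <- 0L
    for (t in seq_len(cfg$n_years)) {
      av <- ped$id[!is.na(ped$cohort) & ped$cohort < t]
      fa <- av[ped$sex[match(av, ped$id)] == "F"]
      ma <- av[ped$sex[match(av, ped$id)] == "M"]
      np <- min(length(fa), length(ma), cfg$max_pairs)
      if (np == 0L) next
      pf <- resample(fa, np); pm <- resample(ma, np)
      for (p in seq_len(np)) {
        nb <- rtpois(1L, cfg$mean_broods_per_pair, cfg$max_broods_per_pair)
        for (b in seq_len(nb)) {
          bn <- bn + 1L
          rows[[bn]] <- data.frame(
            brood_id = paste0("B", bn), year = t, female_id = pf[p],
            male_id = pm[p],
            male_age = t - ped$cohort[match(pm[p], ped$id)],
            n_offspring = resample(cfg$brood_size_min:cfg$brood_size_max, 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    skeleton <- do.call(rbind, rows)
    if (is.null(skeleton)) stop("no eligible breeding pairs in pedigree")
  }
  sk <- skeleton
  fem <- unique(sk$female_id); mal <- unique(sk$male_id)
  pe_f <- setNames(rnorm(length(fem), 0, sqrt(cfg$var_pe_f)), fem)
  pe_m <- setNames(rnorm(length(mal), 0, sqrt(cfg$var_pe_m)), mal)
  pk <- paste(sk$female_id, sk$male_id)
  upk <- unique(pk)
  pair_e <- setNames(rnorm(length(upk), 0, sqrt(cfg$var_pair)), upk)
  yrs <- sort(unique(sk$year))
  yr_e <- setNames(rnorm(length(yrs), 0, sqrt(cfg$var_year)), as.character(yrs))
  baseline <- min(sk$year)
  eta <- cfg$intercept + cfg$beta_year * (sk$year - baseline) +
    cfg$beta_age * sk$male_age +
    cfg$g_f * truth$q[sk$female_id] + cfg$g_m * truth$q[sk$male_id] +
    truth$a[sk$female_id, "a_f"] + truth$a[sk$male_id, "a_m"] +
    pe_f[sk$female_id] + pe_m[sk$male_id] + pair_e[pk] +
    yr_e[as.character(sk$year)] +
    rnorm(nrow(sk), 0, sqrt(cfg$var_residual))
  sk$n_epo <- rbinom(nrow(sk), sk$n_offspring, plogis(unname(eta)))
  rownames(sk) <- NULL
  sk
}
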