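#' Pipeline configuration
#'
#' Bundles every stage setting of the full analysis (validate/prune ->
#' genetic-group coefficients and A-inverse -> MCMC fit -> derived
#' quantities -> scenario back-transformation) in one validated list that is
#' dumped verbatim into every run directory.
#'
#' @param pedigree path to a pedigree CSV, or a \code{pedigree} object.
#' @param broods path to a brood CSV, or a data frame.
#' @param out_dir run directory to create.
#' @param cutoff_year optional immigrant cutoff year (see
#'   [assign_genetic_groups()]).
#' @param chain list of chain settings (\code{n_iter}, \code{burn_in},
#'   \code{thin}).
#' @param priors an [default_priors()] result.
#' @param scenarios data frame of back-transform scenarios (\code{q_value},
#'   \code{year}, \code{male_age}); \code{NULL} for a default contrast of
#'   mean observed q versus q = 0 at the middle year and mean male age.
#' @param seed integer seed governing the whole run.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(pedigree, broods, out_dir,
                            cutoff_year = NULL,
                            chain = list(n_iter = 13000L, burn_in = 3000L,
                                         thin = 5L),
                            priors = default_priors(),
                            scenarios = NULL,
                            seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(pedigree = pedigree, broods = broods, out_dir = out_dir,
                 cutoff_year = cutoff_year, chain = chain, priors = priors,
                 scenarios = scenarios, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Descriptive summary of a dataset
#'
#' Counts of broods, distinct females, males, and social pairings, broods
#' per year, the raw extra-pair paternity rate, per-sex summaries of the
#' immigrant group coefficient, and the mean pairwise kinship among
#' phenotyped individuals.
#'
#' @param ped pedigree.
#' @param broods brood records.
#' @param q optional [compute_q()] result (computed if missing).
#' @return named list of summaries.
#' @export
describe_dataset <- function(ped, broods, q = NULL) {
  broods <- validate_broods(broods)
  phen <- unique(c(broods$female_id, broods$male_id))
  if (is.null(q)) q <- compute_q(ped, assign_genetic_groups(ped), phen)
  per_year <- table(broods$year)
  fem <- unique(broods$female_id)
  mal <- unique(broods$male_id)
  K <- compute_kinship(prune_pedigree(ped, phen))
  Kp <- K[phen, phen]
  off <- Kp[upper.tri(Kp)]
  list(n_broods = nrow(broods),
       n_females = length(fem),
       n_males = length(mal),
       n_pairs = length(unique(paste(broods$female_id, broods$male_id))),
       broods_per_year_mean = mean(per_year),
       broods_per_year_sd = sd(per_year),
       epp_rate = sum(broods$n_epo) / sum(broods$n_offspring),
       q_mean_f = mean(q$q[fem]), q_sd_f = sd(q$q[fem]),
       q_mean_m = mean(q$q[mal]), q_sd_m = sd(q$q[mal]),
       var_q = q$var_q,
       kinship_mean = mean(off), kinship_sd = sd(off))
}

#' Run the full pipeline
#'
#' Executes every stage and writes a self-contained run directory:
#' validated/pruned pedigree, group coefficients and var(q), the A-inverse
#' triplets, posterior draws (CSV), parameter and derived summaries
#' (CSV + JSON), the scenario back-transformation report, the dataset
#' description, and a manifest (config, seed, package version, file
#' checksums). The run is a pure function of (inputs, config, seed).
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with the fitted objects and the run directory.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "load"
  res <- tryCatch({
    ped <- if (inherits(cfg$pedigree, "pedigree")) cfg$pedigree
           else read_pedigree(cfg$pedigree)
    broods <- if (is.data.frame(cfg$broods)) cfg$broods
              else read.csv(cfg$broods, stringsAsFactors = FALSE)
    broods <- validate_broods(broods, ped)

    stage <- "prune"
    phen <- unique(c(broods$female_id, broods$male_id))
    ped <- prune_pedigree(ped, phen)

    stage <- "qcoef"
    groups <- assign_genetic_groups(ped, cfg$cutoff_year)
    q <- compute_q(ped, groups, phen)
    ainv <- compute_A_inverse(ped)

    stage <- "describe"
    descr <- describe_dataset(ped, broods, q)

    stage <- "fit"
    design <- build_design(ped, q, broods)
    chain <- cfg$chain
    chain$seed <- cfg$seed
    fit <- fit_mcmc(design, cfg$priors, chain)

    stage <- "derive"
    derived <- derive_all(fit)

    stage <- "report"
    scen <- cfg$scenarios
    if (is.null(scen)) {
      scen <- data.frame(
        q_value = c(round(mean(q$q[phen]), 2), 0),
        year = rep(round(mean(range(broods$year))), 2),
        male_age = rep(round(mean(broods$male_age), 1), 2))
    }
    rates <- back_transform(fit, scen)
    rate_summ <- summarize_posterior(rates)
    if (ncol(rates) == 2L) {
      dsum <- summarize_posterior(
        matrix(rates[, 1L] - rates[, 2L], ncol = 1L,
               dimnames = list(NULL, "rate_difference")))
      rate_summ <- rbind(rate_summ, dsum)
    }

    stage <- "write"
    out <- cfg$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_pedigree(ped, file.path(out, "pedigree_pruned.csv"))
    write.csv(broods, file.path(out, "broods.csv"), row.names = FALSE)
    qdf <- data.frame(id = names(q$q), q = unname(q$q))
    write.csv(qdf, file.path(out, "qcoef.csv"), row.names = FALSE)
    write_triplets(ainv$Ainv, file.path(out, "a_inverse_triplets.csv"))
    write.csv(as.data.frame(fit$draws), file.path(out, "draws.csv"),
              row.names = FALSE)
    write.csv(summarize_posterior(fit), file.path(out, "summary_model.csv"),
              row.names = FALSE)
    write.csv(summarize_posterior(derived),
              file.path(out, "summary_derived.csv"), row.names = FALSE)
    write.csv(cbind(scen, rate_summ[seq_len(nrow(scen)), -1L]),
              file.path(out, "scenario_rates.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(model = summarize_posterior(fit),
           derived = summarize_posterior(derived),
           scenarios = rate_summ,
           var_q = q$var_q,
           description = descr),
      file.path(out, "summaries.json"), auto_unbox = TRUE, digits = NA)
    writeLines(format_run_report(descr, fit, derived, rate_summ),
               file.path(out, "report.txt"))

    cfg_plain <- cfg
    cfg_plain$priors <- unclass(cfg_plain$priors)
    cfg_plain$pedigree <- if (is.character(cfg$pedigree)) cfg$pedigree
                          else "<in-memory pedigree>"
    cfg_plain$broods <- if (is.character(cfg$broods)) cfg$broods
                        else "<in-memory broods>"
    ## the run directory itself is not part of the run's identity
    cfg_plain$out_dir <- NULL
    yaml::write_yaml(unclass(cfg_plain), file.path(out, "config.yaml"))
    files <- setdiff(list.files(out), "manifest.json")
    manifest <- list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("gganimal")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config_hash = unname(tools::md5sum(file.path(out, "config.yaml"))),
      chain = fit$chain,
      files = as.list(tools::md5sum(file.path(out, sort(files)))))
    names(manifest$files) <- sort(files)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(pedigree = ped, q = q, ainv = ainv, design = design, fit = fit,
         derived = derived, rates = rates, description = descr,
         out_dir = out)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (verbose) message("pipeline complete: ", res$out_dir)
  invisible(res)
}

format_run_report <- function(descr, fit, derived, rate_summ) {
  fmt <- function(df) {
    c(sprintf("%-14s %8s %8s %8s %8s %6s", "parameter", "mean", "mode",
              "hpd_lo", "hpd_hi", "%neg"),
      sprintf("%-14s %8.3f %8.3f %8.3f %8.3f %6.1f", df$parameter, df$mean,
              df$mode, df$hpd_lower, df$hpd_upper, df$pct_negative))
  }
  c("Dataset",
    sprintf("  broods %d | females %d | males %d | pairings %d",
            descr$n_broods, descr$n_females, descr$n_males, descr$n_pairs),
    sprintf("  EPP rate %.3f | mean q (F) %.2f | mean q (M) %.2f | var(q) %.4f",
            descr$epp_rate, descr$q_mean_f, descr$q_mean_m, descr$var_q),
    sprintf("  mean pairwise kinship %.3f (SD %.3f)",
            descr$kinship_mean, descr$kinship_sd),
    "", "Model posterior", fmt(summarize_posterior(fit)),
    "", "Derived posterior", fmt(summarize_posterior(derived)),
    "", "Back-transformed scenario rates", fmt(rate_summ))
}
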