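## small pedigree fixtures built in code

## founder pair + offspring
trio_pedigree <- function() {
  as_pedigree(data.frame(
    id = c("s1", "d1", "o1"),
    dam = c(NA, NA, "d1"),
    sire = c(NA, NA, "s1"),
    sex = c("M", "F", "F"),
    stringsAsFactors = FALSE))
}

## two founders, two full sibs, and their inbred offspring
fullsib_mating_pedigree <- function() {
  as_pedigree(data.frame(
    id = c("s", "d", "b1", "b2", "x"),
    dam = c(NA, NA, "d", "d", "b1"),
    sire = c(NA, NA, "s", "s", "b2"),
    sex = c("M", "F", "F", "M", "F"),
    stringsAsFactors = FALSE))
}

## random valid pedigree: founders then offspring with parents drawn from
## earlier individuals of the right sex
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L),
                            p_immigrant = 0.05) {
  id <- paste0("i", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  sex[1:2] <- c("F", "M")
  dam <- rep(NA_character_, n)
  sire <- rep(NA_character_, n)
  imm <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i <= n_founders) {
      imm[i] <- runif(1) < p_immigrant
      next
    }
    fem <- which(sex[1:(i - 1)] == "F")
    mal <- which(sex[1:(i - 1)] == "M")
    if (length(fem)) dam[i] <- id[fem[sample.int(length(fem), 1L)]]
    if (length(mal)) sire[i] <- id[mal[sample.int(length(mal), 1L)]]
  }
  as_pedigree(data.frame(id = id, dam = dam, sire = sire, sex = sex,
                         cohort = NA, immigrant = imm,
                         stringsAsFactors = FALSE))
}

## brute-force ancestor closure by recursive traversal (independent of
## prune_pedigree's reverse sweep)
ancestor_closure <- function(ped, ids) {
  dam <- setNames(ped$dam, ped$id)
  sire <- setNames(ped$sire, ped$id)
  seen <- character(0)
  visit <- function(i) {
    if (is.na(i) || i %in% seen) return(invisible())
    seen <<- c(seen, i)
    visit(dam[[i]])
    visit(sire[[i]])
  }
  for (i in ids) visit(i)
  sort(seen)
}

## small simulation config for fast tests (defaults overridable)
tiny_config <- function(...) {
  args <- list(n_years = 8L, n_founder_pairs = 6L, max_pairs = 10L)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

## short chain settings for smoke-level fits
short_chain <- function(seed, n_iter = 600L, burn_in = 200L, thin = 2L) {
  list(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)
}

fit_quietly <- function(...) suppressWarnings(fit_mcmc(...))

## simulate + prune + design in one step
prepared_dataset <- function(cfg) {
  sim <- simulate_dataset(cfg)
  phen <- sim$truth$phenotyped
  ped <- prune_pedigree(sim$pedigree, phen)
  q <- compute_q(ped, assign_genetic_groups(ped), phen)
  list(sim = sim, ped = ped, q = q,
       design = build_design(ped, q, sim$broods))
}
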