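#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' \code{id}, \code{dam}, \code{sire} (identifiers; \code{NA} for unknown
#' parents), \code{sex} (\code{"F"}/\code{"M"}, \code{NA} allowed),
#' \code{cohort} (integer hatch year, \code{NA} allowed) and
#' \code{immigrant} (logical). Validation enforces the structural rules an
#' animal model requires: the parent map is acyclic, every named parent has
#' its own record, dams are female and sires male wherever sex is known, and
#' immigrants (individuals that arrived from outside the study population)
#' have both parents unknown.
#'
#' @param x data frame with at least columns \code{id}, \code{dam},
#'   \code{sire}; optional \code{sex}, \code{cohort}, \code{immigrant}.
#' @return a validated \code{pedigree} object (a data frame), topologically
#'   sorted so that parents precede offspring.
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "dam", "sire")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  x$id <- as.character(x$id)
  x$dam <- as.character(x$dam)
  x$sire <- as.character(x$sire)
  if (is.null(x$sex)) x$sex <- NA_character_
  x$sex <- toupper(as.character(x$sex))
  x$sex[!x$sex %in% c("F", "M")] <- NA_character_
  if (is.null(x$cohort)) x$cohort <- NA_integer_
  x$cohort <- as.integer(x$cohort)
  if (is.null(x$immigrant)) x$immigrant <- FALSE
  x$immigrant <- as.logical(x$immigrant)
  x$immigrant[is.na(x$immigrant)] <- FALSE
  x <- x[, c("id", "dam", "sire", "sex", "cohort", "immigrant")]

  if (anyNA(x$id) || any(x$id == ""))
    stop("pedigree contains missing individual ids")
  if (anyDuplicated(x$id))
    stop("duplicated pedigree ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))

  for (col in c("dam", "sire")) {
    bad <- !is.na(x[[col]]) & !x[[col]] %in% x$id
    if (any(bad))
      stop("unknown ", col, " id(s) not present as records: ",
           paste(unique(x[[col]][bad]), collapse = ", "))
  }

  ## sex consistency: dams female, sires male
  sex <- setNames(x$sex, x$id)
  dam_sex <- sex[x$dam[!is.na(x$dam)]]
  if (any(dam_sex == "M", na.rm = TRUE)) {
    bad <- names(dam_sex)[which(dam_sex == "M")]
    stop("individual(s) recorded as dam but sexed male: ",
         paste(unique(bad), collapse = ", "))
  }
  sire_sex <- sex[x$sire[!is.na(x$sire)]]
  if (any(sire_sex == "F", na.rm = TRUE)) {
    bad <- names(sire_sex)[which(sire_sex == "F")]
    stop("individual(s) recorded as sire but sexed female: ",
         paste(unique(bad), collapse = ", "))
  }
  ## infer sex from parental role where unrecorded
  x$sex[x$id %in% x$dam] <- "F"
  x$sex[x$id %in% x$sire] <- "M"

  bad <- x$immigrant & (!is.na(x$dam) | !is.na(x$sire))
  if (any(bad))
    stop("immigrant individual(s) with a named parent: ",
         paste(x$id[bad], collapse = ", "))

  ord <- ped_topological_order(x)
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("pedigree", "data.frame")
  x
}

## Kahn's algorithm; errors on cycles, naming one offending individual.
ped_topological_order <- function(x) {
  n <- nrow(x)
  idx <- setNames(seq_len(n), x$id)
  dam <- idx[x$dam]
  sire <- idx[x$sire]
  indeg <- integer(n)
  indeg[!is.na(dam)] <- indeg[!is.na(dam)] + 1L
  indeg[!is.na(sire)] <- indeg[!is.na(sire)] + 1L
  ## children adjacency: parent -> offspring rows
  kid_of <- c(dam[!is.na(dam)], sire[!is.na(sire)])
  kid_row <- c(which(!is.na(dam)), which(!is.na(sire)))
  adj <- split(kid_row, kid_of)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    kids <- adj[[as.character(v)]]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    cyc <- x$id[indeg > 0L]
    stop("pedigree contains a cycle involving: ",
         paste(head(cyc, 5L), collapse = ", "))
  }
  out
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree file with a configurable column dialect and
#' missing-parent codes, then validates it with [as_pedigree()].
#'
#' @param path path to a CSV (or other delimited) file.
#' @param dialect named list mapping the canonical column names
#'   (\code{id}, \code{dam}, \code{sire}, \code{sex}, \code{cohort},
#'   \code{immigrant}) to the column names used in the file. Only the first
#'   three are required.
#' @param missing_codes character vector of parent codes to treat as unknown
#'   (default: empty string, \code{"NA"}, \code{"0"}).
#' @param sep field separator passed to [utils::read.csv()].
#' @return validated \code{pedigree}.
#' @export
read_pedigree <- function(path,
                          dialect = list(id = "id", dam = "dam", sire = "sire",
                                         sex = "sex", cohort = "cohort",
                                         immigrant = "immigrant"),
                          missing_codes = c("", "NA", "0"),
                          sep = ",") {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = character(0))
  out <- list()
  for (canon in c("id", "dam", "sire", "sex", "cohort", "immigrant")) {
    src <- dialect[[canon]]
    if (!is.null(src) && src %in% names(raw)) {
      out[[canon]] <- raw[[src]]
    } else if (canon %in% c("id", "dam", "sire")) {
      stop("cannot resolve required column '", canon, "' in ", path)
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  for (col in c("dam", "sire"))
    out[[col]][out[[col]] %in% missing_codes] <- NA_character_
  if (!is.null(out$immigrant))
    out$immigrant <- out$immigrant %in% c("TRUE", "T", "1", "yes", "true")
  as_pedigree(out)
}

#' Write a pedigree to CSV
#'
#' @param ped pedigree.
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Retains exactly the phenotyped individuals plus every known ancestor of a
#' phenotyped individual; all other records (e.g. non-breeding offspring that
#' carry no information about the focal individuals) are dropped. Pruning is
#' idempotent.
#'
#' @param ped pedigree.
#' @param phenotyped character vector of ids carrying phenotypes.
#' @return pruned \code{pedigree}.
#' @export
prune_pedigree <- function(ped, phenotyped) {
  phenotyped <- unique(as.character(phenotyped))
  missing <- setdiff(phenotyped, ped$id)
  if (length(missing))
    stop("phenotyped id(s) absent from pedigree: ",
         paste(head(missing, 5L), collapse = ", "))
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  keep <- logical(nrow(ped))
  keep[idx[phenotyped]] <- TRUE
  ## pedigree is topologically sorted: one reverse sweep collects ancestors
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (!is.na(ped$dam[i])) keep[idx[[ped$dam[i]]]] <- TRUE
      if (!is.na(ped$sire[i])) keep[idx[[ped$sire[i]]]] <- TRUE
    }
  }
  out <- ped[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Assign phantom parents to genetic groups
#'
#' Every unknown parent slot in the pedigree is a "phantom parent". Phantom
#' parents of immigrants (optionally restricted to immigrants arriving in or
#' after \code{cutoff_year}) form the immigrant genetic group; all other
#' phantom parents form the founder group. The founder group is the baseline:
#' group coefficients \code{q} measure expected genomic contribution from the
#' immigrant group.
#'
#' @param ped pedigree (normally pruned).
#' @param cutoff_year optional integer; immigrants with \code{cohort >=
#'   cutoff_year} (or unknown cohort) count as recent immigrants. \code{NULL}
#'   (default) counts all flagged immigrants.
#' @return data frame with one row per phantom slot: \code{id} (the
#'   individual whose parent is unknown), \code{slot} (\code{"dam"} or
#'   \code{"sire"}), \code{group} (\code{"founder"} or \code{"immigrant"}).
#' @export
assign_genetic_groups <- function(ped, cutoff_year = NULL) {
  recent <- ped$immigrant
  if (!is.null(cutoff_year))
    recent <- recent & (is.na(ped$cohort) | ped$cohort >= cutoff_year)
  rows <- list()
  for (slot in c("dam", "sire")) {
    open <- is.na(ped[[slot]])
    if (any(open))
      rows[[slot]] <- data.frame(
        id = ped$id[open], slot = slot,
        group = ifelse(recent[open], "immigrant", "founder"),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compute genetic-group coefficients
#'
#' The immigrant-group coefficient \code{q_i} is the expected proportion of
#' individual i's genome descending from the immigrant genetic group. It is
#' computed by the standard halving recursion down the pedigree: each phantom
#' slot contributes 1 if assigned to the immigrant group and 0 otherwise, and
#' every individual's q is the mean of its two parental (or phantom)
#' contributions. The founder-group coefficient is \code{1 - q}, so the two
#' group coefficients sum to one for every individual.
#'
#' @param ped pedigree.
#' @param groups phantom assignment from [assign_genetic_groups()].
#' @param phenotyped ids over which \code{var_q} (the plug-in variance of q
#'   used by the total-genetic-value algebra) is computed; defaults to all
#'   individuals.
#' @return list with \code{q} (named vector), \code{var_q} (scalar, computed
#'   with the population denominator n), \code{mean_q}, and \code{phenotyped}.
#' @export
compute_q <- function(ped, groups, phenotyped = ped$id) {
  phenotyped <- unique(as.character(phenotyped))
  missing <- setdiff(phenotyped, ped$id)
  if (length(missing))
    stop("phenotyped id(s) absent from pedigree: ",
         paste(head(missing, 5L), collapse = ", "))
  key <- paste(groups$id, groups$slot)
  gmap <- setNames(groups$group, key)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  q <- numeric(n)
  for (i in seq_len(n)) {
    contrib <- 0
    for (slot in c("dam", "sire")) {
      p <- ped[[slot]][i]
      if (is.na(p)) {
        g <- gmap[[paste(ped$id[i], slot)]]
        if (is.null(g)) stop("phantom slot without group assignment: ",
                             ped$id[i], " ", slot)
        contrib <- contrib + (g == "immigrant")
      } else {
        contrib <- contrib + q[idx[[p]]]
      }
    }
    q[i] <- contrib / 2
  }
  names(q) <- ped$id
  qp <- q[phenotyped]
  ## population (n-denominator) variance: var_q is a plug-in constant, not an
  ## estimate of a sampling distribution
  var_q <- mean((qp - mean(qp))^2)
  list(q = q, var_q = var_q, mean_q = mean(qp), phenotyped = phenotyped)
}

#' Monte-Carlo gene dropping of group ancestry
#'
#' Independent check on the deterministic q recursion: drops two discrete
#' allele copies (labelled by genetic group of origin) down the pedigree,
#' with each offspring inheriting one uniformly chosen copy from each parent,
#' and estimates q as the mean immigrant-allele dosage across replicates.
#'
#' @param ped pedigree.
#' @param groups phantom assignment from [assign_genetic_groups()].
#' @param n_rep number of gene-dropping replicates.
#' @param chunk replicates per vectorized block (memory control).
#' @return list with \code{q_hat} (named vector of Monte-Carlo means) and
#'   \code{se} (their standard errors).
#' @export
gene_drop_q <- function(ped, groups, n_rep = 10000L, chunk = 10000L) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  key <- paste(groups$id, groups$slot)
  gmap <- setNames(groups$group == "immigrant", key)
  dam <- unname(idx[ped$dam])
  sire <- unname(idx[ped$sire])
  phantom_dam <- vapply(seq_len(n), function(i)
    if (is.na(dam[i])) as.numeric(gmap[[paste(ped$id[i], "dam")]]) else NA_real_,
    numeric(1))
  phantom_sire <- vapply(seq_len(n), function(i)
    if (is.na(sire[i])) as.numeric(gmap[[paste(ped$id[i], "sire")]]) else NA_real_,
    numeric(1))
  sum1 <- numeric(n)
  sum2 <- numeric(n)
  done <- 0L
  while (done < n_rep) {
    m <- min(chunk, n_rep - done)
    A1 <- matrix(0, m, n)  # maternal copy, 1 = immigrant origin
    A2 <- matrix(0, m, n)  # paternal copy
    for (i in seq_len(n)) {
      if (is.na(dam[i])) {
        A1[, i] <- phantom_dam[i]
      } else {
        pick <- runif(m) < 0.5
        A1[, i] <- ifelse(pick, A1[, dam[i]], A2[, dam[i]])
      }
      if (is.na(sire[i])) {
        A2[, i] <- phantom_sire[i]
      } else {
        pick <- runif(m) < 0.5
        A2[, i] <- ifelse(pick, A1[, sire[i]], A2[, sire[i]])
      }
    }
    dose <- (A1 + A2) / 2
    sum1 <- sum1 + colSums(dose)
    sum2 <- sum2 + colSums(dose^2)
    done <- done + m
  }
  q_hat <- sum1 / n_rep
  v <- pmax(sum2 / n_rep - q_hat^2, 0)
  list(q_hat = setNames(q_hat, ped$id),
       se = setNames(sqrt(v / n_rep), ped$id))
}
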