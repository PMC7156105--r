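#' Dense additive relationship matrix (tabular method)
#'
#' Brute-force recursive construction of the numerator relationship matrix A.
#' Quadratic in pedigree size; intended for moderate pedigrees and as the
#' reference object against which the sparse inverse is checked.
#'
#' @param ped pedigree.
#' @return dense symmetric matrix with dimnames = ids, diagonal 1 + F.
#' @export
make_A <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  dam <- unname(idx[ped$dam])
  sire <- unname(idx[ped$sire])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    Fi <- if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
    A[i, i] <- 1 + Fi
  }
  A
}

#' Inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes F for every individual by accumulating the rows of the Cholesky
#' decomposition A = L D L' one individual at a time, so only the ancestors
#' of each individual are visited.
#'
#' @param ped pedigree.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  dam <- unname(idx[ped$dam]); dam[is.na(dam)] <- 0L
  sire <- unname(idx[ped$sire]); sire[is.na(sire)] <- 0L
  F <- numeric(n)
  D <- numeric(n)
  L <- numeric(n)   # workspace: row i of L
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    D[i] <- if (d > 0L && s > 0L) 0.5 - 0.25 * (F[d] + F[s])
            else if (d > 0L) 0.75 - 0.25 * F[d]
            else if (s > 0L) 0.75 - 0.25 * F[s]
            else 1
    L[] <- 0
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] != 0) {
        aii <- aii + L[j]^2 * D[j]
        if (dam[j] > 0L) L[dam[j]] <- L[dam[j]] + 0.5 * L[j]
        if (sire[j] > 0L) L[sire[j]] <- L[sire[j]] + 0.5 * L[j]
      }
    }
    F[i] <- aii - 1
  }
  setNames(F, ped$id)
}

#' Sparse inverse additive relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules with
#' inbreeding accounted for via Meuwissen-Luo coefficients: for individual i
#' with parents s and d, the Mendelian sampling variance is
#' d_i = 0.5 - 0.25 (F_s + F_d) (with the usual adjustments for unknown
#' parents), and 1/d_i is scattered over the (i, s, d) block.
#'
#' @param ped pedigree.
#' @return list with \code{order} (ids in matrix order), \code{Ainv} (sparse
#'   symmetric \code{dsCMatrix}), and \code{inbreeding} (named F vector).
#' @export
compute_A_inverse <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  dam <- unname(idx[ped$dam]); dam[is.na(dam)] <- 0L
  sire <- unname(idx[ped$sire]); sire[is.na(sire)] <- 0L
  F <- inbreeding_coefficients(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  ti <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    Di <- if (d > 0L && s > 0L) 0.5 - 0.25 * (F[d] + F[s])
          else if (d > 0L) 0.75 - 0.25 * F[d]
          else if (s > 0L) 0.75 - 0.25 * F[s]
          else 1
    a <- 1 / Di
    par <- c(d, s)
    par <- par[par > 0L]
    ri <- c(i); rj <- c(i); rx <- c(a)
    for (p in par) {
      ri <- c(ri, i, p); rj <- c(rj, p, i); rx <- c(rx, -a / 2, -a / 2)
    }
    if (length(par)) {
      grid <- expand.grid(p = par, q = par)
      ri <- c(ri, grid$p); rj <- c(rj, grid$q); rx <- c(rx, rep(a / 4, nrow(grid)))
    }
    ti[[i]] <- list(ri, rj, rx)
  }
  ii <- unlist(lapply(ti, `[[`, 1L))
  jj <- unlist(lapply(ti, `[[`, 2L))
  xx <- unlist(lapply(ti, `[[`, 3L))
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
  list(order = ped$id, Ainv = Ainv, inbreeding = F)
}

#' Pairwise kinship coefficients
#'
#' Kinship (coancestry) phi(i, j) is half the additive relationship:
#' phi(i, i) = 0.5 (1 + F_i). Computed from the dense tabular A.
#'
#' @param ped pedigree.
#' @param pairs optional two-column matrix/data frame of id pairs; if
#'   omitted the full kinship matrix is returned.
#' @return full symmetric kinship matrix, or a numeric vector (one entry per
#'   requested pair) when \code{pairs} is given.
#' @export
compute_kinship <- function(ped, pairs = NULL) {
  K <- make_A(ped) / 2
  if (is.null(pairs)) return(K)
  pairs <- as.matrix(pairs)
  K[cbind(as.character(pairs[, 1]), as.character(pairs[, 2]))]
}

#' Export a sparse matrix as coordinate triplets
#'
#' Writes the lower triangle of a symmetric sparse matrix as
#' \code{row,col,value} text (1-based indices in matrix order).
#'
#' @param M sparse symmetric matrix.
#' @param path output file.
#' @export
write_triplets <- function(M, path) {
  T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  keep <- T@i >= T@j
  df <- data.frame(row = T@i[keep] + 1L, col = T@j[keep] + 1L,
                   value = T@x[keep])
  df <- df[order(df$row, df$col), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
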