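# Independent oracles. These deliberately avoid the package's own
# computational paths: dense solve()/determinant() instead of blockwise
# Cholesky, Henderson's mixed-model equations instead of the direct BLUP
# formula, allele dropping instead of the kinship recursion.

# Dense multivariate-normal log-density with explicit inverse and
# log-determinant.
dense_mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(Sigma) %*% r))
}

# Genetic-effect solution of Henderson's mixed-model equations for
# y = X b + Z g + e, var(g) = K sg2, var(e) = I se2, Z = I:
#   [X'X   X'     ] [b]   [X'y]
#   [X     I + lam K^-1] [g] = [y ],  lam = se2/sg2
henderson_blup <- function(y, X, K, sg2, se2) {
  n <- length(y)
  lam <- se2 / sg2
  Kinv <- solve(K)
  p <- ncol(X)
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + lam * Kinv))
  rhs <- c(crossprod(X, y), y)
  sol <- unname(solve(lhs, rhs))
  list(beta = sol[seq_len(p)], g = sol[-seq_len(p)])
}

# Monte-Carlo kinship by gene dropping: two distinct founder alleles per
# founder per locus, transmitted with fair Mendelian draws; K = 2 * phi
# where phi is the probability that one random allele from each individual
# is identical by descent, estimated over n_loci replicate loci.
gene_drop_kinship <- function(ped, n_loci = 1e5) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  fa <- idx[ped$father_id]; mo <- idx[ped$mother_id]
  a1 <- matrix(0L, n, n_loci)   # maternal/paternal allele labels
  a2 <- matrix(0L, n, n_loci)
  next_allele <- 0L
  for (i in seq_len(n)) {       # rows are in topological order
    if (is.na(fa[i])) {
      a1[i, ] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_loci) < 0.5
      a1[i, ] <- ifelse(pick, a1[fa[i], ], a2[fa[i], ])
    }
    if (is.na(mo[i])) {
      a2[i, ] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_loci) < 0.5
      a2[i, ] <- ifelse(pick, a1[mo[i], ], a2[mo[i], ])
    }
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      phi <- (mean(a1[i, ] == a1[j, ]) + mean(a1[i, ] == a2[j, ]) +
                mean(a2[i, ] == a1[j, ]) + mean(a2[i, ] == a2[j, ])) / 4
      if (i == j)  # kinship with self: both alleles from the same genotype
        phi <- (1 + mean(a1[i, ] == a2[i, ])) / 2
      K[i, j] <- 2 * phi
      K[j, i] <- K[i, j]
    }
  }
  K
}
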