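#' Construct a pedigree object
#'
#' A pedigree is a data frame of individuals with parent links, validated
#' for internal consistency: unique ids, resolvable parents, no individual
#' that is its own ancestor. Parents referenced but never listed as rows
#' are added as founders of unknown sex.
#'
#' @param id character or coercible; unique individual identifiers.
#' @param father,mother identifiers of the parents, or `NA`/`"0"` where
#'   unknown. A single known parent is allowed; the missing one is treated
#'   as a unique unrelated founder.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual
#'   (numeric 1/2/0 codes are accepted).
#' @param family family identifier per individual; defaults to a single
#'   family `"F1"`.
#'
#' @return An object of class `pedigree`: a data frame with columns
#'   `family_id`, `id`, `father_id`, `mother_id`, `sex`, ordered so that
#'   parents precede offspring.
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = "unknown",
                     family = "F1") {
  id <- as.character(id)
  n <- length(id)
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  family <- rep_len(as.character(family), n)
  sex <- rep_len(decode_sex(sex), n)
  father[!is.na(father) & father == "0"] <- NA
  mother[!is.na(mother) & mother == "0"] <- NA

  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))

  ped <- data.frame(family_id = family, id = id, father_id = father,
                    mother_id = mother, sex = sex,
                    stringsAsFactors = FALSE)

  # parents referenced but absent become founders of the same family
  for (col in c("father_id", "mother_id")) {
    ref <- setdiff(stats::na.omit(ped[[col]]), ped$id)
    if (length(ref)) {
      fam <- ped$family_id[match(ref, ped[[col]])]
      add <- data.frame(family_id = fam, id = ref, father_id = NA_character_,
                        mother_id = NA_character_,
                        sex = if (col == "father_id") "male" else "female",
                        stringsAsFactors = FALSE)
      ped <- rbind(ped, add)
    }
  }

  ord <- pedigree_toporder(ped)   # errors on cycles
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

decode_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  out[s %in% c("0", "u", "unknown", "na") | is.na(s)] <- "unknown"
  if (anyNA(out))
    stop("unparseable sex code(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

# Kahn's algorithm; errors naming an individual on a parent cycle
# (self-ancestry included).
pedigree_toporder <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle (individual its own ancestor): ",
         paste(ped$id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' Read a pedigree file
#'
#' Reads whitespace- or tab-delimited pedigree files in the LINKAGE
#' pre-makeped or PLINK `.fam` column conventions: family, id, father,
#' mother, sex, with `0` denoting an unknown parent. The PLINK dialect
#' carries a sixth (phenotype) column, which is ignored.
#'
#' @param path path to the pedigree file.
#' @param dialect `"linkage"` or `"plink_fam"`; both share the first five
#'   columns.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, dialect = c("linkage", "plink_fam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  need <- if (dialect == "plink_fam") 6L else 5L
  if (ncol(tab) < 5L)
    stop("expected at least 5 columns (family id father mother sex), got ",
         ncol(tab))
  if (dialect == "plink_fam" && ncol(tab) < need)
    warning("plink_fam file has no phenotype column; proceeding")
  bad <- which(!tolower(tab[[5]]) %in%
                 c("0", "1", "2", "m", "f", "u", "male", "female", "unknown"))
  if (length(bad))
    stop("unparseable sex code on line ", bad[1], ": '", tab[bad[1], 5], "'")
  pedigree(id = tab[[2]], father = tab[[3]], mother = tab[[4]],
           sex = tab[[5]], family = tab[[1]])
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]; writes the five LINKAGE columns with `0`
#' for unknown parents and 1/2/0 sex codes.
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(ped$family_id, ped$id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    sexcode)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Additive genetic relationship (kinship) matrix
#'
#' Computes K = 2*Phi, the additive relationship matrix, by the standard
#' tabular recursion processed in topological order: for individual i with
#' parents f and m, `K[i, j] = (K[f, j] + K[m, j]) / 2` for previously
#' processed j, and `K[i, i] = 1 + K[f, m] / 2`. Unknown parents contribute
#' zero. With this convention a non-inbred individual has diagonal 1 and
#' the diagonal in general is 1 + F (inbreeding coefficient), so that
#' `Sigma = K * sigma_g^2 + I * sigma_e^2` assigns additive variance
#' sigma_g^2 to a non-inbred individual.
#'
#' @param ped a [pedigree].
#' @return A symmetric positive semidefinite numeric matrix with dimnames
#'   equal to the individual ids (the id-to-index map).
#' @export
compute_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  # rows are already in topological order (pedigree() guarantees it)
  for (i in seq_len(n)) {
    f <- fa[i]; m <- mo[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(f)) row <- row + K[f, j]
      if (!is.na(m)) row <- row + K[m, j]
      row <- row / 2
      K[i, j] <- row
      K[j, i] <- row
    }
    K[i, i] <- 1 + if (!is.na(f) && !is.na(m)) K[f, m] / 2 else 0
  }
  K
}

#' Family blocks of a relationship matrix
#'
#' Connected components of the nonzero pattern of `K`. Because the GxE
#' covariance K (Hadamard) Psi + Delta inherits K's zero pattern, the
#' likelihood factorizes over these blocks; all model fitting in this
#' package exploits that.
#'
#' @param K square symmetric matrix.
#' @param tol entries with absolute value at or below `tol` are treated
#'   as structural zeros.
#' @return list of integer index vectors, one per block.
#' @export
relatedness_blocks <- function(K, tol = 0) {
  n <- nrow(K)
  adj <- abs(K) > tol
  seen <- logical(n)
  blocks <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    blocks[[length(blocks) + 1L]] <- sort(comp)
  }
  blocks
}

#' Export / import a kinship matrix as TSV
#'
#' `write_kinship` writes either sparse triplets `(id1, id2, value)` of the
#' nonzero upper triangle (including the diagonal) or a dense matrix with
#' header ids; `read_kinship` reads either format back.
#'
#' @param K kinship matrix with id dimnames.
#' @param path file path.
#' @param format `"triplet"` (default) or `"dense"`.
#' @return `read_kinship` returns the symmetric matrix; ids ordered as
#'   first encountered.
#' @export
write_kinship <- function(K, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(K, path, quote = FALSE, sep = "\t",
                       row.names = TRUE, col.names = NA)
  } else {
    up <- which(upper.tri(K, diag = TRUE) & K != 0, arr.ind = TRUE)
    trip <- data.frame(id1 = rownames(K)[up[, 1]],
                       id2 = colnames(K)[up[, 2]],
                       value = K[up])
    utils::write.table(trip, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_kinship
#' @param ids for the triplet format, the full id set (so that ids with all
#'   zero entries off the recorded triangle are retained); defaults to ids
#'   present in the file.
#' @export
read_kinship <- function(path, format = c("triplet", "dense"), ids = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    K <- as.matrix(tab)
    dimnames(K) <- list(rownames(tab), colnames(tab))
    return(K)
  }
  trip <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "numeric"))
  if (is.null(ids)) ids <- unique(c(trip$id1, trip$id2))
  K <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(trip$id1, ids); j <- match(trip$id2, ids)
  K[cbind(i, j)] <- trip$value
  K[cbind(j, i)] <- trip$value
  K
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- length(unique(x$family_id))
  founders <- sum(is.na(x$father_id) & is.na(x$mother_id))
  cat(sprintf("Pedigree: %d individuals in %d famil%s (%d founders)\n",
              nrow(x), nf, if (nf == 1) "y" else "ies", founders))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
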