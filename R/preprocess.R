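#' Residualize a trait on the standard covariate polynomial
#'
#' Ordinary least-squares residuals of the trait on the design
#' `[1, age, sex, age^2, sex*age, sex*age^2]`. Age is centered at its
#' sample mean before the polynomial terms are formed (reduces
#' collinearity; residuals are unaffected). Aliased columns (e.g. the sex
#' terms in a single-sex sample) are dropped with a warning.
#'
#' @param trait numeric vector.
#' @param age numeric vector of ages in years.
#' @param sex indicator or factor; coded internally as female = 0,
#'   male = 1 (residuals do not depend on the coding).
#' @return numeric vector of residuals, orthogonal to every retained
#'   design column.
#' @export
residualize_trait <- function(trait, age, sex) {
  n <- length(trait)
  stopifnot(length(age) == n, length(sex) == n)
  if (anyNA(trait) || anyNA(age) || anyNA(sex))
    stop("missing values must be removed before residualization")
  sex01 <- encode_sex01(sex)
  agec <- age - mean(age)
  X <- cbind(intercept = 1, age = agec, sex = sex01, age2 = agec^2,
             sex_age = sex01 * agec, sex_age2 = sex01 * agec^2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("rank-deficient covariate design; dropping aliased column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    qrX <- qr(X[, keep, drop = FALSE])
  }
  as.numeric(qr.resid(qrX, trait))
}

encode_sex01 <- function(sex) {
  if (is.numeric(sex) && all(sex %in% c(0, 1))) return(as.numeric(sex))
  s <- decode_sex(sex)
  if (any(s == "unknown"))
    stop("sex must be known for covariate adjustment")
  as.numeric(s == "male")
}

#' Rank-based inverse-normal transform
#'
#' Blom scores: `qnorm((rank - 3/8) / (n + 1/4))` with average ranks for
#' ties. Strictly rank-preserving among distinct values; tied inputs map
#' to identical outputs.
#'
#' @param values numeric vector, length >= 2, finite.
#' @return numeric vector of normal scores.
#' @export
inverse_normal <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L) stop("degenerate trait: all values identical")
  n <- length(values)
  stats::qnorm((rank(values, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Read a per-individual trait/covariate/environment table
#'
#' TSV with a header row; ids are read as character so they match the
#' pedigree's opaque identifiers.
#'
#' @param path file path.
#' @param na missing-value token (default `"NA"`).
#' @param id_col name of the id column (default `"id"`).
#' @return data frame with `id` as character.
#' @export
read_trait_table <- function(path, na = "NA", id_col = "id") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = na, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!id_col %in% names(tab)) stop("no '", id_col, "' column in ", path)
  tab[[id_col]] <- as.character(tab[[id_col]])
  names(tab)[names(tab) == id_col] <- "id"
  tab
}

#' Prepare an analysis-ready phenotype
#'
#' Drops rows with missing trait, age or sex, residualizes the trait on
#' the age/sex covariate polynomial, and applies the inverse-normal
#' transform. This is the standard pre-model pipeline: the mixed models
#' downstream then use an intercept-only fixed-effect design.
#'
#' @param table data frame with columns `id`, the trait, `age`, `sex`
#'   (see `age_col`, `sex_col` to remap).
#' @param trait name of the trait column.
#' @param age_col,sex_col covariate column names.
#' @param min_n minimum number of complete rows (default 30).
#' @return list with `y` (transformed phenotype), `ids` (aligned ids) and
#'   `n_dropped`.
#' @export
prepare_phenotype <- function(table, trait, age_col = "age",
                              sex_col = "sex", min_n = 30) {
  for (col in c("id", trait, age_col, sex_col))
    if (!col %in% names(table)) stop("missing column: ", col)
  ok <- stats::complete.cases(table[, c(trait, age_col, sex_col)])
  n_dropped <- sum(!ok)
  if (n_dropped) message(n_dropped, " row(s) dropped for missing ",
                         trait, "/", age_col, "/", sex_col)
  tab <- table[ok, , drop = FALSE]
  if (nrow(tab) < min_n)
    stop("insufficient sample: ", nrow(tab), " complete rows (< ", min_n, ")")
  r <- residualize_trait(tab[[trait]], tab[[age_col]], tab[[sex_col]])
  list(y = inverse_normal(r), ids = tab$id, n_dropped = n_dropped)
}
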