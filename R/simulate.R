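# Synthetic extended-family data: pedigrees, heritable environment
# indices, and phenotypes drawn from the exact GxE covariance model.
# All generators are pure functions of (config, seed): the caller's RNG
# state is saved and restored around every seeded draw.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles the study conditions emulated by the synthetic-data module:
#' 42 extended families of roughly 28-30 members across three
#' generations. Each family descends from a few founder couples whose
#' children intermarry across sibships (connecting the branches) or marry
#' unrelated founder spouses; couples have about three offspring each.
#' The environment is an education-like
#' heritable environment index (mean 10.16, SD 3.92, h^2 0.41), phenotypes
#' drawn from the GxE covariance model, and a modest age/sex covariate
#' polynomial so that preprocessing is exercised end-to-end.
#'
#' @param n_families number of independent extended families.
#' @param founder_couples founder couples per family.
#' @param mean_offspring mean offspring per couple (truncated Poisson).
#' @param max_offspring upper truncation of the offspring distribution.
#' @param marry_prob probability a second-generation offspring marries
#'   and reproduces (either a second-generation member of another sibship
#'   in the family, or an unrelated founder spouse).
#' @param h2_env heritability of the environment index.
#' @param env_mean,env_sd mean and SD of the environment index.
#' @param params true [gxe_parameters()] of the phenotype model.
#' @param beta length-6 coefficient vector for the covariate design
#'   `[1, age_c, sex, age_c^2, sex*age_c, sex*age_c^2]` (age centered).
#' @param age_range uniform age range in years.
#' @param seed integer seed (mandatory for reproducibility).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 42, founder_couples = 3,
                       mean_offspring = 3, max_offspring = 8,
                       marry_prob = 0.55, h2_env = 0.41,
                       env_mean = 10.16, env_sd = 3.92,
                       params = gxe_parameters(alpha_g = 0, gamma_g = 0.3,
                                               lambda_g = 0.05,
                                               alpha_e = 0, gamma_e = -0.2),
                       beta = c(0, 0.01, 0.2, 1e-4, 0.005, 5e-5),
                       age_range = c(16, 80), seed = 1) {
  stopifnot(h2_env >= 0, h2_env <= 1, env_sd > 0, length(beta) == 6,
            is.numeric(seed), length(seed) == 1)
  structure(list(n_families = n_families, founder_couples = founder_couples,
                 mean_offspring = mean_offspring,
                 max_offspring = max_offspring, marry_prob = marry_prob,
                 h2_env = h2_env, env_mean = env_mean, env_sd = env_sd,
                 params = params, beta = beta, age_range = age_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic extended pedigree
#'
#' Three-generation families. Each of `founder_couples` couples produces
#' a sibship with truncated-Poisson offspring counts. Second-generation
#' offspring marry with probability `marry_prob`: eligible men of one
#' sibship are paired with eligible women of the next (ring order), which
#' connects the founder branches through their grandchildren, and any
#' remaining eligible offspring marry unrelated founder spouses. Every
#' married couple produces a third-generation sibship from the same
#' offspring distribution. Families are mutually unrelated, so the
#' kinship matrix is block-diagonal by family; no marriages are between
#' blood relatives, so the pedigree is non-inbred.
#'
#' @inheritParams sim_config
#' @param seed integer seed; the same seed always yields the identical
#'   pedigree.
#' @return a [pedigree].
#' @export
generate_pedigree <- function(n_families = 42, founder_couples = 3,
                              mean_offspring = 3, max_offspring = 8,
                              marry_prob = 0.55, seed = NULL) {
  if (mean_offspring <= 0 || max_offspring < 1)
    stop("degenerate configuration: offspring counts are all zero")
  with_seed(seed, {
    rows <- vector("list", n_families)
    for (f in seq_len(n_families)) {
      fam <- sprintf("F%02d", f)
      cnt <- 0L
      id <- character(0); fa <- character(0); mo <- character(0)
      sx <- character(0)
      add <- function(sex, father = NA, mother = NA) {
        cnt <<- cnt + 1L
        i <- sprintf("%s_%03d", fam, cnt)
        id <<- c(id, i); fa <<- c(fa, father); mo <<- c(mo, mother)
        sx <<- c(sx, sex)
        i
      }
      noff <- function() min(stats::rpois(1, mean_offspring), max_offspring)
      sibs <- vector("list", founder_couples)   # G2 per founder couple
      for (cp in seq_len(founder_couples)) {
        dad <- add("male"); mum <- add("female")
        kids <- character(0)
        for (k in seq_len(noff()))
          kids <- c(kids, add(sample(c("male", "female"), 1), dad, mum))
        sibs[[cp]] <- kids
      }
      eligible <- lapply(sibs, function(kids)
        kids[stats::runif(length(kids)) < marry_prob])
      couples <- list()   # (father, mother) pairs
      if (founder_couples > 1) {
        for (cp in seq_len(founder_couples)) {
          nxt <- cp %% founder_couples + 1L
          men <- eligible[[cp]][sx[match(eligible[[cp]], id)] == "male"]
          women <- eligible[[nxt]][sx[match(eligible[[nxt]], id)] == "female"]
          for (k in seq_len(min(length(men), length(women)))) {
            couples[[length(couples) + 1L]] <- c(men[k], women[k])
            eligible[[cp]] <- setdiff(eligible[[cp]], men[k])
            eligible[[nxt]] <- setdiff(eligible[[nxt]], women[k])
          }
        }
      }
      for (single in unlist(eligible)) {   # marry in founder spouses
        male <- sx[match(single, id)] == "male"
        spouse <- add(if (male) "female" else "male")
        couples[[length(couples) + 1L]] <-
          if (male) c(single, spouse) else c(spouse, single)
      }
      for (cpl in couples)
        for (j in seq_len(noff()))
          add(sample(c("male", "female"), 1), cpl[1], cpl[2])
      rows[[f]] <- data.frame(family = fam, id = id, father = fa,
                              mother = mo, sex = sx,
                              stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, rows)
    pedigree(id = all$id, father = all$father, mother = all$mother,
             sex = all$sex, family = all$family)
  })
}

# z ~ MVN(0, Sigma) drawn block by block via Cholesky
rmvn_blocks <- function(Sig, blocks, n) {
  z <- numeric(n)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    z[b] <- as.numeric(t(chol(Sig[[k]])) %*% stats::rnorm(length(b)))
  }
  z
}

#' Simulate a heritable environment index
#'
#' `q = mean + g + e`, `g ~ MVN(0, K h2 sd^2)`,
#' `e ~ N(0, (1 - h2) sd^2)` iid — an education-years-like index with
#' familial aggregation, motivating the BLUP genetic correction.
#'
#' @param ped a [pedigree].
#' @param K its kinship matrix.
#' @param h2_env heritability of the index in `[0, 1]`.
#' @param mean,sd population mean and SD of the index.
#' @param seed integer seed.
#' @param blocks optional family blocks of `K`.
#' @return numeric vector named by individual id.
#' @export
simulate_environment <- function(ped, K, h2_env = 0.41, mean = 10.16,
                                 sd = 3.92, seed = NULL, blocks = NULL) {
  stopifnot(h2_env >= 0, h2_env <= 1)
  n <- nrow(K)
  blocks <- resolve_blocks(K, blocks)
  with_seed(seed, {
    g <- if (h2_env > 0) {
      Sig <- lapply(blocks, function(b)
        K[b, b, drop = FALSE] * h2_env * sd^2)
      rmvn_blocks(Sig, blocks, n)
    } else numeric(n)
    q <- mean + g + stats::rnorm(n, 0, sqrt((1 - h2_env) * sd^2))
    names(q) <- rownames(K)
    q
  })
}

#' Simulate a phenotype from the GxE covariance model
#'
#' `y = X beta + z`, `z ~ MVN(0, K (Hadamard) Psi + Delta)` at the true
#' parameters, with age drawn uniformly, sex Bernoulli(1/2), and the
#' standard covariate polynomial attached so the preprocessing path can
#' be exercised end-to-end. Sampling is by Cholesky of the exact model
#' covariance, so estimators are tested against their own data-generating
#' process.
#'
#' @param ped a [pedigree].
#' @param K its kinship matrix.
#' @param q environment index aligned with `ped` (raw, i.e. before any
#'   BLUP correction).
#' @param params true [gxe_parameters()].
#' @param beta length-6 covariate coefficients (see [sim_config()]);
#'   zeros give a pure random-effects phenotype.
#' @param age_range uniform age range.
#' @param seed integer seed.
#' @param blocks optional family blocks of `K`.
#' @param trait_name,env_name column names in the returned table.
#' @return data frame (trait table) with columns `id`, `family_id`,
#'   `age`, `sex`, the environment and the trait; attribute `"X"` carries
#'   the covariate design used.
#' @export
simulate_phenotype <- function(ped, K, q, params,
                               beta = c(0, 0.01, 0.2, 1e-4, 0.005, 5e-5),
                               age_range = c(16, 80), seed = NULL,
                               blocks = NULL, trait_name = "trait",
                               env_name = "env") {
  n <- nrow(K)
  stopifnot(length(q) == n, length(beta) == 6)
  blocks <- resolve_blocks(K, blocks)
  env <- environment_index(as.numeric(q))
  with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    sex01 <- stats::rbinom(n, 1, 0.5)
    agec <- age - base::mean(age)
    X <- cbind(1, agec, sex01, agec^2, sex01 * agec, sex01 * agec^2)
    Sig <- lapply(blocks, function(b) {
      S <- K[b, b, drop = FALSE] * psi_matrix(params, env$q[b], env$q_bar)
      diag(S) <- diag(S) +
        residual_variance_at(params$alpha_e, params$gamma_e, env$q[b],
                             env$q_bar)
      S
    })
    y <- as.numeric(X %*% beta) + rmvn_blocks(Sig, blocks, n)
    tab <- data.frame(id = ped$id, family_id = ped$family_id, age = age,
                      sex = ifelse(sex01 == 1, "male", "female"),
                      stringsAsFactors = FALSE)
    tab[[env_name]] <- as.numeric(q)
    tab[[trait_name]] <- y
    attr(tab, "X") <- X
    tab
  })
}

#' Write a trait table as TSV
#'
#' The same format [read_trait_table()] consumes.
#'
#' @param tab data frame with an `id` column.
#' @param path output path.
#' @export
write_trait_table <- function(tab, path) {
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Simulate a complete study data set
#'
#' Convenience wrapper: pedigree, kinship, heritable environment and a
#' phenotype from one [sim_config()]. Sub-seeds for the three stages are
#' derived deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `ped`, `K`, `blocks`, `q`, `table`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$seed
  ped <- generate_pedigree(config$n_families, config$founder_couples,
                           config$mean_offspring, config$max_offspring,
                           config$marry_prob, seed = s)
  K <- compute_kinship(ped)
  blocks <- relatedness_blocks(K)
  q <- simulate_environment(ped, K, config$h2_env, config$env_mean,
                            config$env_sd, seed = s + 1L, blocks = blocks)
  tab <- simulate_phenotype(ped, K, q, config$params, config$beta,
                            config$age_range, seed = s + 2L,
                            blocks = blocks)
  list(ped = ped, K = K, blocks = blocks, q = q, table = tab)
}
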