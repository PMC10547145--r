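# Small pedigrees and simulation shortcuts used across test files.

# founder couple with one child
ped_trio <- function() {
  pedigree(id = c("dad", "mum", "kid"), father = c(NA, NA, "dad"),
           mother = c(NA, NA, "mum"), sex = c("male", "female", "male"))
}

# founder couple with two children (full siblings)
ped_sibs <- function() {
  pedigree(id = c("p1", "p2", "s1", "s2"), father = c(NA, NA, "p1", "p1"),
           mother = c(NA, NA, "p2", "p2"),
           sex = c("male", "female", "male", "female"))
}

# 20-member three-generation pedigree with one inbred loop:
# offspring 7 and 10 are first cousins (via sibs 3 and 4) and marry;
# their children 12-14 are inbred with F = 1/16.
ped_inbred20 <- function() {
  id <- as.character(1:20)
  father <- c(NA, NA, "1", "1", "1", NA, "3", "3", NA, "4", "4", "7", "7",
              "7", NA, "5", "5", NA, "8", "8")
  mother <- c(NA, NA, "2", "2", "2", NA, "6", "6", NA, "9", "9", "10",
              "10", "10", NA, "15", "15", NA, "18", "18")
  sex <- c("male", "female", "male", "male", "male", "female", "male",
           "male", "female", "female", "male", "male", "female", "male",
           "female", "male", "female", "female", "male", "female")
  pedigree(id = id, father = father, mother = mother, sex = sex)
}

# a random small pedigree with at most `n_max` members (deterministic in
# seed; advances through seeds until the size constraint is met)
random_small_pedigree <- function(seed, n_max = 20) {
  repeat {
    ped <- generate_pedigree(n_families = 1, founder_couples = 1,
                             mean_offspring = 2, max_offspring = 5,
                             marry_prob = 0.5, seed = seed)
    if (nrow(ped) <= n_max && nrow(ped) >= 3) return(ped)
    seed <- seed + 1000L
  }
}

# simulate a compact study: pedigree + kinship + environment + phenotype
sim_small <- function(n_families = 14, seed = 1,
                      params = gxe_parameters(), h2_env = 0.41,
                      beta = c(0, 0.01, 0.2, 1e-4, 0.005, 5e-5)) {
  ped <- generate_pedigree(n_families = n_families, seed = seed)
  K <- compute_kinship(ped)
  blocks <- relatedness_blocks(K)
  q <- simulate_environment(ped, K, h2_env = h2_env, seed = seed + 1L,
                            blocks = blocks)
  tab <- simulate_phenotype(ped, K, q, params, beta = beta,
                            seed = seed + 2L, blocks = blocks)
  list(ped = ped, K = K, blocks = blocks, q = q, tab = tab,
       X = attr(tab, "X"), y = tab$trait)
}

# write a pedigree data frame to a temporary LINKAGE file and return path
write_tmp_ped <- function(lines) {
  path <- tempfile(fileext = ".ped")
  writeLines(lines, path)
  path
}
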