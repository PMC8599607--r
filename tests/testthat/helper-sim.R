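# small designs and shared fixtures used across test files

# a compact two-tissue species for fast unit tests
tiny_design <- function(name = "macaque", n_blood = 40L, n_skin = 20L,
                        max_lifespan = 42, maturity_age = 4) {
  species_design(
    name, max_lifespan, maturity_age,
    data.frame(tissue = c("blood", "skin"), n = c(n_blood, n_skin),
               min_age = c(2, 5), max_age = c(40, 40))
  )
}

tiny_config <- function(seed = 1L, n_cpgs = 300L, ...) {
  sim_config(species = list(tiny_design()), n_cpgs = n_cpgs,
             n_causal_per_tissue = 40L, shared_set_size = 10L,
             shared_min_tissues = 2L, seed = seed, ...)
}

# six equally sized tissues: a design with nominal per-tissue power at the
# p < 1e-4 selection threshold (the weakest planted effect is detected with
# probability ~0.999 at n = 100), used for overlap-recovery tests
six_tissue_config <- function(seed = 1L, n_per_tissue = 100L) {
  tissues <- data.frame(
    tissue = c("adipose", "blood", "cortex", "kidney", "liver", "skin"),
    n = n_per_tissue, min_age = 2, max_age = 40
  )
  sim_config(species = list(species_design("macaque", 42, 4, tissues)),
             seed = seed)
}

# dual-species (macaque + human) config at desk scale
dual_config <- function(seed = 1L, ...) {
  sim_config(species = list(macaque_design(), human_design()), seed = seed,
             ...)
}

# the default macaque study design, cached per seed within a test run
default_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_dataset(sim_config(seed = seed))
    }
    cache[[key]]
  }
})

# independent brute-force oracle: upper-tail hypergeometric p by complete
# enumeration of all size-n draws from the N-element universe
enum_hyper_p <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  in_K <- draws <= K # elements 1..K carry the motif
  mean(colSums(in_K) >= k)
}
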