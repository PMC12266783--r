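# Shared fixtures: small study configurations used across test files.

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_genes = 60L,
                   probes_per_gene = c(promoter = 2L, exon = 1L, intron = 1L),
                   n_animals = c(YV = 0L, OV = 6L, OS = 0L),
                   n_control_probes = 30L,
                   clock = list(n_clock_cpgs = 0L))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

random_beta_matrix <- function(np = 20L, ns = 6L, seed = 1L) {
  set.seed(seed)
  m <- matrix(runif(np * ns), np, ns,
              dimnames = list(sprintf("cg%03d", seq_len(np)),
                              sprintf("s%02d", seq_len(ns))))
  m
}

two_group_sheet <- function(n_per_group = 5L) {
  an <- sprintf("A%02d", seq_len(n_per_group))
  data.frame(
    sample_id = as.vector(t(outer(an, c("PBS", "BaCl2"), paste, sep = "_"))),
    animal_id = rep(an, each = 2L),
    age_group = "old", treatment = "vehicle",
    limb = rep(c("PBS", "BaCl2"), n_per_group),
    batch = "chip01", stringsAsFactors = FALSE)
}
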