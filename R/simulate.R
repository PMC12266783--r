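#' Configuration for a synthetic regeneration study
#'
#' Defines the generative model of a paired contralateral-limb methylation
#' array study: three arms (YV young/vehicle, OV old/vehicle, OS
#' old/senolytic), each animal contributing a PBS (control) and a BaCl2
#' (injured/regenerated) limb; a fraction of promoter CpGs responds to
#' injury with a mean beta-scale shift (negative = hypomethylation); one
#' latent unwanted-variation factor and a per-chip batch shift act on the
#' logit scale; clock CpGs track age linearly on the beta scale, with the
#' age signal of old injured limbs pulled toward the young mean by `rho`
#' (regeneration-driven rejuvenation); RNA-seq counts are negative binomial
#' with promoter-methylation-coupled means for a subset of genes.
#'
#' @param seed integer RNG seed; identical seed gives byte-identical output.
#' @param n_genes number of genes.
#' @param probes_per_gene named integer vector of probes per gene by feature
#'   class (promoter, exon, intron, five_prime_utr, three_prime_utr,
#'   intergenic_downstream).
#' @param n_intergenic extra intergenic probes unassigned to genes.
#' @param n_animals named vector: animals per arm, `c(YV=, OV=, OS=)`.
#' @param effect_fraction fraction of promoter CpGs injury-responsive.
#' @param delta_beta mean beta shift of responsive CpGs in BaCl2 limbs
#'   (negative = hypomethylation); applied on the logit scale so betas stay
#'   in (0,1).
#' @param senolytic_extra_delta additional beta shift in the OS arm.
#' @param batch_sd,ruv_sd,noise_sd,animal_sd logit-scale SDs of the batch
#'   shift, the latent-factor loadings, residual noise, and the shared
#'   per-animal intercept inducing the paired-limb correlation.
#' @param n_control_probes negative-control probes (nonzero latent loadings,
#'   no injury effect) recorded for unwanted-variation estimation.
#' @param promoter_window promoter annotation half-width, bp.
#' @param coupling_gamma log2-expression change per unit *decrease* in
#'   promoter beta for coupled genes (positive = promoter methylation
#'   represses expression, so injury hypomethylation upregulates).
#' @param coupled_fraction fraction of genes owning responsive promoter CpGs
#'   whose expression is coupled.
#' @param de_only_fraction fraction of genes given an expression-only
#'   (methylation-independent) injury response, signs split evenly.
#' @param de_only_lfc absolute log2 fold change of expression-only genes.
#' @param nb_dispersion negative-binomial dispersion alpha
#'   (variance mu + alpha mu^2); 0 gives Poisson counts.
#' @param lib_size_range range of library sizes, uniform.
#' @param clock list: n_clock_cpgs, slope_per_week (beta units/week),
#'   young_age_weeks, old_age_weeks, regen_rejuvenation_rho in \[0,1\].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              probes_per_gene = c(promoter = 2L, exon = 2L,
                                                  intron = 2L,
                                                  five_prime_utr = 1L,
                                                  three_prime_utr = 1L),
                              n_intergenic = 0L,
                              n_animals = c(YV = 6L, OV = 11L, OS = 9L),
                              effect_fraction = 0.10,
                              delta_beta = -0.20,
                              senolytic_extra_delta = -0.05,
                              batch_sd = 0.20,
                              ruv_sd = 0.30,
                              noise_sd = 0.15,
                              animal_sd = 0.20,
                              n_control_probes = 200L,
                              promoter_window = 1000L,
                              coupling_gamma = 5,
                              coupled_fraction = 0.5,
                              de_only_fraction = 0.05,
                              de_only_lfc = 1.5,
                              nb_dispersion = 0.05,
                              lib_size_range = c(5e5, 1.5e6),
                              clock = list()) {
  clock_defaults <- list(n_clock_cpgs = 20L, slope_per_week = 0.002,
                         young_age_weeks = 22, old_age_weeks = 104,
                         regen_rejuvenation_rho = 0.5)
  clock <- utils::modifyList(clock_defaults, as.list(clock))
  # accept named lists (e.g. from YAML configs) as well as named vectors
  na <- unlist(n_animals)
  if (is.null(names(na)) || !all(names(na) %in% c("YV", "OV", "OS")))
    stop("n_animals must be named with arms YV/OV/OS")
  n_animals <- c(YV = 0L, OV = 0L, OS = 0L)
  n_animals[names(na)] <- as.integer(na)
  probes_per_gene <- unlist(probes_per_gene)
  if (is.null(names(probes_per_gene)) ||
      !all(names(probes_per_gene) %in% setdiff(FEATURE_CLASSES, "intergenic")))
    stop("probes_per_gene must be named by feature class")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              probes_per_gene = probes_per_gene,
              n_intergenic = as.integer(n_intergenic),
              n_animals = n_animals,
              effect_fraction = effect_fraction, delta_beta = delta_beta,
              senolytic_extra_delta = senolytic_extra_delta,
              batch_sd = batch_sd, ruv_sd = ruv_sd, noise_sd = noise_sd,
              animal_sd = animal_sd,
              n_control_probes = as.integer(n_control_probes),
              promoter_window = as.integer(promoter_window),
              coupling_gamma = coupling_gamma,
              coupled_fraction = coupled_fraction,
              de_only_fraction = de_only_fraction, de_only_lfc = de_only_lfc,
              nb_dispersion = nb_dispersion,
              lib_size_range = lib_size_range, clock = clock)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  fr <- c(effect_fraction = cfg$effect_fraction,
          coupled_fraction = cfg$coupled_fraction,
          de_only_fraction = cfg$de_only_fraction,
          rho = cfg$clock$regen_rejuvenation_rho)
  bad <- fr < 0 | fr > 1
  if (any(bad)) stop("fractions must lie in [0,1]: ",
                     paste(names(fr)[bad], collapse = ", "))
  sds <- c(cfg$batch_sd, cfg$ruv_sd, cfg$noise_sd, cfg$animal_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  invisible(cfg)
}

clamp01 <- function(x, eps = 0.02) pmin(pmax(x, eps), 1 - eps)

arm_of <- function(sheet) {
  ifelse(sheet$age_group == "young", "YV",
         ifelse(sheet$treatment == "senolytic", "OS", "OV"))
}

#' Simulate a full synthetic study
#'
#' Draws the probe manifest, gene models, beta matrix, RNA-seq counts,
#' sample sheet, the generative clock, and a ground-truth record, under the
#' model documented in [simulation_config()]. Identical config (including
#' seed) yields identical output.
#'
#' @param config a [simulation_config()].
#' @return list of class `methregen_study` with elements manifest, genes,
#'   beta, counts, sheet, clock, truth, config.
#' @export
simulate_study <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  cl <- config$clock

  ## ---- sample sheet -------------------------------------------------------
  arms <- c("YV", "OV", "OS")
  n_an <- config$n_animals[arms]
  n_an[is.na(n_an)] <- 0L
  animal_id <- unlist(lapply(arms, function(a) {
    if (n_an[[a]] == 0L) character() else sprintf("%s%02d", a, seq_len(n_an[[a]]))
  }), use.names = FALSE)
  if (length(animal_id) == 0L) stop("no animals configured")
  sheet <- data.frame(
    sample_id = as.vector(t(outer(animal_id, c("PBS", "BaCl2"), paste,
                                  sep = "_"))),
    animal_id = rep(animal_id, each = 2L),
    age_group = rep(ifelse(grepl("^YV", animal_id), "young", "old"), each = 2L),
    treatment = rep(ifelse(grepl("^OS", animal_id), "senolytic", "vehicle"),
                    each = 2L),
    limb = rep(c("PBS", "BaCl2"), times = length(animal_id)),
    batch = rep(sprintf("chip%02d", ceiling(seq_along(animal_id) / 4)),
                each = 2L),
    stringsAsFactors = FALSE)
  n_s <- nrow(sheet)

  ## ---- gene models --------------------------------------------------------
  ng <- config$n_genes
  chrom <- sprintf("chr%d", ((seq_len(ng) - 1L) %% 19L) + 1L)
  idx_on_chrom <- stats::ave(seq_len(ng), chrom, FUN = seq_along)
  gstart <- idx_on_chrom * 1000000L + 50001L
  glen <- sample(10000:100000, ng, replace = TRUE)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(ng)),
    symbol = sprintf("Gene%04d", seq_len(ng)),
    chrom = chrom, strand = strand,
    start = gstart, end = gstart + glen,
    tss = ifelse(strand == "+", gstart, gstart + glen),
    stringsAsFactors = FALSE)

  ## ---- probe manifest -----------------------------------------------------
  ppg <- config$probes_per_gene
  rows <- list()
  sgn <- ifelse(genes$strand == "+", 1L, -1L)
  for (fc in names(ppg)) {
    k <- ppg[[fc]]
    if (k == 0L) next
    gi <- rep(seq_len(ng), each = k)
    d <- switch(fc,
      promoter = sample(seq(-config$promoter_window, config$promoter_window),
                        ng * k, replace = TRUE),
      five_prime_utr = sample(0:500, ng * k, replace = TRUE),
      exon = , intron = {
        lo <- 501L
        lo + floor(stats::runif(ng * k) * (glen[gi] - lo))
      },
      three_prime_utr = glen[gi] - sample(0:500, ng * k, replace = TRUE),
      intergenic_downstream = glen[gi] + sample(1:5000, ng * k, replace = TRUE))
    rows[[fc]] <- data.frame(
      chrom = genes$chrom[gi],
      pos = pmax(1L, as.integer(genes$tss[gi] + d * sgn[gi])),
      gene_id = genes$gene_id[gi], feature_class = fc,
      tss_distance = as.integer(d), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (config$n_intergenic > 0L) {
    manifest <- rbind(manifest, data.frame(
      chrom = sample(sprintf("chr%d", 1:19), config$n_intergenic,
                     replace = TRUE),
      pos = sample.int(3000000L, config$n_intergenic, replace = TRUE) +
        120000000L,
      gene_id = NA_character_, feature_class = "intergenic",
      tss_distance = NA_integer_, stringsAsFactors = FALSE))
  }
  n_clk <- cl$n_clock_cpgs
  clock_ids <- if (n_clk > 0L) sprintf("clk%04d", seq_len(n_clk)) else character()
  if (n_clk > 0L) {
    manifest <- rbind(manifest, data.frame(
      chrom = "chr19", pos = 150000000L + seq_len(n_clk) * 1000L,
      gene_id = NA_character_, feature_class = "intergenic",
      tss_distance = NA_integer_, stringsAsFactors = FALSE))
  }
  manifest <- data.frame(
    probe_id = c(sprintf("cg%06d", seq_len(nrow(manifest) - n_clk)), clock_ids),
    manifest, stringsAsFactors = FALSE)
  np <- nrow(manifest)
  is_clock <- manifest$probe_id %in% clock_ids

  ## ---- baselines ----------------------------------------------------------
  shape <- list(promoter = c(2, 8), five_prime_utr = c(2, 6), exon = c(6, 3),
                intron = c(5, 4), three_prime_utr = c(5, 4),
                intergenic_downstream = c(6, 3), intergenic = c(6, 3))
  baseline <- numeric(np)
  for (fc in names(shape)) {
    idx <- which(manifest$feature_class == fc & !is_clock)
    baseline[idx] <- clamp01(stats::rbeta(length(idx), shape[[fc]][1],
                                          shape[[fc]][2]), 0.05)
  }

  ## ---- clock CpG generative parameters (beta-linear in age) ---------------
  if (n_clk > 0L) {
    s_mag <- cl$slope_per_week * stats::runif(n_clk, 0.5, 1.5)
    s_sign <- sample(c(1, -1), n_clk, replace = TRUE)
    clk_slope <- s_mag * s_sign
    clk_m <- ifelse(s_sign > 0, stats::runif(n_clk, 0.10, 0.20),
                    stats::runif(n_clk, 0.80, 0.90))
  } else {
    clk_slope <- clk_m <- numeric()
  }

  ## ---- responsive promoter CpGs ------------------------------------------
  prom_idx <- which(manifest$feature_class == "promoter")
  n_resp <- round(config$effect_fraction * length(prom_idx))
  if (n_resp > length(prom_idx))
    stop("more responsive probes requested than promoter probes available")
  resp_idx <- sort(sample(prom_idx, n_resp))
  responsive <- logical(np)
  responsive[resp_idx] <- TRUE

  ## ---- latent structure ---------------------------------------------------
  animal_int <- stats::setNames(stats::rnorm(length(animal_id), 0,
                                             config$animal_sd), animal_id)
  batches <- unique(sheet$batch)
  batch_eff <- stats::setNames(stats::rnorm(length(batches), 0,
                                            config$batch_sd), batches)
  ruv_factor <- stats::setNames(stats::rnorm(n_s), sheet$sample_id)
  loadings <- stats::rnorm(np, 0, config$ruv_sd)
  eligible_ctrl <- which(!responsive & !is_clock)
  n_ctrl <- min(config$n_control_probes, length(eligible_ctrl))
  control_idx <- sort(sample(eligible_ctrl, n_ctrl))

  ## ---- ages ---------------------------------------------------------------
  age <- ifelse(sheet$age_group == "young", cl$young_age_weeks,
                cl$old_age_weeks)
  rho <- cl$regen_rejuvenation_rho
  eff_age <- ifelse(sheet$age_group == "old" & sheet$limb == "BaCl2",
                    age - rho * (age - cl$young_age_weeks), age)

  ## ---- beta matrix --------------------------------------------------------
  base_mat <- matrix(baseline, np, n_s)
  if (n_clk > 0L)
    base_mat[is_clock, ] <- outer(clk_slope, eff_age) + clk_m
  logit <- stats::qlogis(base_mat)
  # injury effect: beta-scale target shift injected on the logit scale
  d1 <- stats::qlogis(clamp01(baseline + config$delta_beta)) -
    stats::qlogis(clamp01(baseline))
  d2 <- stats::qlogis(clamp01(baseline + config$delta_beta +
                              config$senolytic_extra_delta)) -
    stats::qlogis(clamp01(baseline + config$delta_beta))
  arm <- arm_of(sheet)
  bacl2 <- sheet$limb == "BaCl2"
  for (s in which(bacl2)) {
    logit[resp_idx, s] <- logit[resp_idx, s] + d1[resp_idx]
    if (arm[s] == "OS")
      logit[resp_idx, s] <- logit[resp_idx, s] + d2[resp_idx]
  }
  shift_s <- animal_int[sheet$animal_id] + batch_eff[sheet$batch]
  logit <- sweep(logit, 2L, shift_s, `+`)
  logit <- logit + outer(loadings, ruv_factor)
  if (config$noise_sd > 0)
    logit <- logit + matrix(stats::rnorm(np * n_s, 0, config$noise_sd), np, n_s)
  beta <- stats::plogis(logit)
  dimnames(beta) <- list(manifest$probe_id, sheet$sample_id)

  ## ---- emitted clock: exact linear inverse of the generative trend --------
  clock <- NULL
  if (n_clk > 0L) {
    w <- clk_slope / sum(clk_slope^2)
    gold <- apply(beta[clock_ids, , drop = FALSE], 1L, stats::median)
    clock <- clock_model(name = "synthetic-generative",
                         intercept = -sum(w * clk_m),
                         weights = stats::setNames(w, clock_ids),
                         gold_medians = gold)
  }

  ## ---- counts -------------------------------------------------------------
  base_lexpr <- stats::rnorm(ng, 5, 2)
  resp_genes <- unique(manifest$gene_id[resp_idx])
  n_cpl <- round(config$coupled_fraction * length(resp_genes))
  coupled_genes <- sort(sample(resp_genes, n_cpl))
  pool <- setdiff(genes$gene_id, resp_genes)
  n_deo <- min(round(config$de_only_fraction * ng), length(pool))
  de_only_genes <- sort(sample(pool, n_deo))
  de_only_sign <- stats::setNames(
    rep_len(c(1, -1), n_deo)[sample.int(max(n_deo, 1L), n_deo)], de_only_genes)

  l2shift <- matrix(0, ng, n_s, dimnames = list(genes$gene_id, sheet$sample_id))
  for (g in coupled_genes) {
    pj <- intersect(which(responsive), which(manifest$gene_id == g &
                                             manifest$feature_class == "promoter"))
    dev <- colMeans(beta[pj, , drop = FALSE]) - mean(baseline[pj])
    l2shift[g, ] <- -config$coupling_gamma * dev
  }
  if (n_deo > 0L)
    l2shift[de_only_genes, bacl2] <- de_only_sign * config$de_only_lfc
  rel <- 2^(base_lexpr + l2shift)
  frac <- sweep(rel, 2L, colSums(rel), `/`)
  lib <- stats::runif(n_s, config$lib_size_range[1], config$lib_size_range[2])
  mu <- sweep(frac, 2L, lib, `*`)
  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(ng * n_s, mu = mu, size = 1 / config$nb_dispersion),
           ng, n_s)
  } else {
    matrix(stats::rpois(ng * n_s, mu), ng, n_s)
  }
  dimnames(counts) <- dimnames(mu)

  truth <- list(
    responsive = data.frame(probe_id = manifest$probe_id[resp_idx],
                            delta_beta = rep(config$delta_beta,
                                             length(resp_idx)),
                            stringsAsFactors = FALSE),
    control_probes = manifest$probe_id[control_idx],
    coupled = data.frame(gene_id = coupled_genes,
                         gamma = rep(config$coupling_gamma,
                                     length(coupled_genes)),
                         stringsAsFactors = FALSE),
    de_only = data.frame(gene_id = de_only_genes,
                         lfc = unname(de_only_sign * config$de_only_lfc),
                         stringsAsFactors = FALSE),
    clock_probes = data.frame(probe_id = clock_ids, slope = clk_slope,
                              level = clk_m, stringsAsFactors = FALSE),
    ages = data.frame(sample_id = sheet$sample_id, age_weeks = age,
                      true_dnam_age = eff_age, stringsAsFactors = FALSE),
    batch_effects = batch_eff, animal_intercepts = animal_int,
    ruv_factor = ruv_factor, ruv_loadings = stats::setNames(loadings,
                                                            manifest$probe_id))

  structure(list(manifest = manifest, genes = genes, beta = beta,
                 counts = counts, sheet = sheet, clock = clock,
                 truth = truth, config = config),
            class = "methregen_study")
}

#' @export
print.methregen_study <- function(x, ...) {
  cat(sprintf(
    "methregen_study: %d probes x %d samples, %d genes, %d responsive CpGs, seed %d\n",
    nrow(x$beta), ncol(x$beta), nrow(x$genes), nrow(x$truth$responsive),
    x$config$seed))
  invisible(x)
}

#' Differential expression table from simulated counts
#'
#' A lightweight internal two-group test so the synthetic pipeline is closed:
#' per-gene moderated t on log2(counts-per-million + 0.5) between the BaCl2
#' and PBS limbs of one arm, BH-adjusted. Genes with all-zero counts across
#' the tested samples are excluded (with a message).
#'
#' @param counts gene x sample count matrix.
#' @param sheet sample sheet covering the count columns.
#' @param contrast arm to test: "YV", "OV" or "OS".
#' @param paired include a per-animal blocking factor.
#' @return data.frame: gene_id, log2_fold_change, p, adj_p.
#' @export
emit_de_table <- function(counts, sheet, contrast = "OV", paired = TRUE) {
  sheet <- sheet[arm_of(sheet) == contrast, , drop = FALSE]
  if (length(unique(sheet$limb)) < 2L ||
      min(table(sheet$limb)) < 2L)
    stop("need >= 2 samples per contrast level in arm ", contrast)
  counts <- counts[, sheet$sample_id, drop = FALSE]
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    message(sum(zero), " genes with all-zero counts excluded")
    counts <- counts[!zero, , drop = FALSE]
  }
  cpm <- sweep(counts, 2L, colSums(counts), `/`) * 1e6
  y <- log2(cpm + 0.5)
  design <- build_design(sheet, paired = paired, batch = FALSE)
  fit <- fit_probe_models(y, design)
  mod <- tryCatch(moderate_variances(fit$sigma2, fit$df),
                  error = function(e) {
                    # too few genes to estimate a prior: ordinary t
                    list(d0 = 0, s0_sq = NA_real_, post_var = fit$sigma2)
                  })
  tt <- moderated_t(fit, mod)
  data.frame(gene_id = rownames(counts), log2_fold_change = fit$effect,
             p = tt$p, adj_p = benjamini_hochberg(tt$p),
             stringsAsFactors = FALSE, row.names = NULL)
}
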