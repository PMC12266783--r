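#' Build a design matrix for a within-arm limb contrast
#'
#' Models the BaCl2-vs-PBS contrast inside one arm. With `paired = TRUE` a
#' per-animal blocking factor absorbs the shared-animal intercept (batch is
#' then redundant because contralateral limbs share a chip); with
#' `paired = FALSE` batch indicator columns are included instead, matching a
#' covariate-only model. An optional unwanted-variation factor is appended
#' as a numeric column.
#'
#' @param sheet sample sheet (already restricted to one arm, or use `arm`).
#' @param arm optional arm label ("YV"/"OV"/"OS") to subset by.
#' @param paired include per-animal blocking.
#' @param batch include batch indicators (ignored when paired).
#' @param ruv optional named numeric per-sample factor values.
#' @return list with `X` (design matrix), `contrast` (vector picking the
#'   BaCl2 effect), `sample_ids`.
#' @export
build_design <- function(sheet, arm = NULL, paired = TRUE, batch = TRUE,
                         ruv = NULL) {
  if (!is.null(arm)) sheet <- sheet[arm_of(sheet) == arm, , drop = FALSE]
  if (nrow(sheet) == 0L) stop("no samples selected for design")
  limb <- as.integer(sheet$limb == "BaCl2")
  cols <- list(intercept = rep(1, nrow(sheet)), limbBaCl2 = limb)
  if (paired) {
    an <- factor(sheet$animal_id)
    if (nlevels(an) > 1L) {
      mm <- stats::model.matrix(~an)[, -1L, drop = FALSE]
      colnames(mm) <- paste0("animal_", levels(an)[-1L])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  } else if (batch) {
    ba <- factor(sheet$batch)
    if (nlevels(ba) > 1L) {
      mm <- stats::model.matrix(~ba)[, -1L, drop = FALSE]
      colnames(mm) <- paste0("batch_", levels(ba)[-1L])
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  if (!is.null(ruv)) {
    v <- if (!is.null(names(ruv))) ruv[sheet$sample_id] else ruv
    if (length(v) != nrow(sheet) || anyNA(v))
      stop("ruv factor does not cover the design samples")
    cols[["ruv1"]] <- as.numeric(v)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- sheet$sample_id
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient")
  contrast <- as.numeric(colnames(X) == "limbBaCl2")
  list(X = X, contrast = contrast, sample_ids = sheet$sample_id)
}

#' Estimate one unwanted-variation factor from control probes
#'
#' Removes the fitted known-covariate effects from the control-probe
#' submatrix, row-centres the residuals, and returns the first right
#' singular vector (unit norm, sign fixed so the largest-magnitude entry is
#' positive) as the per-sample factor.
#'
#' @param beta beta (or M-value) matrix, probes x samples.
#' @param design design list from [build_design()] (known covariates only).
#' @param control_probes probe ids of negative controls (>= 10).
#' @param k number of factors; only 1 supported.
#' @return named numeric vector of per-sample factor values.
#' @export
estimate_ruv_factor <- function(beta, design, control_probes, k = 1L) {
  if (k != 1L) stop("only k = 1 is supported")
  control_probes <- intersect(control_probes, rownames(beta))
  if (length(control_probes) < 10L) stop("need >= 10 control probes")
  Y <- beta[control_probes, design$sample_ids, drop = FALSE]
  if (anyNA(Y)) stop("control probes must be complete (no missing values)")
  X <- design$X
  H <- X %*% solve(crossprod(X), t(X))
  E <- Y - Y %*% t(H)
  E <- E - rowMeans(E)
  sv <- svd(E, nu = 0, nv = 1L)
  if (sv$d[1L] <= 1e-12)
    stop("control-probe residual matrix has rank 0; cannot estimate factor")
  f <- sv$v[, 1L]
  f <- f * sign(f[which.max(abs(f))])
  stats::setNames(f, design$sample_ids)
}

#' Per-probe least-squares fits
#'
#' Ordinary least squares of each probe on the design; probes with missing
#' values are fitted on their observed subset with recomputed residual
#' degrees of freedom. Returns everything the moderation step needs.
#'
#' @param y probes x samples response matrix (betas, M-values, or log-CPM).
#' @param design design list from [build_design()].
#' @return list of per-probe vectors: `effect` (contrast estimate),
#'   `sigma2` (residual variance), `df` (residual df), `u` (unscaled
#'   standard error of the contrast), `n_obs`.
#' @export
fit_probe_models <- function(y, design) {
  X <- design$X
  cvec <- design$contrast
  y <- y[, rownames(X), drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank-deficient")
  np <- nrow(y)
  effect <- sigma2 <- u <- rep(NA_real_, np)
  df <- n_obs <- rep(NA_integer_, np)
  complete <- !apply(y, 1L, anyNA)

  if (any(complete)) {
    XtXi <- solve(crossprod(X))
    coef <- y[complete, , drop = FALSE] %*% X %*% XtXi  # rows = probes
    res <- y[complete, , drop = FALSE] - coef %*% t(X)
    d <- n - p
    effect[complete] <- drop(coef %*% cvec)
    sigma2[complete] <- rowSums(res^2) / d
    df[complete] <- d
    u[complete] <- sqrt(drop(t(cvec) %*% XtXi %*% cvec))
    n_obs[complete] <- n
  }
  for (i in which(!complete)) {
    ok <- !is.na(y[i, ])
    Xi <- X[ok, , drop = FALSE]
    if (sum(ok) <= ncol(Xi) || qr(Xi)$rank < ncol(Xi)) next  # unestimable
    XtXi <- solve(crossprod(Xi))
    b <- XtXi %*% crossprod(Xi, y[i, ok])
    r <- y[i, ok] - drop(Xi %*% b)
    d <- sum(ok) - ncol(Xi)
    effect[i] <- sum(cvec * b)
    sigma2[i] <- sum(r^2) / d
    df[i] <- d
    u[i] <- sqrt(drop(t(cvec) %*% XtXi %*% cvec))
    n_obs[i] <- sum(ok)
  }
  list(effect = stats::setNames(effect, rownames(y)), sigma2 = sigma2,
       df = df, u = u, n_obs = n_obs)
}

# Newton inversion of the trigamma function (x = trigamma(y), solve for y).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the scaled inverse-chi-square prior (d0, s0^2) by matching the
#' first two moments of log s_g^2 to the scaled-F prior predictive
#' (digamma/trigamma inversion), then shrinks each variance to its posterior
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`. When the observed log-variances are
#' no more dispersed than chi-square sampling alone explains, d0 is
#' infinite and every posterior variance equals s0^2.
#'
#' @param sigma2 per-probe residual variances.
#' @param df per-probe residual degrees of freedom.
#' @return list: `d0`, `s0_sq`, `post_var` (per-probe posterior variances,
#'   aligned with the input).
#' @export
moderate_variances <- function(sigma2, df) {
  ok <- is.finite(sigma2) & is.finite(df) & df > 0 & sigma2 > 0
  if (sum(ok) < 30L)
    stop("need >= 30 probes with positive residual variance")
  z <- log(sigma2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1L) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0) || d0 <= 0) {  # non-convergent inversion
      message("trigamma inversion failed; falling back to d0 = Inf")
      d0 <- Inf
    }
  } else {
    d0 <- Inf
  }
  s0_sq <- if (is.finite(d0)) exp(ebar + digamma(d0 / 2) - log(d0 / 2))
           else mean(sigma2[ok])  # no excess dispersion: pooled variance
  post <- rep(NA_real_, length(sigma2))
  s2 <- ifelse(is.finite(sigma2), sigma2, NA_real_)
  if (is.finite(d0)) {
    post <- (d0 * s0_sq + df * s2) / (d0 + df)
  } else {
    post[!is.na(s2)] <- s0_sq
  }
  list(d0 = d0, s0_sq = s0_sq, post_var = post)
}

#' Moderated t statistics
#'
#' @param fit output of [fit_probe_models()].
#' @param moderation output of [moderate_variances()].
#' @return list: `t`, `df_total`, `p` (two-sided).
#' @export
moderated_t <- function(fit, moderation) {
  t_mod <- fit$effect / (fit$u * sqrt(moderation$post_var))
  # d0 + d_g, capped at the total residual df the data actually carry
  df_total <- pmin(moderation$d0 + fit$df, sum(fit$df, na.rm = TRUE))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(t = t_mod, df_total = df_total, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper around the standard step-up FDR adjustment.
#'
#' @param p vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in the original order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify differential-methylation records
#'
#' Adds the direction call: `hypo` if q < threshold and the BaCl2-minus-PBS
#' effect is negative, `hyper` if positive, `ns` otherwise. A significant
#' record with an exactly zero effect is left `ns` (with a message).
#'
#' @param records data.frame with columns `effect` and `q`.
#' @param q_threshold significance threshold on the adjusted p-value.
#' @return `records` with a `direction` column.
#' @export
classify_dm <- function(records, q_threshold = 0.05) {
  sig <- !is.na(records$q) & records$q < q_threshold
  dir <- rep("ns", nrow(records))
  dir[sig & records$effect < 0] <- "hypo"
  dir[sig & records$effect > 0] <- "hyper"
  if (any(sig & records$effect == 0))
    message("significant record with zero effect left 'ns'")
  records$direction <- dir
  records
}

#' Tally significant probes by feature class
#'
#' @param records classified DM records (with `direction`, `feature_class`).
#' @return list: `tally` (data.frame feature_class x hypo/hyper counts) and
#'   `promoter_by_gene` (per-gene promoter counts).
#' @export
tally_by_feature <- function(records) {
  sig <- records[records$direction %in% c("hypo", "hyper"), , drop = FALSE]
  fcs <- intersect(FEATURE_CLASSES, unique(records$feature_class))
  tal <- data.frame(
    feature_class = fcs,
    hypo = vapply(fcs, function(f)
      sum(sig$feature_class == f & sig$direction == "hypo"), 0L),
    hyper = vapply(fcs, function(f)
      sum(sig$feature_class == f & sig$direction == "hyper"), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  prom <- sig[sig$feature_class == "promoter", , drop = FALSE]
  pg <- if (nrow(prom)) {
    agg <- stats::aggregate(list(n_hypo = prom$direction == "hypo",
                                 n_hyper = prom$direction == "hyper"),
                            by = list(gene_id = prom$gene_id), FUN = sum)
    agg[order(agg$gene_id), , drop = FALSE]
  } else {
    data.frame(gene_id = character(), n_hypo = integer(),
               n_hyper = integer(), stringsAsFactors = FALSE)
  }
  list(tally = tal, promoter_by_gene = pg)
}

#' Paired BaCl2/PBS fold changes
#'
#' Per-animal ratio of the BaCl2 limb beta to the contralateral PBS limb
#' beta, summarised by the geometric mean. Animals lacking either limb, or
#' with a zero PBS beta, are skipped (the latter with a message).
#'
#' @param beta beta matrix.
#' @param sheet sample sheet.
#' @param probe_id single probe id; if NULL, the geometric-mean summary is
#'   returned for every probe.
#' @param arm optional arm restriction.
#' @return for one probe, list(ratios, geometric_mean); otherwise a named
#'   vector of geometric means.
#' @export
paired_fold_change <- function(beta, sheet, probe_id = NULL, arm = NULL) {
  if (!is.null(arm)) sheet <- sheet[arm_of(sheet) == arm, , drop = FALSE]
  pbs <- sheet[sheet$limb == "PBS", ]
  ba <- sheet[sheet$limb == "BaCl2", ]
  animals <- intersect(pbs$animal_id, ba$animal_id)
  s_pbs <- pbs$sample_id[match(animals, pbs$animal_id)]
  s_ba <- ba$sample_id[match(animals, ba$animal_id)]
  one <- function(pid) {
    num <- beta[pid, s_ba]
    den <- beta[pid, s_pbs]
    keep <- !is.na(num) & !is.na(den) & den > 0
    if (any(!is.na(den) & den == 0))
      message("probe ", pid, ": animal with zero PBS beta skipped")
    r <- stats::setNames(num[keep] / den[keep], animals[keep])
    list(ratios = r, geometric_mean = exp(mean(log(r))))
  }
  if (!is.null(probe_id)) return(one(probe_id))
  num <- beta[, s_ba, drop = FALSE]
  den <- beta[, s_pbs, drop = FALSE]
  lr <- log(num / den)
  lr[!is.finite(lr)] <- NA
  exp(rowMeans(lr, na.rm = TRUE))
}

#' Differential methylation for one arm's limb contrast
#'
#' The full per-probe chain: design construction (optionally with one
#' unwanted-variation factor estimated from negative-control probes),
#' least-squares fits, empirical-Bayes variance moderation, BH correction,
#' direction classification, paired fold changes, and manifest annotation.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet.
#' @param manifest probe manifest.
#' @param arm arm to contrast ("YV", "OV", "OS").
#' @param q_threshold significance threshold (default 0.05).
#' @param paired use per-animal blocking (default TRUE; set FALSE for the
#'   covariate-only model with batch indicators).
#' @param ruv "none", "auto" (controls = least-variable 1% of probes after
#'   covariate removal) or "supplied" (use `control_probes`).
#' @param control_probes probe ids of negative controls when
#'   `ruv = "supplied"`.
#' @param on model "beta" values directly (default) or "mvalue" (logit).
#' @return data.frame of per-probe records: probe_id, gene_id,
#'   feature_class, effect, paired_fc, t_mod, p, q, direction. The
#'   moderation parameters are attached as attributes `d0` and `s0_sq`.
#' @export
diff_methylation <- function(beta, sheet, manifest, arm,
                             q_threshold = 0.05, paired = TRUE,
                             ruv = c("none", "auto", "supplied"),
                             control_probes = NULL,
                             on = c("beta", "mvalue")) {
  ruv <- match.arg(ruv)
  on <- match.arg(on)
  validate_beta_matrix(beta)
  y <- if (on == "mvalue") stats::qlogis(pmin(pmax(beta, 1e-6), 1 - 1e-6))
       else beta
  design <- build_design(sheet, arm = arm, paired = paired)
  y <- y[, design$sample_ids, drop = FALSE]

  if (ruv != "none") {
    if (ruv == "auto") {
      X <- design$X
      H <- X %*% solve(crossprod(X), t(X))
      cc <- y[!apply(y, 1L, anyNA), , drop = FALSE]
      E <- cc - cc %*% t(H)
      rv <- rowSums(E^2)
      n_ctrl <- max(10L, ceiling(0.01 * nrow(cc)))
      control_probes <- rownames(cc)[order(rv)[seq_len(n_ctrl)]]
    }
    if (is.null(control_probes)) stop("ruv='supplied' needs control_probes")
    fac <- estimate_ruv_factor(y, design, control_probes)
    design <- build_design(sheet, arm = arm, paired = paired, ruv = fac)
  }

  fit <- fit_probe_models(y, design)
  mod <- moderate_variances(fit$sigma2, fit$df)
  tt <- moderated_t(fit, mod)
  q <- benjamini_hochberg(tt$p)
  rec <- data.frame(probe_id = rownames(y),
                    effect = unname(fit$effect),
                    t_mod = unname(tt$t), p = unname(tt$p), q = unname(q),
                    stringsAsFactors = FALSE, row.names = NULL)
  rec$paired_fc <- unname(paired_fold_change(beta, sheet, arm = arm)[rec$probe_id])
  rec <- classify_dm(rec, q_threshold = q_threshold)
  ann <- manifest[match(rec$probe_id, manifest$probe_id),
                  c("gene_id", "feature_class")]
  rec$gene_id <- ann$gene_id
  rec$feature_class <- ann$feature_class
  rec <- rec[, c("probe_id", "gene_id", "feature_class", "effect",
                 "paired_fc", "t_mod", "p", "q", "direction")]
  attr(rec, "d0") <- mod$d0
  attr(rec, "s0_sq") <- mod$s0_sq
  rec
}
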