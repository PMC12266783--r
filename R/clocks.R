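#' Construct a DNA-methylation age clock
#'
#' A clock is a sparse linear predictor of age (in weeks) from beta values:
#' `age = transform(intercept + sum_j w_j * beta_j)`. Every weighted probe
#' must carry a gold-median reference value used to impute the probe when it
#' is absent from (or missing in) the matrix the clock is applied to.
#'
#' @param name clock label.
#' @param intercept intercept, weeks.
#' @param weights named numeric vector, probe_id -> weight.
#' @param gold_medians named numeric vector of reference beta medians in
#'   \[0, 1\]; must cover every weighted probe.
#' @param transform output transform: "identity" (age in weeks) or
#'   "log_linear" with parameters `adult_age` (weeks), mirroring the
#'   calibrated transforms published clocks use.
#' @param transform_params list of transform parameters.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, weights, gold_medians,
                        transform = c("identity", "log_linear"),
                        transform_params = list()) {
  transform <- match.arg(transform)
  if (is.null(names(weights)) || any(names(weights) == ""))
    stop("clock weights must be named by probe_id")
  if (!all(is.finite(weights))) stop("clock weights must be finite")
  miss <- setdiff(names(weights), names(gold_medians))
  if (length(miss))
    stop("weighted probes without gold medians: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  if (any(gold_medians < 0 | gold_medians > 1))
    stop("gold medians must lie in [0,1]")
  structure(list(name = name, intercept = intercept, weights = weights,
                 gold_medians = gold_medians, transform = transform,
                 transform_params = transform_params),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model '%s': %d probes, intercept %.3f weeks, %s transform\n",
              x$name, length(x$weights), x$intercept, x$transform))
  invisible(x)
}

clock_transform <- function(raw, clock) {
  switch(clock$transform,
         identity = raw,
         log_linear = {
           # inverse of Horvath-style log-linear age calibration
           a <- clock$transform_params$adult_age %||% 52
           ifelse(raw < 0, (1 + a) * exp(raw) - 1, (1 + a) * raw + a)
         })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Apply a clock to a beta matrix
#'
#' Missing clock probes (absent rows or NA cells) are imputed with the
#' clock's gold medians; a probe absent from both the matrix and the gold
#' medians is an error.
#'
#' @param beta beta matrix (probes x samples).
#' @param clock a [clock_model()].
#' @return data.frame with sample_id, dnam_age (weeks), n_imputed.
#' @export
apply_clock <- function(beta, clock) {
  probes <- names(clock$weights)
  absent <- setdiff(probes, rownames(beta))
  # absent probes fall back to gold medians, which the constructor guarantees
  present <- intersect(probes, rownames(beta))
  if (length(present) == 0L && length(clock$gold_medians) == 0L)
    stop("no clock probe present in matrix or gold medians")
  x <- matrix(rep(clock$gold_medians[probes], ncol(beta)),
              nrow = length(probes), ncol = ncol(beta),
              dimnames = list(probes, colnames(beta)))
  imputed <- matrix(TRUE, nrow = length(probes), ncol = ncol(beta))
  rownames(imputed) <- probes
  if (length(present)) {
    obs <- beta[present, , drop = FALSE]
    keep <- !is.na(obs)
    x[present, ][keep] <- obs[keep]
    imputed[present, ][keep] <- FALSE
  }
  raw <- clock$intercept + drop(crossprod(x, clock$weights[probes]))
  data.frame(sample_id = colnames(beta),
             dnam_age = clock_transform(raw, clock),
             n_imputed = colSums(imputed),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Train a synthetic clock by ridge regression
#'
#' Ridge-penalised least squares of age on candidate-probe betas (intercept
#' unpenalised, fitted on centred data). Gold medians are the per-probe
#' medians of the training matrix; NA cells are median-imputed before
#' fitting.
#'
#' @param beta training beta matrix (probes x samples).
#' @param ages named numeric vector of ages in weeks (names = sample ids) or
#'   a numeric vector aligned with `colnames(beta)`.
#' @param penalty ridge penalty lambda > 0.
#' @param candidate_probes probes eligible for weights; default all rows.
#' @param name clock label.
#' @return a [clock_model()].
#' @export
train_synthetic_clock <- function(beta, ages, penalty = 1e-3,
                                  candidate_probes = NULL,
                                  name = "synthetic") {
  if (ncol(beta) < 2L) stop("need at least 2 training samples")
  if (length(unique(ages)) < 2L) stop("need at least 2 distinct ages")
  if (penalty <= 0) stop("penalty must be > 0")
  if (!is.null(names(ages))) ages <- ages[colnames(beta)]
  if (length(ages) != ncol(beta)) stop("ages do not align with samples")
  probes <- candidate_probes %||% rownames(beta)
  X <- t(beta[probes, , drop = FALSE])
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  for (j in seq_along(med)) X[is.na(X[, j]), j] <- med[j]
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- ages - mean(ages)
  p <- ncol(Xc)
  w <- drop(solve(crossprod(Xc) + diag(penalty, p), crossprod(Xc, yc)))
  names(w) <- probes
  clock_model(name = name,
              intercept = mean(ages) - sum(w * xbar),
              weights = w, gold_medians = med)
}

#' Percent deceleration of DNA-methylation age
#'
#' `100 * (mean_control - mean_treated) / mean_control`, the convention used
#' to summarise clock deceleration between a control condition (e.g. the
#' PBS-injected limb) and a treated/regenerated condition.
#'
#' @param mean_control mean DNAmAGE of the control condition, weeks (> 0).
#' @param mean_treated mean DNAmAGE of the treated condition, weeks.
#' @return list with `percent` and `weeks` (absolute difference).
#' @export
percent_deceleration <- function(mean_control, mean_treated) {
  if (!is.finite(mean_control) || mean_control <= 0)
    stop("mean_control must be > 0")
  list(percent = 100 * (mean_control - mean_treated) / mean_control,
       weeks = mean_control - mean_treated)
}

#' Write a clock definition file
#'
#' TSV with `#key value` metadata lines (name, intercept, transform) followed
#' by probe_id / weight / gold_median rows.
#'
#' @param clock a [clock_model()].
#' @param path output path.
#' @export
write_clock_model <- function(clock, path) {
  meta <- c(sprintf("#name\t%s", clock$name),
            sprintf("#intercept\t%.17g", clock$intercept),
            sprintf("#transform\t%s", clock$transform))
  probes <- union(names(clock$weights), names(clock$gold_medians))
  w <- ifelse(probes %in% names(clock$weights), clock$weights[probes], 0)
  body <- sprintf("%s\t%.17g\t%.17g", probes, w, clock$gold_medians[probes])
  writeLines(c(meta, "probe_id\tweight\tgold_median", body), path)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", meta), "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  w <- stats::setNames(body$weight, body$probe_id)
  clock_model(name = vals[keys == "name"],
              intercept = as.numeric(vals[keys == "intercept"]),
              weights = w[w != 0],
              gold_medians = stats::setNames(body$gold_median, body$probe_id),
              transform = vals[keys == "transform"])
}
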