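#' Regulatory-potential decay parameters
#'
#' The per-peak contribution to a gene decays with absolute TSS distance d
#' as `exp(-(alpha + beta_decay * d / window_d))`, zero beyond `window_d`.
#'
#' @param alpha decay offset (default 0.5).
#' @param beta_decay decay rate (default 4).
#' @param window_d maximum TSS distance in bp (default 100000).
#' @return list of class `rp_params`.
#' @export
rp_params <- function(alpha = 0.5, beta_decay = 4, window_d = 1e5) {
  if (window_d <= 0) stop("window_d must be > 0")
  if (beta_decay <= 0) stop("beta_decay must be > 0")
  structure(list(alpha = alpha, beta_decay = beta_decay,
                 window_d = window_d), class = "rp_params")
}

#' Methylation peaks from differential-methylation records
#'
#' Recasts each significant DM CpG as a single-bp genomic feature, in the
#' spirit of transcription-factor binding peaks, optionally restricted by
#' direction. Output is sorted by (chrom, pos).
#'
#' @param dm classified DM records.
#' @param manifest probe manifest providing positions.
#' @param q_threshold significance threshold.
#' @param direction_filter "both", "hypo_only" or "hyper_only".
#' @return data.frame: chrom, pos (1-based), probe_id, direction.
#' @export
peaks_from_dm <- function(dm, manifest, q_threshold = 0.05,
                          direction_filter = c("both", "hypo_only",
                                               "hyper_only")) {
  direction_filter <- match.arg(direction_filter)
  sig <- dm[!is.na(dm$q) & dm$q < q_threshold &
              dm$direction %in% c("hypo", "hyper"), , drop = FALSE]
  sig <- switch(direction_filter,
                both = sig,
                hypo_only = sig[sig$direction == "hypo", , drop = FALSE],
                hyper_only = sig[sig$direction == "hyper", , drop = FALSE])
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      probe_id = character(), direction = character(),
                      stringsAsFactors = FALSE))
  idx <- match(sig$probe_id, manifest$probe_id)
  if (anyNA(idx))
    stop("significant probes absent from manifest: ",
         paste(sig$probe_id[is.na(idx)], collapse = ", "))
  out <- data.frame(chrom = manifest$chrom[idx], pos = manifest$pos[idx],
                    probe_id = sig$probe_id, direction = sig$direction,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$probe_id), , drop = FALSE]
}

#' Regulatory potential of genes from methylation peaks
#'
#' For each gene, sums the decaying contributions of all peaks within
#' `window_d` of its strand-aware TSS (absolute distance; upstream and
#' downstream are treated alike). Genes with no peaks in the window score 0.
#'
#' @param genes gene-model data.frame (gene_id, chrom, strand, tss).
#' @param peaks peak data.frame (chrom, pos) from [peaks_from_dm()].
#' @param params decay parameters from [rp_params()].
#' @return data.frame: gene_id, rp, n_peaks.
#' @export
regulatory_potential <- function(genes, peaks, params = rp_params()) {
  rp <- numeric(nrow(genes))
  n_pk <- integer(nrow(genes))
  if (nrow(peaks) > 0L) {
    tss_gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(1L, genes$tss - as.integer(params$window_d)),
                       genes$tss + as.integer(params$window_d)))
    pk_gr <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$pos, peaks$pos))
    hits <- GenomicRanges::findOverlaps(tss_gr, pk_gr)
    gi <- S4Vectors::queryHits(hits)
    pj <- S4Vectors::subjectHits(hits)
    d <- abs(peaks$pos[pj] - genes$tss[gi])
    keep <- d <= params$window_d
    gi <- gi[keep]; d <- d[keep]
    contrib <- exp(-(params$alpha + params$beta_decay * d / params$window_d))
    agg <- rowsum(contrib, gi)
    rp[as.integer(rownames(agg))] <- agg[, 1L]
    cnt <- table(gi)
    n_pk[as.integer(names(cnt))] <- as.integer(cnt)
  }
  data.frame(gene_id = genes$gene_id, rp = rp, n_peaks = n_pk,
             stringsAsFactors = FALSE, row.names = NULL)
}

# deterministic competition-style rank: strict order by key, ties broken by id
strict_rank <- function(key, id) {
  ord <- order(key, id)
  r <- integer(length(key))
  r[ord] <- seq_along(key)
  r
}

#' Rank-product integration of regulatory potential and expression
#'
#' Within each differential-expression direction set (up: adj_p < threshold
#' and lfc > 0; down: adj_p < threshold and lfc < 0) genes are ranked by
#' regulatory potential (descending) and by DE p-value (ascending), ties
#' broken lexicographically by gene id, and combined as
#' `rank_product = rank_rp * rank_de / n^2`. A gene is a predicted
#' epigenetically regulated target when its rank product falls below
#' `rp_cutoff` and it has at least one peak in the window. Genes not in
#' either direction set are labelled `static` (adj_p >= `static_threshold`,
#' the direction-test background) or `excluded`.
#'
#' @param rp_scores output of [regulatory_potential()].
#' @param de DE table (gene_id, log2_fold_change, p, adj_p).
#' @param de_adj_p_threshold DE significance threshold (default 0.05).
#' @param rp_cutoff rank-product prediction cutoff (default 0.25).
#' @param static_threshold adj_p at or above which a gene is background.
#' @return data.frame of gene scores: gene_id, rp, n_peaks, de_class,
#'   rank_rp, rank_de, rank_product, predicted.
#' @export
rank_product_integration <- function(rp_scores, de,
                                     de_adj_p_threshold = 0.05,
                                     rp_cutoff = 0.25,
                                     static_threshold = 0.5) {
  m <- merge(de, rp_scores, by = "gene_id", all.x = TRUE)
  m$rp[is.na(m$rp)] <- 0
  m$n_peaks[is.na(m$n_peaks)] <- 0L
  sig <- !is.na(m$adj_p) & m$adj_p < de_adj_p_threshold
  m$de_class <- ifelse(sig & m$log2_fold_change > 0, "up",
                ifelse(sig & m$log2_fold_change < 0, "down",
                ifelse(!is.na(m$adj_p) & m$adj_p >= static_threshold,
                       "static", "excluded")))
  m$rank_rp <- m$rank_de <- m$rank_product <- NA_real_
  m$predicted <- FALSE
  for (lab in c("up", "down")) {
    idx <- which(m$de_class == lab)
    if (length(idx) == 0L) {
      message("empty DE direction set: ", lab)
      next
    }
    n <- length(idx)
    r_rp <- strict_rank(-m$rp[idx], m$gene_id[idx])
    r_de <- strict_rank(m$p[idx], m$gene_id[idx])
    m$rank_rp[idx] <- r_rp
    m$rank_de[idx] <- r_de
    m$rank_product[idx] <- r_rp * r_de / n^2
    m$predicted[idx] <- m$rank_product[idx] < rp_cutoff & m$n_peaks[idx] >= 1L
  }
  m <- m[order(m$gene_id), c("gene_id", "rp", "n_peaks", "de_class",
                             "rank_rp", "rank_de", "rank_product",
                             "predicted")]
  rownames(m) <- NULL
  m
}

# one-sided statistic: sup_x [ P(set >= x) - P(bg >= x) ]
dplus_stat <- function(set, bg) {
  u <- sort(unique(c(set, bg)))
  ss <- sort(set); bb <- sort(bg)
  s_set <- (length(ss) - findInterval(u, ss, left.open = TRUE)) / length(ss)
  s_bg <- (length(bb) - findInterval(u, bb, left.open = TRUE)) / length(bb)
  max(s_set - s_bg)
}

#' Activating/repressive direction test
#'
#' Compares the regulatory-potential distribution of one DE direction set
#' (up- or down-regulated genes) against the static background by a
#' one-sided two-sample Kolmogorov-Smirnov statistic
#' `D+ = sup_x [S_set(x) - S_bg(x)]` on the survival functions, so that
#' systematically larger regulatory potential in the set gives a larger D+.
#' The p-value is the asymptotic `exp(-2 D+^2 mn/(m+n))` when both groups
#' have at least 50 genes, otherwise a seeded label-permutation p
#' `(1 + #{D+perm >= D+obs}) / (B + 1)`.
#'
#' @param scores gene scores from [rank_product_integration()] (columns
#'   `rp` and `de_class`), or any data.frame with those columns.
#' @param set_label "up" or "down".
#' @param method "auto", "asymptotic" or "permutation".
#' @param B number of permutations (default 9999).
#' @param seed permutation RNG seed.
#' @return list of class `direction_test`: set_label, d_plus, p, n_set,
#'   n_background, method.
#' @export
direction_test <- function(scores, set_label = c("up", "down"),
                           method = c("auto", "asymptotic", "permutation"),
                           B = 9999L, seed = 1L) {
  set_label <- match.arg(set_label)
  method <- match.arg(method)
  set <- scores$rp[scores$de_class == set_label]
  bg <- scores$rp[scores$de_class == "static"]
  m <- length(set); n <- length(bg)
  if (m == 0L || n == 0L)
    stop("direction test needs a non-empty set and background")
  d_obs <- dplus_stat(set, bg)
  if (method == "auto")
    method <- if (min(m, n) >= 50L) "asymptotic" else "permutation"
  if (method == "asymptotic") {
    p <- exp(-2 * d_obs^2 * m * n / (m + n))
    p <- min(max(p, .Machine$double.xmin), 1)
    meth <- "asymptotic"
  } else {
    pool <- c(set, bg)
    exceed <- 0L
    withr_seed <- seed  # permutation stream independent of caller RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(withr_seed)
    for (b in seq_len(B)) {
      lab <- sample.int(m + n, m)
      # ties on the D+ lattice count as exceedances (1e-9 guards rounding)
      if (dplus_stat(pool[lab], pool[-lab]) >= d_obs - 1e-9)
        exceed <- exceed + 1L
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    p <- (1 + exceed) / (B + 1)
    meth <- sprintf("permutation(seed=%d,B=%d)", seed, B)
  }
  structure(list(set_label = set_label, d_plus = d_obs, p = p, n_set = m,
                 n_background = n, method = meth),
            class = "direction_test")
}

#' @export
print.direction_test <- function(x, ...) {
  cat(sprintf("direction_test[%s]: D+ = %.4f, p = %.4g (%d vs %d, %s)\n",
              x$set_label, x$d_plus, x$p, x$n_set, x$n_background, x$method))
  invisible(x)
}

#' Overlap of two gene sets
#'
#' @param genes_a,genes_b character vectors of gene ids.
#' @return list: n_a_only, n_b_only, n_shared, shared (sorted ids).
#' @export
overlap_sets <- function(genes_a, genes_b) {
  a <- unique(genes_a); b <- unique(genes_b)
  shared <- sort(intersect(a, b))
  list(n_a_only = length(setdiff(a, b)), n_b_only = length(setdiff(b, a)),
       n_shared = length(shared), shared = shared)
}
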