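#' Estimator options for f-statistics
#'
#' @param bias_correction Apply the finite-sample heterozygosity correction
#'   to f2 and f3 (subtracting `h/n` terms with
#'   `h = p (1 - p) n / (n - 1)` for each population sampled twice in the
#'   statistic).  Off by default so that the exact linear identities among
#'   plain-average estimators hold; f4 over four distinct populations is
#'   unbiased without correction.
#' @param polymorphic_only Drop sites that are monomorphic (fixed for the
#'   same allele) across the populations entering the statistic.  Off by
#'   default: fixed sites are informative about the absolute scale of
#'   f-statistics.
#' @param z_threshold |Z| above which a statistic is reported as
#'   significantly non-zero (no general rule exists; this is a knob
#'   reported alongside results).
#' @param max_overlap Experimental: in [build_basis()], compute each basis
#'   statistic on the largest SNP set available for its own populations
#'   instead of the intersection over all model populations.  Can give
#'   unreliable fits and is excluded from fitting defaults.
#' @return A list of class `estimator_options`.
#' @export
estimator_options <- function(bias_correction = FALSE,
                              polymorphic_only = FALSE,
                              z_threshold = 3,
                              max_overlap = FALSE) {
  stopifnot(z_threshold > 0)
  structure(list(bias_correction = isTRUE(bias_correction),
                 polymorphic_only = isTRUE(polymorphic_only),
                 z_threshold = z_threshold,
                 max_overlap = isTRUE(max_overlap)),
            class = "estimator_options")
}

new_f_stat <- function(kind, pops, value, se, n_snps, n_blocks) {
  z <- if (!is.na(se) && se > 0) value / se else NA_real_
  structure(list(kind = kind, pops = pops, value = value, se = se, z = z,
                 n_snps = n_snps, n_blocks = n_blocks),
            class = "f_stat")
}

#' @export
print.f_stat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  (se %.3g, Z %.2f, %d SNPs, %d blocks)\n",
              x$kind, fstat_label_pops(x$kind, x$pops), x$value, x$se,
              if (is.na(x$z)) NA else x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

fstat_label_pops <- function(kind, pops) {
  switch(kind,
         f2 = paste(pops[1:2], collapse = ","),
         f3 = paste0(pops[1], ";", pops[2], ",", pops[3]),
         paste0(pops[1], ",", pops[2], ";", pops[3], ",", pops[4]))
}

fstat_label <- function(kind, pops) {
  paste0(kind, "(", fstat_label_pops(kind, pops), ")")
}

#' @export
as.data.frame.f_stat <- function(x, ...) {
  data.frame(kind = x$kind, pops = paste(x$pops, collapse = ","),
             value = x$value, se = x$se, z = x$z, n_snps = x$n_snps,
             n_blocks = x$n_blocks, stringsAsFactors = FALSE)
}

# Expand an f2/f3/f4 population tuple to the defining f4 quadruple.
as_quadruple <- function(pops) {
  switch(as.character(length(pops)),
         "2" = c(pops[1], pops[2], pops[1], pops[2]),
         "3" = c(pops[1], pops[2], pops[1], pops[3]),
         "4" = pops,
         stop("a statistic involves 2, 3 or 4 populations"))
}

# Per-SNP products (pA - pB)(pC - pD) on the rows `idx`, with optional
# heterozygosity bias correction for repeated populations (f2/f3).
per_site_terms <- function(panel, quad, idx, bias_correction = FALSE) {
  fr <- panel$freq
  x <- (fr[idx, quad[1]] - fr[idx, quad[2]]) *
       (fr[idx, quad[3]] - fr[idx, quad[4]])
  if (bias_correction) {
    corr_pop <- function(p) {
      n <- panel$count[idx, p]
      pp <- fr[idx, p]
      h <- pp * (1 - pp) * n / (n - 1)
      h / n
    }
    if (quad[1] == quad[3]) x <- x - corr_pop(quad[1])
    if (quad[2] == quad[4]) x <- x - corr_pop(quad[2])
  }
  x
}

#' Weighted delete-one-block jackknife
#'
#' Given per-block sums of a statistic's per-SNP contributions and the
#' per-block SNP counts (the jackknife weights), returns the full-data
#' estimate (total sum over total weight) and the weighted delete-one-block
#' jackknife standard error.  With equal blocks this reduces to the
#' standard `sqrt(((m-1)/m) * sum((theta_j - mean)^2))` formula on the
#' leave-one-out values.
#'
#' @param sums Numeric vector of per-block sums.
#' @param weights Numeric vector of per-block weights (SNP counts).
#' @return A list with `estimate`, `se`, `loo` (leave-one-block-out
#'   estimates) and `n_blocks`.
#' @export
block_jackknife <- function(sums, weights) {
  keep <- weights > 0
  sums <- sums[keep]
  weights <- weights[keep]
  m <- length(sums)
  if (m < 2L)
    stop("block jackknife needs at least 2 non-empty blocks; ",
         "add blocks or more data")
  n <- sum(weights)
  est <- sum(sums) / n
  loo <- (sum(sums) - sums) / (n - weights)
  res <- jackknife_from_loo(est, loo, weights)
  list(estimate = est, se = res$se, loo = loo, n_blocks = m)
}

# Weighted jackknife SE (Busing et al. 1999) from leave-one-out estimates.
jackknife_from_loo <- function(est, loo, weights) {
  m <- length(loo)
  n <- sum(weights)
  h <- n / weights
  tau <- h * est - (h - 1) * loo
  theta_j <- m * est - sum((1 - weights / n) * loo)
  v <- mean((tau - theta_j)^2 / (h - 1))
  list(se = sqrt(max(v, 0)), pseudo = tau, theta_j = theta_j)
}

# Shared machinery: compute one statistic (as f4 quadruple) on a fixed SNP
# set with jackknife SE.
fstat_on_idx <- function(panel, kind, pops, idx,
                         options = estimator_options()) {
  quad <- as_quadruple(pops)
  if (length(idx) == 0L)
    stop("no overlapping sites: the populations (",
         paste(unique(pops), collapse = ", "),
         ") share no SNPs with data in all of them")
  x <- per_site_terms(panel, quad, idx,
                      bias_correction = options$bias_correction &&
                        kind %in% c("f2", "f3"))
  if (is.null(panel$block))
    stop("panel has no jackknife blocks; call assign_blocks() first")
  bl <- panel$block[idx]
  ub <- unique(bl)
  if (length(ub) < 2L) {
    est <- mean(x)
    return(new_f_stat(kind, pops, est, NA_real_, length(idx), length(ub)))
  }
  f <- factor(bl, levels = ub)
  sums <- as.vector(rowsum(x, f))
  w <- as.vector(table(f))
  jk <- block_jackknife(sums, w)
  new_f_stat(kind, pops, jk$estimate, jk$se, length(idx), jk$n_blocks)
}

fstat_idx <- function(panel, pops, options) {
  idx <- usable_snps(panel, unique(pops), options$polymorphic_only)
  if (options$bias_correction)
    idx <- idx[rowSums(panel$count[idx, unique(pops), drop = FALSE] < 2) == 0]
  idx
}

#' f4-statistic with block-jackknife standard error
#'
#' `f4(A,B;C,D)` is the average over SNPs of `(pA - pB)(pC - pD)`: the
#' correlation of allele-frequency differences between the pair (A,B) and
#' the pair (C,D).  Under an unadmixed phylogeny ((A,B),(C,D)) its
#' expectation is zero; a significantly non-zero value reflects shared
#' drift crossing that split, e.g. via admixture.  Sites are restricted to
#' those with data in all four populations.
#'
#' @param panel A [freq_panel()] with blocks assigned.
#' @param A,B,C,D Population labels.
#' @param options An [estimator_options()] list.
#' @return An object of class `f_stat` with fields `kind`, `pops`, `value`,
#'   `se`, `z`, `n_snps`, `n_blocks`.
#' @export
compute_f4 <- function(panel, A, B, C, D, options = estimator_options()) {
  pops <- c(A, B, C, D)
  check_pops(panel, pops)
  fstat_on_idx(panel, "f4", pops, fstat_idx(panel, pops, options), options)
}

#' f2-statistic (squared allele-frequency distance)
#'
#' `f2(A,B) = f4(A,B;A,B)`: the average of `(pA - pB)^2`, the branch-length
#' metric of population trees in f-statistic (drift) units.  The optional
#' bias correction subtracts each population's within-sample
#' heterozygosity term `h/n`.
#'
#' @inheritParams compute_f4
#' @return An `f_stat` object.
#' @export
compute_f2 <- function(panel, A, B, options = estimator_options()) {
  pops <- c(A, B)
  check_pops(panel, pops)
  fstat_on_idx(panel, "f2", pops, fstat_idx(panel, pops, options), options)
}

#' f3-statistic (three-population test)
#'
#' `f3(A;B,C) = f4(A,B;A,C)`: the average of `(pA - pB)(pA - pC)`.  A
#' significantly negative value (Z below `-z_threshold`) can only arise if
#' A is admixed between sources related to B and C, making this the
#' classic three-population admixture test.  The optional bias correction
#' removes A's sampling-noise term.
#'
#' @inheritParams compute_f4
#' @return An `f_stat` object.
#' @export
compute_f3 <- function(panel, A, B, C, options = estimator_options()) {
  pops <- c(A, B, C)
  check_pops(panel, pops)
  fstat_on_idx(panel, "f3", pops, fstat_idx(panel, pops, options), options)
}

#' D-statistic (normalized f4; ABBA-BABA)
#'
#' Same numerator as [compute_f4()] but normalized by
#' `sum((pA + pB - 2 pA pB)(pC + pD - 2 pC pD))`, which bounds the scale
#' and makes values approximately comparable across SNP sets.  The sign
#' always agrees with the f4-statistic.  The jackknife is applied to the
#' ratio.
#'
#' @inheritParams compute_f4
#' @return An `f_stat` object with `kind = "D"`.
#' @export
compute_d <- function(panel, A, B, C, D, options = estimator_options()) {
  pops <- c(A, B, C, D)
  check_pops(panel, pops)
  idx <- fstat_idx(panel, pops, options)
  if (length(idx) == 0L)
    stop("no overlapping sites: the populations (",
         paste(unique(pops), collapse = ", "),
         ") share no SNPs with data in all of them")
  fr <- panel$freq
  num <- (fr[idx, A] - fr[idx, B]) * (fr[idx, C] - fr[idx, D])
  den <- (fr[idx, A] + fr[idx, B] - 2 * fr[idx, A] * fr[idx, B]) *
         (fr[idx, C] + fr[idx, D] - 2 * fr[idx, C] * fr[idx, D])
  if (sum(den) == 0)
    stop("zero denominator: no heterozygosity at the usable sites")
  bl <- panel$block[idx]
  ub <- unique(bl)
  if (length(ub) < 2L) {
    return(new_f_stat("D", pops, sum(num) / sum(den), NA_real_,
                      length(idx), length(ub)))
  }
  f <- factor(bl, levels = ub)
  ns <- as.vector(rowsum(num, f))
  ds <- as.vector(rowsum(den, f))
  w <- as.vector(table(f))
  est <- sum(ns) / sum(ds)
  loo <- (sum(ns) - ns) / (sum(ds) - ds)
  se <- jackknife_from_loo(est, loo, w)$se
  new_f_stat("D", pops, est, se, length(idx), length(ub))
}

#' Jackknife covariance matrix for a set of f-statistics
#'
#' Computes all statistics on one shared SNP set (sites with data in every
#' population involved) and estimates their joint covariance from the same
#' leave-one-block-out replicates, so that off-diagonal entries capture
#' shared drift and shared sampling noise.  The diagonal equals each
#' statistic's squared jackknife standard error.
#'
#' @param panel A [freq_panel()] with blocks assigned.
#' @param stats A list of population tuples; each of length 2 (f2), 3 (f3)
#'   or 4 (f4).
#' @param options An [estimator_options()] list.
#' @return A symmetric positive semidefinite matrix with row/column names
#'   labelling the statistics.  The full-data estimates are attached as
#'   attribute `estimates`, the shared SNP count as `n_snps`.
#' @export
jackknife_covariance <- function(panel, stats, options = estimator_options()) {
  res <- fstat_block_system(panel, stats, options)
  Q <- res$Q
  attr(Q, "estimates") <- res$estimates
  attr(Q, "n_snps") <- res$n_snps
  Q
}

# Estimates + jackknife covariance from per-block sums for a list of
# statistics. In the default (complete-cases) mode every statistic uses the
# SNPs covered in all populations involved in any of them.
fstat_block_system <- function(panel, stats, options = estimator_options()) {
  stats <- lapply(stats, as.character)
  all_pops <- unique(unlist(stats))
  check_pops(panel, all_pops)
  if (is.null(panel$block))
    stop("panel has no jackknife blocks; call assign_blocks() first")
  labels <- vapply(stats, function(p) {
    kind <- c("f2", "f3", "f4")[length(p) - 1L]
    fstat_label(kind, p)
  }, character(1))
  k <- length(stats)

  if (!options$max_overlap) {
    idx <- fstat_idx(panel, all_pops, options)
    if (length(idx) == 0L)
      stop("no overlapping sites across populations (",
           paste(all_pops, collapse = ", "),
           "); try other populations or more data")
    bl <- factor(panel$block[idx], levels = unique(panel$block[idx]))
    m <- nlevels(bl)
    if (m < 2L) stop("need at least 2 jackknife blocks")
    w <- as.vector(table(bl))
    sums <- matrix(0, m, k)
    for (j in seq_len(k)) {
      quad <- as_quadruple(stats[[j]])
      x <- per_site_terms(panel, quad, idx,
                          bias_correction = options$bias_correction &&
                            length(stats[[j]]) < 4L)
      sums[, j] <- rowsum(x, bl)
    }
    n <- sum(w)
    est <- colSums(sums) / n
    loo <- sweep(-sums, 2L, colSums(sums), `+`) / (n - w)
    h <- n / w
    wmat <- matrix(w, m, k)
    hmat <- matrix(h, m, k)
    n_used <- rep(length(idx), k)
  } else {
    # experimental per-statistic maximal-overlap mode
    blocks_all <- unique(panel$block)
    m <- length(blocks_all)
    if (m < 2L) stop("need at least 2 jackknife blocks")
    sums <- matrix(0, m, k)
    wmat <- matrix(0, m, k)
    est <- numeric(k)
    n_used <- integer(k)
    for (j in seq_len(k)) {
      quad <- as_quadruple(stats[[j]])
      idx_j <- fstat_idx(panel, stats[[j]], options)
      if (length(idx_j) == 0L)
        stop("no usable sites for ", labels[j])
      x <- per_site_terms(panel, quad, idx_j,
                          bias_correction = options$bias_correction &&
                            length(stats[[j]]) < 4L)
      bl <- factor(panel$block[idx_j], levels = blocks_all)
      s <- numeric(m)
      got <- rowsum(x, as.integer(bl))
      s[as.integer(rownames(got))] <- got[, 1]
      sums[, j] <- s
      wmat[, j] <- as.vector(table(bl))
      est[j] <- sum(x) / length(idx_j)
      n_used[j] <- length(idx_j)
    }
    if (any(wmat == 0))
      stop("max_overlap mode requires every block to contain usable sites ",
           "for every statistic; use the default complete-cases mode")
    nvec <- colSums(wmat)
    loo <- sweep(-sums, 2L, colSums(sums), `+`) /
      sweep(-wmat, 2L, nvec, `+`)
    hmat <- sweep(1 / wmat, 2L, nvec, `*`)
  }

  estmat <- matrix(est, m, k, byrow = TRUE)
  tau <- hmat * estmat - (hmat - 1) * loo
  theta_j <- colSums(estmat - (1 - wmat / matrix(colSums(wmat), m, k,
                                                 byrow = TRUE)) * loo)
  dev <- sweep(tau, 2L, theta_j) / sqrt(hmat - 1)
  Q <- crossprod(dev) / m
  Q <- (Q + t(Q)) / 2
  dimnames(Q) <- list(labels, labels)
  names(est) <- labels
  list(estimates = est, Q = Q, labels = labels,
       n_snps = if (options$max_overlap) n_used else n_used[1],
       n_blocks = m)
}

#' All three f4 permutations for a quartet
#'
#' Computes `f4(A,B;C,D)`, `f4(A,C;B,D)` and `f4(A,D;B,C)` on the
#' identical SNP set.  If all three are significantly non-zero
#' (|Z| above `z_threshold`), at least one of the four populations must be
#' admixed: no permutation of an unadmixed quartet tree yields three
#' non-zero expectations.
#'
#' @inheritParams compute_f4
#' @return A list of class `quartet_report` with elements `stats` (three
#'   `f_stat`s), `admixture_implied`, and `z_threshold`.
#' @export
quartet_report <- function(panel, A, B, C, D, options = estimator_options()) {
  pops <- c(A, B, C, D)
  check_pops(panel, pops)
  idx <- fstat_idx(panel, pops, options)
  perms <- list(c(A, B, C, D), c(A, C, B, D), c(A, D, B, C))
  stats <- lapply(perms, function(p) fstat_on_idx(panel, "f4", p, idx, options))
  zs <- vapply(stats, function(s) s$z, numeric(1))
  structure(list(stats = stats,
                 admixture_implied = all(!is.na(zs)) &&
                   all(abs(zs) > options$z_threshold),
                 z_threshold = options$z_threshold),
            class = "quartet_report")
}

#' @export
print.quartet_report <- function(x, ...) {
  for (s in x$stats) print(s)
  cat(sprintf("admixture implied (all |Z| > %g): %s\n", x$z_threshold,
              x$admixture_implied))
  invisible(x)
}
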