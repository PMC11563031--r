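#' Per-population allele-frequency panel
#'
#' A `freq_panel` holds, for a set of biallelic SNPs, the observed allele
#' frequency and the number of observed allele copies (2 x diploid
#' individuals with data) in each population, plus SNP metadata and a
#' jackknife block label per SNP.  Frequencies are stored for one arbitrary
#' (but consistent) allele per SNP; f-statistics are invariant to which
#' allele is tracked.
#'
#' A frequency is missing (`NA`) exactly where the corresponding count is
#' zero.  Block labels must form contiguous runs in genome (row) order, as
#' required by the leave-one-block-out jackknife.
#'
#' @param freq Numeric matrix (SNPs x populations) of allele frequencies in
#'   \[0, 1\], with unique column names giving the population labels.
#' @param count Numeric matrix, same shape, of observed allele counts per
#'   SNP and population (0 means missing; `Inf` marks exact population
#'   frequencies from the simulator's infinite-sample mode).
#' @param snp Optional data frame with columns `id`, `chrom`, `pos`
#'   (1-based physical position).  Defaults to synthetic ids on one
#'   chromosome.
#' @param block Optional vector of per-SNP block labels (contiguous runs).
#'   If omitted, call [assign_blocks()] before any jackknife-based analysis.
#' @return An object of class `freq_panel`.
#' @seealso [assign_blocks()], [read_eigenstrat()], [read_freq_table()]
#' @export
freq_panel <- function(freq, count, snp = NULL, block = NULL) {
  freq <- as.matrix(freq)
  count <- as.matrix(count)
  storage.mode(freq) <- "double"
  storage.mode(count) <- "double"
  if (!identical(dim(freq), dim(count)))
    stop("`freq` and `count` must have identical dimensions")
  pops <- colnames(freq)
  if (is.null(pops) || anyDuplicated(pops) || any(!nzchar(pops)))
    stop("`freq` must have unique, non-empty column names (population labels)")
  colnames(count) <- pops
  n <- nrow(freq)
  if (n < 1L) stop("panel must contain at least one SNP")
  if (any(count < 0, na.rm = TRUE)) stop("allele counts must be non-negative")
  freq[count == 0] <- NA_real_
  bad <- !is.na(freq) & (freq < 0 | freq > 1)
  if (any(bad)) stop("allele frequencies must lie in [0, 1]")
  if (any(is.na(freq) & count > 0))
    stop("frequency may be missing only where the count is zero")
  if (is.null(snp)) {
    snp <- data.frame(id = paste0("snp", seq_len(n)), chrom = 1L,
                      pos = seq_len(n), stringsAsFactors = FALSE)
  } else {
    snp <- as.data.frame(snp)
    if (!all(c("id", "chrom", "pos") %in% names(snp)))
      stop("`snp` needs columns id, chrom, pos")
    if (nrow(snp) != n) stop("`snp` must have one row per SNP")
    if (anyDuplicated(snp$id)) stop("duplicate SNP ids in `snp`")
  }
  if (!is.null(block)) {
    if (length(block) != n) stop("`block` must have one label per SNP")
    check_blocks_contiguous(block)
  }
  structure(list(freq = freq, count = count, snp = snp, block = block,
                 pops = pops),
            class = "freq_panel")
}

check_blocks_contiguous <- function(block) {
  r <- rle(as.character(block))
  if (anyDuplicated(r$values))
    stop("block labels must form contiguous runs in genome order")
  invisible(TRUE)
}

#' @export
print.freq_panel <- function(x, ...) {
  cat("freq_panel:", nrow(x$freq), "SNPs,", length(x$pops), "populations (",
      paste(x$pops, collapse = ", "), ")\n")
  if (is.null(x$block)) {
    cat("  blocks: not assigned\n")
  } else {
    cat("  blocks:", length(unique(x$block)), "\n")
  }
  invisible(x)
}

#' @export
dim.freq_panel <- function(x) dim(x$freq)

#' Assign jackknife blocks to a panel
#'
#' Blocks are contiguous along the genome.  The default policy cuts 5-Mb
#' windows by chromosome and physical position; when positions are absent
#' (all equal or missing) it falls back to fixed-size chunks of 500 SNPs.
#' Alternatively an exact number of equal-size contiguous blocks can be
#' requested (used by the simulator and in small examples).
#'
#' @param panel A [freq_panel()].
#' @param size Window size in base pairs for the positional policy.
#' @param chunk Chunk size in SNPs for the fallback policy.
#' @param n_blocks If given, cut exactly this many equal contiguous blocks
#'   instead.
#' @return The panel with its `block` field set.
#' @export
assign_blocks <- function(panel, size = 5e6, chunk = 500L, n_blocks = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  n <- nrow(panel$freq)
  if (!is.null(n_blocks)) {
    n_blocks <- as.integer(n_blocks)
    if (n_blocks < 1L || n_blocks > n)
      stop("`n_blocks` must be between 1 and the number of SNPs")
    block <- ceiling(seq_len(n) / (n / n_blocks))
  } else {
    pos <- panel$snp$pos
    chrom <- panel$snp$chrom
    if (is.null(pos) || all(is.na(pos)) || length(unique(pos)) == 1L) {
      block <- ceiling(seq_len(n) / chunk)
    } else {
      win <- floor((pos - 1) / size)
      block <- cumsum(c(1L, (chrom[-1] != chrom[-n]) | (win[-1] != win[-n])))
    }
  }
  panel$block <- as.integer(block)
  check_blocks_contiguous(panel$block)
  panel
}

#' Restrict a panel to a subset of SNPs and/or populations
#'
#' @param panel A [freq_panel()].
#' @param snps Integer or logical index of SNP rows to keep.
#' @param pops Character vector of population labels to keep.
#' @return A `freq_panel`.
#' @export
panel_subset <- function(panel, snps = NULL, pops = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  if (is.null(snps)) snps <- seq_len(nrow(panel$freq))
  if (is.null(pops)) pops <- panel$pops
  miss <- setdiff(pops, panel$pops)
  if (length(miss)) stop("unknown population(s): ", paste(miss, collapse = ", "))
  freq_panel(panel$freq[snps, pops, drop = FALSE],
             panel$count[snps, pops, drop = FALSE],
             snp = panel$snp[snps, , drop = FALSE],
             block = if (is.null(panel$block)) NULL else panel$block[snps])
}

check_pops <- function(panel, pops) {
  miss <- setdiff(pops, panel$pops)
  if (length(miss))
    stop("unknown population label(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# SNPs with data in every one of `pops` (complete-cases policy), optionally
# dropping sites monomorphic across those populations.
usable_snps <- function(panel, pops, polymorphic_only = FALSE) {
  check_pops(panel, pops)
  cnt <- panel$count[, unique(pops), drop = FALSE]
  ok <- rowSums(cnt > 0) == ncol(cnt)
  if (polymorphic_only) {
    fr <- panel$freq[, unique(pops), drop = FALSE]
    mono <- ok
    mono[ok] <- apply(fr[ok, , drop = FALSE], 1L, function(p) {
      all(p == p[1L]) && (p[1L] == 0 || p[1L] == 1)
    })
    ok <- ok & !mono
  }
  which(ok)
}
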