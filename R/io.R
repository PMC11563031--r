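#' Read an EIGENSTRAT genotype trio into a frequency panel
#'
#' Reads the geno/snp/ind file triple: one genotype character per
#' individual per SNP line (0/1/2 copies of the first listed allele, 9 =
#' missing), SNP metadata (id, chromosome, genetic position, physical
#' position, optional alleles), and individual metadata (id, sex,
#' population label).  Individuals are pooled into populations by label,
#' in first-appearance order; per SNP and population the frequency is the
#' pooled allele frequency and the count is twice the number of
#' individuals with data.
#'
#' @param geno,snp,ind File paths; alternatively give `prefix` and the
#'   three paths default to `<prefix>.geno` etc.
#' @param prefix Common path prefix.
#' @param blocks Block policy applied after reading: `"5mb"` (default),
#'   `"chunk"` (500-SNP chunks), or a number of equal blocks.
#' @return A [freq_panel()].
#' @export
read_eigenstrat <- function(prefix = NULL, geno = NULL, snp = NULL,
                            ind = NULL, blocks = "5mb") {
  if (!is.null(prefix)) {
    if (is.null(geno)) geno <- paste0(prefix, ".geno")
    if (is.null(snp)) snp <- paste0(prefix, ".snp")
    if (is.null(ind)) ind <- paste0(prefix, ".ind")
  }
  ind_lines <- readLines(ind)
  ind_tok <- strsplit(trimws(ind_lines), "[ \t]+")
  bad <- which(lengths(ind_tok) < 3L & nzchar(trimws(ind_lines)))
  if (length(bad))
    stop(ind, " line ", bad[1], ": expected 'id sex population'")
  ind_tok <- ind_tok[nzchar(trimws(ind_lines))]
  ids <- vapply(ind_tok, `[`, character(1), 1L)
  pop_of <- vapply(ind_tok, `[`, character(1), 3L)
  pops <- unique(pop_of)

  snp_lines <- readLines(snp)
  snp_tok <- strsplit(trimws(snp_lines), "[ \t]+")
  keep <- nzchar(trimws(snp_lines))
  snp_tok <- snp_tok[keep]
  bad <- which(lengths(snp_tok) < 4L)
  if (length(bad))
    stop(snp, " line ", bad[1],
         ": expected 'id chrom genetic_pos physical_pos [alleles]'")
  snp_df <- data.frame(
    id = vapply(snp_tok, `[`, character(1), 1L),
    chrom = vapply(snp_tok, `[`, character(1), 2L),
    pos = as.numeric(vapply(snp_tok, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  dupi <- which(duplicated(snp_df$id))
  if (length(dupi))
    stop(snp, " line ", dupi[1], ": duplicate SNP id '", snp_df$id[dupi[1]],
         "'")

  geno_lines <- readLines(geno)
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) != nrow(snp_df))
    stop(geno, ": ", length(geno_lines), " genotype lines but ",
         nrow(snp_df), " SNPs in ", snp)
  widths <- nchar(geno_lines)
  bad <- which(widths != length(ids))
  if (length(bad))
    stop(geno, " line ", bad[1], ": ", widths[bad[1]],
         " genotype characters for ", length(ids), " individuals")
  n <- length(geno_lines)
  G <- matrix(0L, n, length(ids))
  allowed <- c("0", "1", "2", "9")
  for (j in seq_along(ids)) {
    cj <- substr(geno_lines, j, j)
    badc <- which(!(cj %in% allowed))
    if (length(badc))
      stop(geno, " line ", badc[1], ": unknown genotype character '",
           cj[badc[1]], "'")
    G[, j] <- as.integer(cj)
  }
  G[G == 9L] <- NA_integer_
  fr <- matrix(NA_real_, n, length(pops), dimnames = list(NULL, pops))
  ct <- matrix(0, n, length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    sub <- G[, pop_of == p, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    ct[, p] <- 2 * nn
    fr[, p] <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / (2 * nn), NA)
  }
  panel <- freq_panel(fr, ct, snp = snp_df)
  apply_block_policy(panel, blocks)
}

apply_block_policy <- function(panel, blocks) {
  if (is.numeric(blocks)) return(assign_blocks(panel, n_blocks = blocks))
  if (tolower(as.character(blocks)) == "5mb") return(assign_blocks(panel))
  if (tolower(as.character(blocks)) == "chunk") {
    panel$block <- as.integer(ceiling(seq_len(nrow(panel$freq)) / 500))
    return(panel)
  }
  stop("unknown block policy '", blocks, "'")
}

#' Write a frequency panel as an EIGENSTRAT trio
#'
#' Emits synthetic diploid individuals per population whose pooled
#' genotypes reproduce the panel's frequencies and counts exactly
#' (genotype 9 fills in missing data).  Panels with infinite counts
#' (exact frequencies) cannot be written.
#'
#' @param panel A [freq_panel()].
#' @param prefix Output path prefix (`<prefix>.geno/.snp/.ind`).
#' @return Invisibly, the three file paths.
#' @export
write_eigenstrat <- function(panel, prefix) {
  ct <- panel$count
  if (any(is.infinite(ct)))
    stop("panel has infinite counts (exact frequencies); cannot write ",
         "genotypes")
  if (any(ct %% 2 != 0))
    stop("allele counts must be even (diploid) to write EIGENSTRAT")
  n_ind <- apply(ct, 2L, max) / 2
  ind_lines <- character(0)
  for (p in panel$pops)
    ind_lines <- c(ind_lines,
                   sprintf("%s_%d\tU\t%s", p, seq_len(n_ind[p]), p))
  k <- round(panel$freq * ct)
  k[is.na(k)] <- 0
  geno_lines <- vapply(seq_len(nrow(ct)), function(i) {
    row <- character(0)
    for (p in panel$pops) {
      m <- ct[i, p] / 2
      ki <- k[i, p]
      gs <- c(rep(2L, ki %/% 2L), rep(1L, ki %% 2L))
      gs <- c(gs, rep(0L, m - length(gs)))
      gs <- c(gs, rep(9L, n_ind[p] - m))
      row <- c(row, gs)
    }
    paste(row, collapse = "")
  }, character(1))
  snp_lines <- sprintf("%s\t%s\t0.0\t%d\tA\tC", panel$snp$id,
                       panel$snp$chrom, as.integer(panel$snp$pos))
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  writeLines(geno_lines, paths[1])
  writeLines(snp_lines, paths[2])
  writeLines(ind_lines, paths[3])
  invisible(paths)
}

#' Read/write per-population frequency tables
#'
#' Tab-separated text with columns `snp_id`, `chrom`, `pos`, optional
#' `block`, then `<pop>_freq` and `<pop>_count` per population.  Values
#' round-trip through [write_freq_table()] at full double precision.
#'
#' @param path File path.
#' @return A [freq_panel()] (blocks set if a `block` column is present).
#' @export
read_freq_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop(path, ": frequency table needs columns snp_id, chrom, pos")
  fcols <- grep("_freq$", names(tab), value = TRUE)
  pops <- sub("_freq$", "", fcols)
  if (!length(pops)) stop(path, ": no <pop>_freq columns found")
  miss <- setdiff(paste0(pops, "_count"), names(tab))
  if (length(miss))
    stop(path, ": missing count column(s): ", paste(miss, collapse = ", "))
  fr <- as.matrix(tab[, paste0(pops, "_freq"), drop = FALSE])
  ct <- as.matrix(tab[, paste0(pops, "_count"), drop = FALSE])
  colnames(fr) <- colnames(ct) <- pops
  freq_panel(fr, ct,
             snp = data.frame(id = tab$snp_id, chrom = tab$chrom,
                              pos = tab$pos, stringsAsFactors = FALSE),
             block = tab$block)
}

#' @rdname read_freq_table
#' @param panel A [freq_panel()] (blocks should be assigned).
#' @export
write_freq_table <- function(panel, path) {
  out <- data.frame(snp_id = panel$snp$id, chrom = panel$snp$chrom,
                    pos = panel$snp$pos, stringsAsFactors = FALSE)
  if (!is.null(panel$block)) out$block <- panel$block
  for (p in panel$pops) {
    out[[paste0(p, "_freq")]] <- fmt_num(panel$freq[, p])
    out[[paste0(p, "_count")]] <- fmt_num(panel$count[, p])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- NA
  trimws(out)
}

#' Write analysis results to files
#'
#' Deterministic writers used by the command-line interface:
#' \itemize{
#'   \item `f_stat` / `quartet_report`: a TSV row per statistic.
#'   \item `admix_fit`: `<prefix>_graph.txt` (fitted graph),
#'     `<prefix>_graph.dot`, `<prefix>_residuals.tsv` (basis residuals,
#'     |Z| descending), `<prefix>_fit.json` (score, parameters,
#'     identifiability, configuration echo).
#'   \item `residual_table`: a TSV sorted by |Z| descending.
#' }
#'
#' @param x A result object.
#' @param prefix Output path prefix.
#' @param config Optional configuration list echoed into JSON output.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, prefix, config = NULL) {
  UseMethod("write_results")
}

#' @export
write_results.f_stat <- function(x, prefix, config = NULL) {
  path <- paste0(prefix, "_stats.tsv")
  write_stats_tsv(list(x), path)
  invisible(path)
}

#' @export
write_results.quartet_report <- function(x, prefix, config = NULL) {
  path <- paste0(prefix, "_stats.tsv")
  write_stats_tsv(x$stats, path)
  invisible(path)
}

write_stats_tsv <- function(stats, path) {
  tab <- do.call(rbind, lapply(stats, as.data.frame))
  tab$value <- fmt_num(tab$value)
  tab$se <- fmt_num(tab$se)
  tab$z <- fmt_num(tab$z)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
write_results.residual_table <- function(x, prefix, config = NULL) {
  path <- paste0(prefix, "_residuals.tsv")
  tab <- as.data.frame(x)
  for (cn in c("observed", "predicted", "se", "z"))
    tab[[cn]] <- fmt_num(tab[[cn]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
write_results.admix_fit <- function(x, prefix, config = NULL) {
  paths <- c(graph = paste0(prefix, "_graph.txt"),
             dot = paste0(prefix, "_graph.dot"),
             residuals = paste0(prefix, "_residuals.tsv"),
             json = paste0(prefix, "_fit.json"))
  writeLines(serialize_graph(x$graph, "text"), paths["graph"])
  writeLines(serialize_graph(x$graph, "dot"), paths["dot"])
  tab <- x$residuals[order(-abs(x$residuals$z), x$residuals$statistic), ]
  for (cn in c("observed", "predicted", "se", "z"))
    tab[[cn]] <- fmt_num(tab[[cn]])
  utils::write.table(tab, paths["residuals"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  summary <- list(
    score = x$score,
    lsq = x$lsq,
    converged = x$converged,
    n_restarts_used = x$n_restarts_used,
    parameters = list(
      lengths = setNames(as.list(x$graph$edges$length), x$graph$edges$name),
      alpha = if (nrow(x$graph$admix))
        setNames(as.list(x$graph$admix$alpha), x$graph$admix$child)
      else NULL),
    identifiability = list(
      rank = x$identifiability$rank,
      n_params = x$identifiability$n_params,
      n_free_theoretical = x$identifiability$n_free_theoretical,
      underdetermined = x$identifiability$underdetermined,
      compound = as.list(x$identifiability$compound)),
    basis = x$basis_info[c("base_pop", "pops", "n_snps", "n_blocks")],
    config = config,
    package_version = as.character(utils::packageVersion("admixkit")))
  jsonlite::write_json(summary, paths["json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
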