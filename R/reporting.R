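#' Bonferroni significance threshold at printed precision
#'
#' `alpha / m`, rounded to `sig_figs` significant figures — the form in
#' which family-wise thresholds are quoted in results tables (e.g.
#' `0.05 / 9886 = 5.06e-6` at three significant figures).
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @param sig_figs Significant figures for display (default 2).
#' @return Rounded threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m, sig_figs = 2) {
  stopifnot(alpha > 0, alpha < 1, m >= 1, sig_figs >= 1)
  signif(alpha / m, sig_figs)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of a query gene list against named gene
#' sets over a background universe (equivalent to one-sided Fisher's exact
#' test on the 2x2 overlap table).  Sets are intersected with the
#' background before testing; query genes outside the background are
#' dropped with a warning.
#'
#' @param query Character vector of query genes.
#' @param sets Named list of gene sets.
#' @param background Character vector: the gene universe.
#' @param adjust Multiple-testing adjustment across sets: `"BH"` (default)
#'   or `"bonferroni"`.
#' @return data.frame (class `enrichment_result`) with columns `set_id,
#'   k_overlap, K_set, n_query, N_background, p, p_adjusted,
#'   overlap_genes` (comma-separated), ordered by `p`.
#' @export
hypergeometric_enrichment <- function(query, sets, background,
                                      adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  background <- unique(background)
  if (length(background) == 0L) stop("empty background gene universe")
  drop <- setdiff(query, background)
  if (length(drop))
    warning(length(drop), " query genes outside the background were dropped")
  query <- unique(intersect(query, background))
  N <- length(background); n <- length(query)
  res <- lapply(names(sets), function(id) {
    set <- intersect(unique(sets[[id]]), background)
    ov <- intersect(query, set)
    k <- length(ov); K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k_overlap = k, K_set = K, n_query = n,
               N_background = N, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out <- out[order(out$p, out$set_id),
             c("set_id", "k_overlap", "K_set", "n_query", "N_background",
               "p", "p_adjusted", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Read gene sets in two-column long format
#'
#' `set-name <TAB> gene`, one membership per line, header optional.
#'
#' @param path Delimited file.
#' @return Named list of gene character vectors.
#' @export
read_gene_sets <- function(path) {
  d <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (tolower(d[1, 1]) %in% c("set", "set_id", "setname"))
    d <- d[-1, , drop = FALSE]
  split(as.character(d[[2]]), as.character(d[[1]]))
}

#' Format a variant count on the "K" (thousands) scale
#'
#' @param n Count in variants.
#' @param digits Decimal places (default 2), giving the "0.21K" style.
#' @return Character scalar.
#' @export
format_kcount <- function(n, digits = 2) {
  sprintf(paste0("%.", digits, "fK"), n / 1000)
}

#' Write the lower triangle of all pairwise genetic correlations
#'
#' One row per unordered trait pair (`C(T, 2)` rows) with the estimate,
#' standard error and two-sided p-value, as a tab-delimited table.
#'
#' @param fits Named list of `ldsc_rg` fits; names like `"t1:t2"` give the
#'   pair labels (any separator containing `:`).
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_rg_table <- function(fits, path) {
  rows <- lapply(names(fits), function(nm) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    f <- fits[[nm]]
    data.frame(trait1 = pair[1], trait2 = pair[2],
               rg = signif(f$rg, 6), rg_se = signif(f$rg_se, 6),
               p = signif(f$p, 6), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Write a polygenic-overlap (Venn) table
#'
#' Emits the unique/shared effective-variant counts in "K" formatting with
#' standard errors and the mixture-implied genetic correlation.
#'
#' @param summaries Named list of [overlap_summary()] results (names are
#'   `"t1:t2"` pair labels).
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_overlap_table <- function(summaries, path) {
  rows <- lapply(names(summaries), function(nm) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    s <- summaries[[nm]]
    data.frame(trait1 = pair[1], trait2 = pair[2],
               unique1 = format_kcount(s$unique_1),
               shared = format_kcount(s$n_shared),
               shared_se = ifelse(is.na(s$se_shared), "NA",
                                  format_kcount(s$se_shared)),
               unique2 = format_kcount(s$unique_2),
               shared_raw = format_kcount(s$n_shared_raw),
               rg_mixer = signif(s$rg_mixer, 4),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Write a gene-scan results table
#'
#' Tab-delimited per-gene table: multi-trait p, per-trait p, replicate
#' count and the pleiotropic/novel flags.
#'
#' @param scan A `gene_scan` result.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_gene_scan <- function(scan, path) {
  tab <- scan$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) signif(v, 6))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
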