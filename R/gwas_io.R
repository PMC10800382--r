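#' Read GWAS summary statistics
#'
#' Reads a tab/whitespace-delimited summary-statistics file into a validated
#' `sumstats` object.  Column names are resolved through `dialect`, a named
#' character vector mapping canonical names (`snp`, `chr`, `bp`, `a1`, `a2`,
#' `z`, `beta`, `se`, `n`, `p`, `freq`) to the names used in the file.  A `z`
#' column is used directly; otherwise `z = beta / se` is computed from
#' `beta`/`se` columns.
#'
#' Rows are validated against the per-SNP record contract: finite `z`,
#' `a1 != a2`, positive `n`, and (when a p-value column is present) agreement
#' of `p` with the two-sided normal tail of `|z|` to within `p_tol`.  Failing
#' rows are dropped and counted in the audit attached to the result; records
#' are sorted by `(chr, bp)` and duplicate SNP ids are dropped (first kept).
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector mapping canonical column names to
#'   file column names.  Defaults cover the conventional
#'   `SNP CHR BP A1 A2 Z N P` layout.
#' @param trait_id Trait label; defaults to the file name without extension.
#' @param p_tol Maximum tolerated discrepancy between a supplied p-value and
#'   the two-sided normal tail implied by `z` (default `1e-4`).
#' @return A `sumstats` object: list with `trait_id`, `data` (data.frame with
#'   columns `snp, chr, bp, a1, a2, z, n, p` and optionally `freq`) and
#'   `audit` (named integer vector of dropped-row counts by reason).
#' @export
read_sumstats <- function(path, dialect = NULL, trait_id = NULL, p_tol = 1e-4) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  dl <- default_dialect()
  if (!is.null(dialect)) dl[names(dialect)] <- dialect
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  cols <- names(dt)
  get_col <- function(canon) {
    nm <- dl[[canon]]
    if (!is.null(nm) && nm %in% cols) dt[[nm]] else NULL
  }
  for (canon in c("snp", "chr", "bp", "a1", "a2", "n")) {
    nm <- dl[[canon]]
    if (is.null(nm) || !nm %in% cols)
      stop("mandatory column missing from ", path, ": ", canon,
           " (expected file column '", nm, "')")
  }
  z <- get_col("z")
  if (is.null(z)) {
    beta <- get_col("beta"); se <- get_col("se")
    if (is.null(beta) || is.null(se))
      stop("mandatory column missing from ", path,
           ": z (and no beta/se pair to derive it)")
    z <- beta / se
  }
  d <- data.frame(
    snp = as.character(get_col("snp")),
    chr = as.character(get_col("chr")),
    bp  = as.integer(get_col("bp")),
    a1  = toupper(as.character(get_col("a1"))),
    a2  = toupper(as.character(get_col("a2"))),
    z   = as.numeric(z),
    n   = as.numeric(get_col("n")),
    stringsAsFactors = FALSE
  )
  p <- get_col("p")
  d$p <- if (is.null(p)) 2 * stats::pnorm(-abs(d$z)) else as.numeric(p)
  fr <- get_col("freq")
  if (!is.null(fr)) d$freq <- as.numeric(fr)

  audit <- c(nonfinite_z = 0L, same_alleles = 0L, bad_n = 0L,
             p_inconsistent = 0L, duplicate_id = 0L)
  bad <- !is.finite(d$z)
  audit["nonfinite_z"] <- sum(bad)
  same <- !bad & d$a1 == d$a2
  audit["same_alleles"] <- sum(same); bad <- bad | same
  badn <- !bad & (!is.finite(d$n) | d$n <= 0)
  audit["bad_n"] <- sum(badn); bad <- bad | badn
  if (!is.null(p)) {
    pref <- 2 * stats::pnorm(-abs(d$z))
    pb <- !bad & (!is.finite(d$p) | abs(d$p - pref) > p_tol)
    audit["p_inconsistent"] <- sum(pb); bad <- bad | pb
  }
  d <- d[!bad, , drop = FALSE]
  d <- d[order(d$chr, d$bp, d$snp), , drop = FALSE]
  dup <- duplicated(d$snp)
  audit["duplicate_id"] <- sum(dup)
  d <- d[!dup, , drop = FALSE]
  rownames(d) <- NULL
  if (nrow(d) == 0L) stop("no valid rows in ", path)
  new_sumstats(trait_id, d, audit)
}

default_dialect <- function() {
  list(snp = "SNP", chr = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
       z = "Z", beta = "BETA", se = "SE", n = "N", p = "P", freq = "FREQ")
}

new_sumstats <- function(trait_id, data, audit = integer()) {
  structure(list(trait_id = trait_id, data = data, audit = audit),
            class = "sumstats")
}

#' Construct a sumstats object in memory
#'
#' @param trait_id Trait label.
#' @param snp,chr,bp,a1,a2,z,n Per-SNP fields (vectors of equal length).
#' @param p Optional p-values; computed from `z` when omitted.
#' @return A `sumstats` object.
#' @export
sumstats <- function(trait_id, snp, chr, bp, a1, a2, z, n, p = NULL) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  d <- data.frame(snp = as.character(snp), chr = as.character(chr),
                  bp = as.integer(bp), a1 = toupper(a1), a2 = toupper(a2),
                  z = z, n = n, p = p, stringsAsFactors = FALSE)
  d <- d[order(d$chr, d$bp, d$snp), , drop = FALSE]
  if (anyDuplicated(d$snp)) stop("duplicate SNP ids")
  rownames(d) <- NULL
  new_sumstats(trait_id, d)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for trait '", x$trait_id, "': ",
      nrow(x$data), " SNPs, median N = ",
      stats::median(x$data$n), "\n", sep = "")
  dropped <- sum(x$audit)
  if (length(x$audit) && dropped > 0)
    cat("  dropped during ingestion:", dropped, "rows\n")
  invisible(x)
}

#' Write summary statistics in the canonical column order
#'
#' Emits `SNP CHR BP A1 A2 Z N P` as a tab-delimited file.
#'
#' @param x A `sumstats` object.
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  d <- x$data
  out <- data.frame(SNP = d$snp, CHR = d$chr, BP = d$bp, A1 = d$a1,
                    A2 = d$a2, Z = signif(d$z, 10), N = d$n,
                    P = signif(d$p, 10))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reference genotype panel
#'
#' @param dosages sample x SNP matrix of allele counts in 0/1/2 (NA for
#'   missing).
#' @param meta data.frame with columns `snp, chr, bp, a1, a2` describing the
#'   SNP columns.
#' @param drop_monomorphic Drop SNPs with zero variance after removing
#'   missing values (default TRUE; they cannot enter a correlation).
#' @return A `geno_panel` object with an `audit` count of dropped columns.
#' @export
geno_panel <- function(dosages, meta, drop_monomorphic = TRUE) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(meta))
    stop("dosage column count does not match SNP metadata rows")
  v <- apply(dosages, 2, function(col) stats::var(col[!is.na(col)]))
  mono <- !is.finite(v) | v <= 0
  audit <- c(monomorphic = sum(mono))
  if (any(mono)) {
    if (!drop_monomorphic) stop(sum(mono), " monomorphic SNP columns in panel")
    dosages <- dosages[, !mono, drop = FALSE]
    meta <- meta[!mono, , drop = FALSE]
  }
  rownames(meta) <- NULL
  structure(list(dosages = dosages, meta = meta,
                 n_samples = nrow(dosages), audit = audit),
            class = "geno_panel")
}

#' Read a reference panel from a dosage matrix plus SNP metadata sidecar
#'
#' @param dosage_path Delimited sample x SNP matrix of allele counts (no
#'   header); missing values may be `NA` or `missing_code`.
#' @param meta_path Delimited table with header `snp chr bp a1 a2`.
#' @param missing_code Numeric sentinel treated as missing (default -9).
#' @return A `geno_panel`.
#' @export
read_panel <- function(dosage_path, meta_path, missing_code = -9) {
  g <- as.matrix(data.table::fread(dosage_path, header = FALSE,
                                   data.table = FALSE))
  g[g == missing_code] <- NA
  meta <- data.table::fread(meta_path, header = TRUE, data.table = FALSE)
  names(meta) <- tolower(names(meta))
  meta$a1 <- toupper(meta$a1); meta$a2 <- toupper(meta$a2)
  meta$snp <- as.character(meta$snp); meta$chr <- as.character(meta$chr)
  geno_panel(g, meta)
}

#' Read gene models from an interval table
#'
#' Coordinates are 1-based inclusive throughout the package.  `format =
#' "bed"` converts standard 0-based half-open BED intervals on input.
#'
#' @param path 4+ column table: chrom, start, end, gene id, optional strand.
#'   A header line is detected automatically.
#' @param format `"onebased"` (default) or `"bed"`.
#' @return data.frame with columns `gene_id, chr, start, end, strand`.
#' @export
read_gene_models <- function(path, format = c("onebased", "bed")) {
  format <- match.arg(format)
  first <- strsplit(readLines(path, n = 1), "[\t ]+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2])))
  d <- data.table::fread(path, header = has_header, data.table = FALSE)
  g <- data.frame(gene_id = as.character(d[[4]]), chr = as.character(d[[1]]),
                  start = as.integer(d[[2]]), end = as.integer(d[[3]]),
                  strand = if (ncol(d) >= 5) as.character(d[[5]]) else "unknown",
                  stringsAsFactors = FALSE)
  if (format == "bed") g$start <- g$start + 1L
  if (any(g$start > g$end)) stop("gene model with start > end")
  g
}

#' Read a binary SNP annotation matrix
#'
#' One row per SNP, one column per category, header required.  An optional
#' leading `SNP` id column is used as row names.
#'
#' @param path Delimited file.
#' @return Numeric 0/1 matrix, SNP ids as rownames when present.
#' @export
read_annotations <- function(path) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  rn <- NULL
  if (tolower(names(d)[1]) %in% c("snp", "id")) {
    rn <- as.character(d[[1]]); d <- d[, -1, drop = FALSE]
  }
  m <- as.matrix(d)
  if (!all(m %in% c(0, 1))) stop("annotation matrix must be binary 0/1")
  rownames(m) <- rn
  m
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  !is.na(COMPLEMENT[a1]) & COMPLEMENT[a1] == a2
}

#' Harmonize several traits' summary statistics against a reference panel
#'
#' Restricts to SNPs present in every trait and in the panel, aligns each
#' trait's effect allele to the panel's (flipping the sign of `z` where
#' `a1`/`a2` are swapped, with or without a strand complement), removes
#' strand-ambiguous palindromic SNPs (A/T, C/G) outright, and removes SNPs
#' whose alleles cannot be reconciled with the panel in any trait.
#'
#' @param traits List of `sumstats` objects.
#' @param panel A `geno_panel` (or a data.frame with `snp, chr, bp, a1, a2`
#'   acting as the allele reference).
#' @return List with `z` (traits x SNPs matrix, rownames = trait ids,
#'   colnames = SNP ids), `n` (matching matrix of sample sizes), `snps`
#'   (data.frame of the harmonized universe: `snp, chr, bp, a1, a2`), and
#'   `audit` (data.frame `snp, disposition` over all candidate SNPs with
#'   dispositions `kept`, `palindromic`, `allele_mismatch`).
#' @export
harmonize <- function(traits, panel) {
  if (length(traits) < 1) stop("need at least one trait")
  meta <- if (inherits(panel, "geno_panel")) panel$meta else panel
  ids <- meta$snp
  for (tr in traits) ids <- intersect(ids, tr$data$snp)
  if (length(ids) == 0L) stop("no SNPs shared by all traits and the panel")
  ref <- meta[match(ids, meta$snp), , drop = FALSE]

  disposition <- rep("kept", length(ids))
  pal <- is_palindromic(ref$a1, ref$a2)
  disposition[pal] <- "palindromic"

  m <- length(traits)
  z <- matrix(NA_real_, m, length(ids))
  nmat <- matrix(NA_real_, m, length(ids))
  for (t in seq_len(m)) {
    d <- traits[[t]]$data[match(ids, traits[[t]]$data$snp), , drop = FALSE]
    same  <- d$a1 == ref$a1 & d$a2 == ref$a2
    swap  <- d$a1 == ref$a2 & d$a2 == ref$a1
    csame <- COMPLEMENT[d$a1] == ref$a1 & COMPLEMENT[d$a2] == ref$a2
    cswap <- COMPLEMENT[d$a1] == ref$a2 & COMPLEMENT[d$a2] == ref$a1
    csame[is.na(csame)] <- FALSE; cswap[is.na(cswap)] <- FALSE
    sgn <- ifelse(same | csame, 1, ifelse(swap | cswap, -1, NA))
    disposition[is.na(sgn) & disposition == "kept"] <- "allele_mismatch"
    z[t, ] <- d$z * sgn
    nmat[t, ] <- d$n
  }
  keep <- disposition == "kept"
  audit <- data.frame(snp = ids, disposition = disposition,
                      stringsAsFactors = FALSE)
  if (!any(keep)) stop("no SNPs survived allele harmonization")
  ord <- order(ref$chr[keep], ref$bp[keep])
  kept_idx <- which(keep)[ord]
  z <- z[, kept_idx, drop = FALSE]
  nmat <- nmat[, kept_idx, drop = FALSE]
  snps <- ref[kept_idx, c("snp", "chr", "bp", "a1", "a2")]
  rownames(snps) <- NULL
  rownames(z) <- rownames(nmat) <- vapply(traits, `[[`, "", "trait_id")
  colnames(z) <- colnames(nmat) <- snps$snp
  list(z = z, n = nmat, snps = snps, audit = audit)
}

#' Map SNPs to genes by position
#'
#' A SNP is assigned to every gene whose (flank-extended) interval contains
#' it; boundaries are inclusive.  Genes with no SNPs are omitted.
#'
#' @param snps data.frame with `snp, chr, bp` (ordered; e.g. the `snps`
#'   element returned by [harmonize()]).
#' @param genes data.frame of gene models (`gene_id, chr, start, end`).
#' @param flank_bp Flank added to both gene ends (default 0).
#' @return Named list mapping gene id to the integer indices of its SNPs in
#'   `snps`, sorted by position.
#' @export
map_snps_to_genes <- function(snps, genes, flank_bp = 0) {
  stopifnot(flank_bp >= 0)
  out <- list()
  for (g in seq_len(nrow(genes))) {
    idx <- which(snps$chr == genes$chr[g] &
                 snps$bp >= genes$start[g] - flank_bp &
                 snps$bp <= genes$end[g] + flank_bp)
    if (length(idx)) out[[genes$gene_id[g]]] <- idx[order(snps$bp[idx])]
  }
  out
}
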