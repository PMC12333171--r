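# The five supernatant conditions of the secretome design, in canonical order.
NPX_CONDITIONS <- c("Medium", "PBMC", "rMSC", "Coculture", "D3cMSC")

# Absolute tolerance for threshold comparisons on NPX values.
NPX_EPS <- 1e-9

#' Construct an NPX matrix
#'
#' Container for a protein x sample table of Olink-style NPX values
#' (log2-scale arbitrary units) together with the sample -> condition design.
#' Missing values (including values removed by LOD filtering) are stored as
#' `NA` and are never consumed numerically downstream.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; both
#'   dimnames must be set and unique.
#' @param design named character vector mapping every sample (column) to one
#'   of the five conditions `Medium`, `PBMC`, `rMSC`, `Coculture`, `D3cMSC`.
#' @return an object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and sample colnames")
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p))
    stop("duplicate protein ids: ", paste(dup_p, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  design <- unlist(design)
  missing_design <- setdiff(colnames(values), names(design))
  if (length(missing_design))
    stop("samples without a condition in the design: ",
         paste(missing_design, collapse = ", "))
  design <- design[colnames(values)]
  bad <- setdiff(unique(design), NPX_CONDITIONS)
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "),
         " (expected ", paste(NPX_CONDITIONS, collapse = ", "), ")")
  structure(list(values = values, design = design),
            class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat("NPX matrix:", nrow(x$values), "proteins x", ncol(x$values), "samples\n")
  tab <- table(factor(x$design, levels = NPX_CONDITIONS))
  cat("Samples per condition:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("Missing cells:", sum(is.na(x$values)), "\n")
  removed <- attr(x, "removed_proteins")
  if (!is.null(removed) && length(removed))
    cat("Proteins removed by missingness filter:", length(removed), "\n")
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

# Parse numbers that may use a decimal comma (as printed in the source table).
parse_decimal <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  as.numeric(sub(",", ".", x, fixed = TRUE))
}

read_design_csv <- function(design_path) {
  d <- utils::read.csv(design_path, stringsAsFactors = FALSE,
                       check.names = FALSE)
  need <- c("sample", "condition")
  if (!all(need %in% names(d)))
    stop("design file must have columns 'sample' and 'condition'")
  stats::setNames(as.character(d$condition), as.character(d$sample))
}

#' Read an NPX table from CSV
#'
#' Reads a wide (first column `protein`, one column per sample) or long
#' (columns `sample`, `protein`, `npx`, optional `lod`) CSV of NPX values
#' plus a `sample,condition` design CSV, and returns a validated
#' [npx_matrix()]. Decimal commas are converted to dots.
#'
#' @param path path to the NPX CSV.
#' @param layout `"wide"` or `"long"`.
#' @param design_path path to the design CSV with columns `sample,condition`.
#' @return an `npx_matrix`; for long input with an `lod` column, the per
#'   protein LOD table is attached as attribute `"lod"`.
#' @export
read_npx_table <- function(path, layout = c("wide", "long"), design_path) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  design <- read_design_csv(design_path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (layout == "wide") {
    if (names(raw)[1] != "protein")
      stop("wide layout requires first column 'protein'")
    proteins <- raw$protein
    vals <- vapply(raw[-1], parse_decimal, numeric(nrow(raw)))
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(proteins, names(raw)[-1]))
    m <- npx_matrix(vals, design)
  } else {
    need <- c("sample", "protein", "npx")
    if (!all(need %in% names(raw)))
      stop("long layout requires columns 'sample', 'protein', 'npx'")
    raw$npx <- parse_decimal(raw$npx)
    key <- paste(raw$protein, raw$sample, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (protein, sample) rows: ",
           paste(unique(gsub("\r", "/", key[duplicated(key)])),
                 collapse = ", "))
    proteins <- unique(raw$protein)
    samples <- unique(raw$sample)
    vals <- matrix(NA_real_, length(proteins), length(samples),
                   dimnames = list(proteins, samples))
    vals[cbind(match(raw$protein, proteins), match(raw$sample, samples))] <-
      raw$npx
    m <- npx_matrix(vals, design)
    if ("lod" %in% names(raw)) {
      raw$lod <- parse_decimal(raw$lod)
      lod <- tapply(raw$lod, raw$protein, function(v) {
        v <- unique(v[!is.na(v)])
        if (length(v) > 1) stop("conflicting LOD entries for a protein")
        if (length(v)) v else NA_real_
      })
      attr(m, "lod") <- lod[!is.na(lod)]
    }
  }
  m
}

#' Remove below-LOD values
#'
#' Sets every cell strictly below its protein's limit of detection to
#' missing. Values equal to the LOD are retained; proteins without an LOD
#' entry pass through unchanged. No rows or columns are dropped.
#'
#' @param matrix an [npx_matrix()].
#' @param lod named numeric vector, protein -> LOD (log2 NPX units).
#' @return the filtered `npx_matrix`.
#' @export
apply_lod_filter <- function(matrix, lod) {
  stopifnot(inherits(matrix, "npx_matrix"))
  lod <- unlist(lod)
  common <- intersect(rownames(matrix$values), names(lod))
  for (p in common) {
    below <- !is.na(matrix$values[p, ]) &
      matrix$values[p, ] < lod[[p]] - NPX_EPS
    matrix$values[p, below] <- NA_real_
  }
  matrix
}

#' Exclude proteins with excessive missingness
#'
#' Removes proteins whose missing fraction (over all samples, after LOD
#' filtering) is strictly greater than `max_missing_frac`. The removed
#' protein ids are reported in the `"removed_proteins"` attribute of the
#' result.
#'
#' @param matrix an [npx_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction (default 0.5,
#'   i.e. proteins with > 50\% missing values are excluded).
#' @return the filtered `npx_matrix`.
#' @export
filter_missingness <- function(matrix, max_missing_frac = 0.5) {
  stopifnot(inherits(matrix, "npx_matrix"))
  frac <- rowMeans(is.na(matrix$values))
  drop <- frac > max_missing_frac + NPX_EPS
  removed <- rownames(matrix$values)[drop]
  matrix$values <- matrix$values[!drop, , drop = FALSE]
  if (nrow(matrix$values) == 0L)
    warning("no proteins remain after missingness filtering")
  attr(matrix, "removed_proteins") <- removed
  matrix
}

#' Per-condition mean profiles
#'
#' Computes, for every protein, the mean NPX over non-missing cells in each
#' of the five conditions. A profile lacking any condition mean (all cells
#' missing, or no sample in that condition) is flagged unclassifiable.
#'
#' @param matrix an [npx_matrix()].
#' @return data frame with columns `protein`, `med`, `pbmc`, `rmsc`, `coc`,
#'   `d3`, per-condition non-missing counts `n_med` .. `n_d3`, and
#'   `classifiable`.
#' @export
condition_means <- function(matrix) {
  stopifnot(inherits(matrix, "npx_matrix"))
  cond <- factor(matrix$design, levels = NPX_CONDITIONS)
  short <- c(Medium = "med", PBMC = "pbmc", rMSC = "rmsc",
             Coculture = "coc", D3cMSC = "d3")
  out <- data.frame(protein = rownames(matrix$values),
                    stringsAsFactors = FALSE)
  for (cn in NPX_CONDITIONS) {
    cols <- which(cond == cn)
    sub <- matrix$values[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- ifelse(n > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
    out[[short[[cn]]]] <- as.numeric(mu)
    out[[paste0("n_", short[[cn]])]] <- as.integer(n)
  }
  out$classifiable <- stats::complete.cases(
    out[, c("med", "pbmc", "rmsc", "coc", "d3")])
  rownames(out) <- NULL
  out
}

#' Differential secretion across conditions
#'
#' Per-protein one-way ANOVA of NPX values across the condition groups,
#' with Benjamini-Hochberg adjustment across all tested proteins. A protein
#' is testable when at least two conditions have at least two non-missing
#' samples; untestable proteins are reported with `tested = FALSE` and are
#' excluded from the adjustment family. When all groups have zero variance,
#' p is 1 for equal means and 0 otherwise.
#'
#' @param matrix an [npx_matrix()].
#' @param alpha significance threshold on the adjusted p value
#'   (default 0.01).
#' @param welch use Welch's unequal-variance ANOVA instead of the classical
#'   equal-variance F test (default `FALSE`).
#' @return data frame with columns `protein`, `statistic` (F), `p`, `padj`,
#'   `significant`, `tested`.
#' @export
differential_secretion <- function(matrix, alpha = 0.01, welch = FALSE) {
  stopifnot(inherits(matrix, "npx_matrix"))
  cond <- factor(matrix$design, levels = NPX_CONDITIONS)
  res <- data.frame(protein = rownames(matrix$values),
                    statistic = NA_real_, p = NA_real_, padj = NA_real_,
                    significant = FALSE, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(matrix$values))) {
    y <- matrix$values[i, ]
    ok <- !is.na(y)
    g <- droplevels(cond[ok])
    y <- y[ok]
    big <- names(which(table(g) >= 2L))
    if (length(big) < 2L) next
    keep <- g %in% big
    g <- droplevels(g[keep])
    y <- y[keep]
    res$tested[i] <- TRUE
    wvar <- tapply(y, g, stats::var)
    if (all(wvar[!is.na(wvar)] < NPX_EPS)) {
      mu <- tapply(y, g, mean)
      same <- diff(range(mu)) < NPX_EPS
      res$statistic[i] <- if (same) 0 else Inf
      res$p[i] <- if (same) 1 else 0
    } else {
      fit <- stats::oneway.test(y ~ g, var.equal = !welch)
      res$statistic[i] <- unname(fit$statistic)
      res$p[i] <- fit$p.value
    }
  }
  tested <- res$tested
  res$padj[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$significant <- tested & !is.na(res$padj) & res$padj < alpha
  res
}
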