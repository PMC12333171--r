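# In-code fixtures shared across test files.

# A tiny NPX matrix with a known design: 2 proteins x 3 samples, all Medium.
tiny_wide_csv <- function(dir = file.path(tempdir(), "mscpotency-fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  npx <- file.path(dir, "npx.csv")
  design <- file.path(dir, "design.csv")
  writeLines(c("protein,s1,s2,s3",
               "EGF,\"5,08\",4.9,5.2",
               "IL6,1.2,1.3,1.1"), npx)
  writeLines(c("sample,condition",
               "s1,Medium", "s2,Medium", "s3,Medium"), design)
  list(npx = npx, design = design)
}

# Random NPX matrix across all five conditions, n samples per condition.
random_npx <- function(n_proteins = 6, n_per_condition = 4, seed = 42,
                       missing_frac = 0) {
  set.seed(seed)
  conds <- c("Medium", "PBMC", "rMSC", "Coculture", "D3cMSC")
  samples <- paste0(rep(conds, each = n_per_condition), "_",
                    seq_len(n_per_condition))
  vals <- matrix(rnorm(n_proteins * length(samples), mean = 5),
                 n_proteins, length(samples),
                 dimnames = list(paste0("P", seq_len(n_proteins)), samples))
  if (missing_frac > 0)
    vals[runif(length(vals)) < missing_frac] <- NA_real_
  npx_matrix(vals, setNames(rep(conds, each = n_per_condition), samples))
}

# One-row profile helper for the classifier.
profile_row <- function(protein, med, pbmc, rmsc, coc, d3) {
  data.frame(protein = protein, med = med, pbmc = pbmc, rmsc = rmsc,
             coc = coc, d3 = d3, stringsAsFactors = FALSE)
}

# Random classifier profiles with NPX-like means.
random_profiles <- function(n, seed = 1, spread = 2) {
  set.seed(seed)
  data.frame(protein = paste0("R", seq_len(n)),
             med = runif(n, 0, 10), pbmc = runif(n, 0, 10),
             rmsc = runif(n, 0, 10), coc = runif(n, 0, 10),
             d3 = runif(n, 0, 10), stringsAsFactors = FALSE)
}

# Independent per-event debarcoding oracle: plain loops, no shared code
# with the implementation.
oracle_debarcode_rank <- function(events, scheme, min_separation) {
  k <- scheme$k
  chans <- scheme$channels
  out <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    x <- events[i, chans]
    ord <- order(x, decreasing = TRUE)
    topk <- sort(chans[ord[1:k]])
    sep <- if (length(chans) > k) x[ord[k]] - x[ord[k + 1]] else Inf
    hit <- "UNASSIGNED"
    if (sep > 1e-9 && sep >= min_separation - 1e-9) {
      for (s in names(scheme$codes)) {
        if (identical(sort(scheme$codes[[s]]), topk)) { hit <- s; break }
      }
    }
    out[i] <- hit
  }
  out
}
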