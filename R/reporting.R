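#' Volcano-style up/down/ns summary
#'
#' Classifies each protein as `up` (log2 fold-change at least
#' `log2(fc_cut)` with `p < p_cut`), `down` (at most `-log2(fc_cut)` with
#' `p < p_cut`) or `ns`. The defaults are the representation cut-offs used
#' for the secretome volcano plots: fold-change 1.5 (log2 ~ 0.585) and
#' p 0.05.
#'
#' @param proteins character vector of protein ids.
#' @param log2fc matched numeric vector of log2 fold-changes.
#' @param p matched numeric vector of p values.
#' @param p_cut p-value cut-off (default 0.05).
#' @param fc_cut fold-change cut-off on the linear scale (default 1.5).
#' @return data frame `protein`, `log2fc`, `p`, `direction`, plus the
#'   per-direction counts in attribute `"counts"`.
#' @export
make_volcano_summary <- function(proteins, log2fc, p,
                                 p_cut = 0.05, fc_cut = 1.5) {
  if (length(proteins) != length(log2fc) || length(proteins) != length(p))
    stop("proteins, log2fc and p must have matching lengths")
  thr <- log2(fc_cut)
  direction <- rep("ns", length(proteins))
  direction[p < p_cut & log2fc >= thr - NPX_EPS] <- "up"
  direction[p < p_cut & log2fc <= -thr + NPX_EPS] <- "down"
  out <- data.frame(protein = proteins, log2fc = log2fc, p = p,
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(up = sum(direction == "up"),
                           down = sum(direction == "down"),
                           ns = sum(direction == "ns"))
  out
}
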