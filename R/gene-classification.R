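#' Binary methylated-site call from read counts
#'
#' A covered cytosine is called methylated when its methylated read count is
#' unlikely under the sequencing error / bisulfite non-conversion rate: call
#' 1 iff the one-sided binomial tail `P(X >= mc | n = total, p = error_rate)`
#' is at or below `alpha`. Sites without coverage get no call (`NA`).
#'
#' @param mc_count,total_count Integer vectors of methylated and total read
#'   counts.
#' @param error_rate Per-read probability of a spurious methylated call;
#'   default 0.005, a typical non-conversion magnitude.
#' @param alpha Tail-probability threshold for the call.
#' @return Integer vector of 0/1 calls, `NA` where `total_count == 0`.
#' @export
call_sites <- function(mc_count, total_count, error_rate = 0.005,
                       alpha = 0.01) {
  stopifnot(error_rate >= 0, error_rate <= 1, alpha > 0, alpha <= 1)
  tail_p <- pbinom(mc_count - 1L, total_count, error_rate,
                   lower.tail = FALSE)
  out <- as.integer(tail_p <= alpha & mc_count > 0L)
  out[total_count == 0L] <- NA_integer_
  out
}

#' Background methylated-site rates per context
#'
#' The fraction of covered cytosines carrying a positive methylated-site
#' call, per context, over either the coding sequences of the supplied
#' genes or the whole genome. These rates are the null `pi` of the
#' per-gene binomial enrichment test.
#'
#' @param meth Methylome table with a `site_call` column.
#' @param genes Gene annotation (required for `scope = "cds"`).
#' @param scope `"cds"` (sites within the supplied gene intervals) or
#'   `"genome"`.
#' @return Named numeric vector `c(CG = , CHG = , CHH = )`.
#' @export
background_rates <- function(meth, genes = NULL, scope = c("cds", "genome")) {
  scope <- match.arg(scope)
  x <- meth[total_count > 0L & !is.na(site_call)]
  if (scope == "cds") {
    if (is.null(genes) || nrow(genes) == 0L)
      stop("scope 'cds' requires a non-empty gene annotation")
    f <- data.table::as.data.table(genes)[, .(chrom, fstart = start + 1L,
                                              fend = end, id)]
    data.table::setkey(f, chrom, fstart, fend)
    x <- x[, .(chrom, pos, context_class, site_call, pstart = pos,
               pend = pos)]
    x <- data.table::foverlaps(x, f, by.x = c("chrom", "pstart", "pend"),
                               nomatch = NULL)
  }
  if (nrow(x) == 0L) stop("no covered sites in scope")
  tab <- x[, .(pi = mean(site_call == 1L), n = .N), by = context_class]
  miss <- setdiff(.CONTEXTS, tab$context_class)
  if (length(miss))
    stop(sprintf("no covered sites in scope for context(s): %s",
                 paste(miss, collapse = ", ")))
  setNames(tab$pi, tab$context_class)[.CONTEXTS]
}

#' Classify genes by context-specific methylation enrichment
#'
#' Per gene and context, counts covered coding-sequence cytosines (`n`) and
#' those with a positive methylated-site call (`k`) and tests enrichment
#' against the background rate with a one-sided binomial test,
#' `p = P(X >= k | n, pi_ctx)`. p-values are Benjamini-Hochberg adjusted
#' within each context across all genes; a context is enriched iff
#' `q <= alpha_q`. Classes are assigned by precedence: CHH-enriched genes
#' are `mCHH` regardless of the other contexts (they typically carry mCG
#' and mCHG too); otherwise CHG-enriched genes are `mCHG` (which may carry
#' mCG); otherwise CG-enriched genes are `gbM`; otherwise `unmethylated`.
#' A gene with zero covered sites in a context is treated as not enriched
#' there and flagged.
#'
#' @param meth Methylome table with `site_call` (set `recompute_calls` to
#'   re-derive calls from the counts).
#' @param genes Gene annotation table (`id`, 0-based half-open intervals).
#' @param background Named vector of per-context background rates in (0,1);
#'   computed from the genes' coding sequences via [background_rates()]
#'   when `NULL`.
#' @param alpha_q Enrichment threshold on the BH-adjusted q-value.
#' @param recompute_calls Recompute site calls with [call_sites()].
#' @param error_rate,alpha Site-call parameters used when recomputing.
#' @return `data.table`, one row per gene: per-context `n_*`, `k_*`, `p_*`,
#'   `q_*`, `enriched_*`, a `flagged` marker for missing-context genes and
#'   the assigned `class`.
#' @export
classify_genes <- function(meth, genes, background = NULL, alpha_q = 0.05,
                           recompute_calls = FALSE, error_rate = 0.005,
                           alpha = 0.01) {
  genes <- data.table::as.data.table(genes)
  if (nrow(genes) == 0L) stop("empty gene set")
  x <- meth[total_count > 0L]
  if (recompute_calls)
    x <- data.table::copy(x)[, site_call := call_sites(mc_count, total_count,
                                                       error_rate, alpha)]
  if (is.null(background))
    background <- background_rates(x, genes, scope = "cds")
  if (any(background <= 0 | background >= 1))
    stop("background rates must lie strictly within (0, 1)")

  f <- genes[, .(chrom, fstart = start + 1L, fend = end, id)]
  data.table::setkey(f, chrom, fstart, fend)
  pts <- x[, .(chrom, pos, context_class, site_call, pstart = pos,
               pend = pos)]
  ov <- data.table::foverlaps(pts, f, by.x = c("chrom", "pstart", "pend"),
                              nomatch = NULL)
  counts <- ov[, .(n = .N, k = sum(site_call == 1L)),
               by = .(id, context = context_class)]
  grid <- data.table::CJ(id = genes$id, context = .CONTEXTS, sorted = FALSE)
  counts <- counts[grid, on = c("id", "context")]
  counts[is.na(n), `:=`(n = 0L, k = 0L)]
  counts[, p := data.table::fifelse(
    n > 0L, pbinom(k - 1L, n, background[context], lower.tail = FALSE),
    NA_real_)]
  counts[, q := {
    qq <- rep(NA_real_, .N)
    ok <- !is.na(p)
    qq[ok] <- p.adjust(p[ok], method = "BH")
    qq
  }, by = context]
  counts[, enriched := !is.na(q) & q <= alpha_q & n > 0L]

  wide <- data.table::dcast(counts, id ~ context,
                            value.var = c("n", "k", "p", "q", "enriched"))
  wide[, flagged := n_CG == 0L | n_CHG == 0L | n_CHH == 0L]
  wide[, class := data.table::fcase(
    enriched_CHH, "mCHH",
    enriched_CHG, "mCHG",
    enriched_CG, "gbM",
    default = "unmethylated")]
  wide <- wide[data.table::data.table(id = genes$id), on = "id"]
  n_flag <- sum(wide$flagged)
  if (n_flag > 0L)
    message(sprintf("classify_genes: %d gene(s) lack covered sites in at least one context",
                    n_flag))
  wide[]
}
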