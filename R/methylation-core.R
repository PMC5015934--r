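.filter_context <- function(meth, context) {
  if (length(context) == 1L && context == "ALL") return(meth)
  bad <- setdiff(context, .CONTEXTS)
  if (length(bad))
    stop(sprintf("unknown context(s): %s", paste(bad, collapse = ", ")))
  meth[context_class %in% context]
}

#' Weighted methylation level of a set of cytosines
#'
#' The coverage-weighted methylation level: the sum of methylated read
#' counts divided by the sum of total read counts over all qualifying
#' covered cytosines (`total_count > 0`). Sites without coverage never
#' contribute. With no qualifying site the level is undefined and returned
#' as `NA`, which is distinct from 0.
#'
#' @param meth A methylome table (see [methylome()]).
#' @param context `"CG"`, `"CHG"`, `"CHH"`, a vector of these, or `"ALL"`
#'   to pool the three contexts.
#' @param region Optional interval: a list or one-row data.frame with
#'   `chrom`, `start`, `end` (0-based half-open). A site belongs to the
#'   region iff `pos - 1` lies in `[start, end)`.
#' @return A list with `level`, `n_sites`, `sum_mc`, `sum_total`.
#' @export
weighted_methylation <- function(meth, context = "ALL", region = NULL) {
  x <- meth[total_count > 0L]
  x <- .filter_context(x, context)
  if (!is.null(region)) {
    region <- as.list(region)
    x <- x[chrom == region$chrom & (pos - 1L) >= region$start &
             (pos - 1L) < region$end]
  }
  st <- sum(as.numeric(x$total_count))
  list(level = if (st > 0) sum(as.numeric(x$mc_count)) / st else NA_real_,
       n_sites = nrow(x),
       sum_mc = sum(as.numeric(x$mc_count)),
       sum_total = st)
}

#' Tile chromosomes into fixed-width windows
#'
#' Non-overlapping half-open tiles `[0, w), [w, 2w), ...`; the final partial
#' tile is retained, so window widths sum exactly to the chromosome length.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window_bp Window width in bp (> 0).
#' @return A `data.table` with `chrom`, `start`, `end`, `id`, `kind`.
#' @export
make_windows <- function(chrom_lengths, window_bp) {
  stopifnot(window_bp > 0, all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- as.integer(chrom_lengths[[cn]])
    starts <- seq.int(0L, len - 1L, by = as.integer(window_bp))
    data.table::data.table(chrom = cn, start = starts,
                           end = pmin(starts + as.integer(window_bp), len))
  })
  w <- data.table::rbindlist(out)
  w[, id := sprintf("win_%s_%07d", chrom, start)]
  w[, kind := "window"]
  w[]
}

.full_stat_grid <- function(windows, agg, contexts) {
  grid <- data.table::CJ(id = windows$id, context = contexts, sorted = FALSE)
  grid <- windows[, .(chrom, start, end, id)][grid, on = "id"]
  out <- agg[grid, on = c("chrom", "start", "context")]
  out[is.na(n_sites), `:=`(n_sites = 0L, sum_mc = 0, sum_total = 0)]
  out[, level := data.table::fifelse(sum_total > 0, sum_mc / sum_total,
                                     NA_real_)]
  data.table::setorder(out, chrom, start, context)
  out[, .(chrom, start, end, context, n_sites, sum_mc, sum_total, level)]
}

#' Per-window methylation profile across chromosomes
#'
#' Tiles every chromosome into `window_bp` windows (see [make_windows()])
#' and computes, per window and context, the weighted methylation level and
#' its site and read counts in a single pass over the sorted methylome.
#' Windows without covered sites get `n_sites = 0` and an undefined (`NA`)
#' level. `"ALL"` in `contexts` adds a pooled all-context entry.
#'
#' @param meth Methylome table.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_bp Window width in bp; the chromosome-scale default is
#'   50 kb.
#' @param contexts Contexts to tabulate; any of `"CG"`, `"CHG"`, `"CHH"`,
#'   `"ALL"`.
#' @return Long-format `data.table`: `chrom`, `start`, `end`, `context`,
#'   `n_sites`, `sum_mc`, `sum_total`, `level`.
#' @export
chromosome_profile <- function(meth, chrom_lengths, window_bp = 50000,
                               contexts = c("CG", "CHG", "CHH")) {
  windows <- make_windows(chrom_lengths, window_bp)
  x <- meth[total_count > 0L]
  x <- x[chrom %in% names(chrom_lengths)]
  x[, start := (as.integer(pos) - 1L) %/% as.integer(window_bp) *
      as.integer(window_bp)]
  per_ctx <- x[, .(n_sites = .N, sum_mc = sum(as.numeric(mc_count)),
                   sum_total = sum(as.numeric(total_count))),
               by = .(chrom, start, context = context_class)]
  aggs <- list()
  plain <- setdiff(contexts, "ALL")
  if (length(plain)) aggs <- c(aggs, list(per_ctx[context %in% plain]))
  if ("ALL" %in% contexts) {
    pooled <- per_ctx[, .(n_sites = sum(n_sites), sum_mc = sum(sum_mc),
                          sum_total = sum(sum_total)),
                      by = .(chrom, start)]
    pooled[, context := "ALL"]
    aggs <- c(aggs, list(pooled))
  }
  agg <- data.table::rbindlist(aggs, use.names = TRUE)
  .full_stat_grid(windows, agg, contexts)
}

#' Per-feature methylation statistics for arbitrary regions
#'
#' Computes weighted methylation per annotated interval (genes, promoters,
#' custom regions) and context. Serves region-level questions such as the
#' methylation of individual silenced-gene promoters.
#'
#' @param meth Methylome table.
#' @param features Annotation table (0-based half-open `start`/`end`, `id`).
#' @param contexts Contexts to tabulate (may include `"ALL"`).
#' @return Long-format `data.table`: `id`, `chrom`, `start`, `end`,
#'   `context`, `n_sites`, `sum_mc`, `sum_total`, `level`.
#' @export
region_profile <- function(meth, features, contexts = c("CG", "CHG", "CHH")) {
  features <- data.table::as.data.table(features)
  if (nrow(features) == 0L) stop("empty feature set")
  f <- features[, .(chrom, fstart = start + 1L, fend = end, id)]
  data.table::setkey(f, chrom, fstart, fend)
  x <- meth[total_count > 0L][, .(chrom, pos, context_class, mc_count,
                                  total_count, pstart = pos, pend = pos)]
  ov <- data.table::foverlaps(x, f, by.x = c("chrom", "pstart", "pend"),
                              nomatch = NULL)
  per_ctx <- ov[, .(n_sites = .N, sum_mc = sum(as.numeric(mc_count)),
                    sum_total = sum(as.numeric(total_count))),
                by = .(id, context = context_class)]
  aggs <- list()
  plain <- setdiff(contexts, "ALL")
  if (length(plain)) aggs <- c(aggs, list(per_ctx[context %in% plain]))
  if ("ALL" %in% contexts) {
    pooled <- per_ctx[, .(n_sites = sum(n_sites), sum_mc = sum(sum_mc),
                          sum_total = sum(sum_total)), by = .(id)]
    pooled[, context := "ALL"]
    aggs <- c(aggs, list(pooled))
  }
  agg <- data.table::rbindlist(aggs, use.names = TRUE)
  grid <- data.table::CJ(id = features$id, context = contexts, sorted = FALSE)
  out <- agg[grid, on = c("id", "context")]
  out <- features[, .(id, chrom, start, end)][out, on = "id"]
  out[is.na(n_sites), `:=`(n_sites = 0L, sum_mc = 0, sum_total = 0)]
  out[, level := data.table::fifelse(sum_total > 0, sum_mc / sum_total,
                                     NA_real_)]
  data.table::setorder(out, chrom, start, context)
  out[]
}

.check_same_grid <- function(a, b) {
  ka <- a[, .(chrom, start, end, context)]
  kb <- b[, .(chrom, start, end, context)]
  data.table::setorder(ka, chrom, start, context)
  data.table::setorder(kb, chrom, start, context)
  if (!isTRUE(all.equal(ka, kb, check.attributes = FALSE)))
    stop("window grids of the two samples do not match")
}

#' Treated-over-control relative methylation per window
#'
#' For each window and context, the ratio of the treated weighted level to
#' the control weighted level. The ratio is undefined (`NA`) wherever
#' either level is undefined or the control level is 0 — never infinity.
#'
#' @param treated,control Window statistics on identical grids (same
#'   chromosomes, windows and contexts), as from [chromosome_profile()].
#' @return `data.table` with the grid columns, both levels and `ratio`.
#' @export
relative_profile <- function(treated, control) {
  .check_same_grid(treated, control)
  t <- data.table::copy(treated)[, .(chrom, start, end, context,
                                     treated_level = level)]
  c <- data.table::copy(control)[, .(chrom, start, end, context,
                                     control_level = level)]
  out <- t[c, on = c("chrom", "start", "end", "context")]
  out[, ratio := data.table::fifelse(
    !is.na(treated_level) & !is.na(control_level) & control_level > 0,
    treated_level / control_level, NA_real_)]
  data.table::setorder(out, chrom, start, context)
  out[]
}

#' Distribution of per-site methylation levels
#'
#' Histogram of `mc_count / total_count` over covered sites of one context,
#' plus the fraction of sites that are completely methylated (level exactly
#' 1, i.e. `mc_count == total_count`). With `only_methylated_sites` the
#' distribution is restricted to sites with a positive methylated-site call,
#' matching the "fraction of methylated cytosines that are completely
#' methylated" summary.
#'
#' @param meth Methylome table.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"` or `"ALL"`.
#' @param only_methylated_sites Restrict to sites with `site_call == 1`.
#' @param breaks Histogram bin edges spanning \[0, 1\].
#' @return List with `context`, `breaks`, `counts`, `fraction` (normalized
#'   to sum to 1), `fraction_fully_methylated` and `n_sites`.
#' @export
site_level_distribution <- function(meth, context = "CG",
                                    only_methylated_sites = FALSE,
                                    breaks = seq(0, 1, by = 0.05)) {
  x <- meth[total_count > 0L]
  x <- .filter_context(x, context)
  if (only_methylated_sites) x <- x[site_call == 1L]
  if (nrow(x) == 0L)
    stop("no qualifying sites: distribution undefined")
  lev <- x$mc_count / x$total_count
  h <- graphics::hist(lev, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(context = context,
       breaks = h$breaks,
       counts = h$counts,
       fraction = h$counts / length(lev),
       fraction_fully_methylated = mean(x$mc_count == x$total_count),
       n_sites = length(lev))
}

#' Pairwise treated-vs-control levels in highly methylated windows
#'
#' Retains windows whose control level is defined and at or above
#' `min_control_level` and whose treated level is defined, and returns the
#' paired (control, treated) levels — the input to pairwise density plots
#' comparing demethylation in pericentromere versus chromosome arms. The
#' quantiles of the per-window treated/control ratio are attached as the
#' `"ratio_quantiles"` attribute.
#'
#' @param treated,control Window statistics on identical grids (typically
#'   100 bp windows).
#' @param context Single context to compare.
#' @param min_control_level Control-level threshold in \[0, 1\]; the
#'   chromosome-scale analysis uses 0.5 for CG and 0.3 for CHH.
#' @return `data.table` of retained windows with `control_level`,
#'   `treated_level` and `ratio`.
#' @export
pairwise_high_meth_windows <- function(treated, control, context = "CG",
                                       min_control_level = 0.5) {
  stopifnot(min_control_level >= 0, min_control_level <= 1)
  t <- treated[treated$context == context]
  c <- control[control$context == context]
  .check_same_grid(t, c)
  out <- relative_profile(t, c)
  out <- out[!is.na(control_level) & control_level >= min_control_level &
               !is.na(treated_level)]
  out[, ratio := data.table::fifelse(control_level > 0,
                                     treated_level / control_level, NA_real_)]
  data.table::setattr(out, "ratio_quantiles",
                      quantile(out$ratio, c(0.25, 0.5, 0.75), na.rm = TRUE,
                               names = TRUE))
  out[]
}

#' Assign windows to pericentromere or chromosome arms
#'
#' A window is pericentromeric iff its midpoint lies within the supplied
#' pericentromere interval of its chromosome (half-open). Windows on
#' chromosomes without an interval are arm windows. Every window is
#' assigned to exactly one compartment.
#'
#' @param x Window table or window statistics (`chrom`, `start`, `end`).
#' @param pericentromere `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), one row per chromosome with a defined pericentromere.
#' @return Copy of `x` with a `compartment` column
#'   (`"pericentromere"`/`"arm"`).
#' @export
partition_pericentromere <- function(x, pericentromere) {
  x <- data.table::copy(data.table::as.data.table(x))
  peri <- data.table::as.data.table(pericentromere)
  x[, mid := (start + end) / 2]
  x[, compartment := "arm"]
  for (i in seq_len(nrow(peri))) {
    x[chrom == peri$chrom[i] & mid >= peri$start[i] & mid < peri$end[i],
      compartment := "pericentromere"]
  }
  x[, mid := NULL]
  x[]
}
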