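#' Metagene methylation profile over scaled gene bodies with fixed flanks
#'
#' For each feature, the gene body is divided into `body_bins` proportional
#' bins and each flank into `flank_bins` fixed-width bins spanning
#' `flank_bp` (1500 bp up- and downstream by default). Within each feature
#' and bin the weighted methylation level is computed per context; the
#' profile value of a bin is the unweighted mean over features with a
#' defined level there, so long or deeply covered genes do not dominate.
#' Minus-strand features are mirrored so bin 1 is always the outermost 5'
#' flank bin. Features shorter than `body_bins` bp are skipped with a
#' message.
#'
#' @param meth Methylome table.
#' @param features Feature annotation (genes or TE genes; 0-based
#'   half-open, stranded).
#' @param flank_bp Flank span in bp on each side (>= 0).
#' @param body_bins Number of proportional bins across the body.
#' @param flank_bins Number of fixed-width bins per flank.
#' @param contexts Contexts to profile (may include `"ALL"`).
#' @return `data.table` with one row per bin per context: `bin` (1-based,
#'   5' to 3'), `segment` (`upstream`/`body`/`downstream`), `context`,
#'   `mean_level` (`NA` if no feature has a defined level) and
#'   `n_features` contributing.
#' @export
metagene_profile <- function(meth, features, flank_bp = 1500,
                             body_bins = 20, flank_bins = 15,
                             contexts = c("CG", "CHG", "CHH")) {
  features <- data.table::as.data.table(features)
  stopifnot(nrow(features) > 0L, flank_bp >= 0, body_bins >= 1)
  if (flank_bp == 0) flank_bins <- 0L
  stopifnot(flank_bp == 0 || flank_bins >= 1)

  short <- features[end - start < body_bins]
  if (nrow(short) > 0L) {
    message(sprintf("metagene_profile: skipped %d feature(s) shorter than %d bp",
                    nrow(short), body_bins))
    features <- features[end - start >= body_bins]
    if (nrow(features) == 0L) stop("no usable features")
  }

  flank_w <- if (flank_bins > 0L) flank_bp / flank_bins else 1
  n_bins <- 2L * flank_bins + body_bins

  f <- features[, .(chrom, fstart = start - flank_bp + 1L, fend = end + flank_bp,
                    id, gstart = start, gend = end, gstrand = strand)]
  data.table::setkey(f, chrom, fstart, fend)
  x <- meth[total_count > 0L][, .(chrom, pos, context_class, mc_count,
                                  total_count, pstart = pos, pend = pos)]
  ov <- data.table::foverlaps(x, f, by.x = c("chrom", "pstart", "pend"),
                              nomatch = NULL)
  # strand-corrected offset from the 5' gene start; negative = upstream
  ov[, rel := data.table::fifelse(gstrand == "-", gend - pos,
                                  pos - 1L - gstart)]
  ov[, len := gend - gstart]
  # floor divisions in exact integer arithmetic so bin seams are stable
  ov[, bin := NA_integer_]
  ov[rel < 0, bin := flank_bins + 1L +
       as.integer((as.numeric(rel) * flank_bins) %/% flank_bp)]
  ov[rel >= 0 & rel < len,
     bin := flank_bins + 1L +
       pmin(as.integer((as.numeric(rel) * body_bins) %/% len),
            body_bins - 1L)]
  ov[rel >= len,
     bin := flank_bins + body_bins + 1L +
       pmin(as.integer((as.numeric(rel - len) * flank_bins) %/% flank_bp),
            flank_bins - 1L)]
  ov <- ov[!is.na(bin) & bin >= 1L & bin <= n_bins]

  per_feat <- ov[, .(sum_mc = sum(as.numeric(mc_count)),
                     sum_total = sum(as.numeric(total_count))),
                 by = .(id, bin, context = context_class)]
  if ("ALL" %in% contexts) {
    pooled <- per_feat[, .(sum_mc = sum(sum_mc), sum_total = sum(sum_total)),
                       by = .(id, bin)]
    pooled[, context := "ALL"]
    per_feat <- data.table::rbindlist(
      list(per_feat[context %in% setdiff(contexts, "ALL")], pooled),
      use.names = TRUE)
  } else {
    per_feat <- per_feat[context %in% contexts]
  }
  per_feat[, level := sum_mc / sum_total]

  agg <- per_feat[sum_total > 0,
                  .(mean_level = mean(level), n_features = .N),
                  by = .(bin, context)]
  grid <- data.table::CJ(bin = seq_len(n_bins), context = contexts,
                         sorted = FALSE)
  out <- agg[grid, on = c("bin", "context")]
  out[is.na(n_features), n_features := 0L]
  out[, segment := data.table::fcase(
    bin <= flank_bins, "upstream",
    bin <= flank_bins + body_bins, "body",
    default = "downstream")]
  data.table::setorder(out, context, bin)
  out[, .(bin, segment, context, mean_level, n_features)]
}
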