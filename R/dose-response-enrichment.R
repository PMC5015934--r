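#' Linear dose-response fit of methylation on inhibitor concentration
#'
#' Ordinary least squares of the weighted methylation level on the
#' demethylating-agent concentration, `lm(level ~ concentration)`. The
#' designed use takes exactly one genome-wide (or per-context) level per
#' concentration — typically the four points at 0, 25, 50 and 100 uM — so
#' the slope p-value is reported but low-powered at that n.
#'
#' @param points `data.frame` with columns `concentration` (uM) and `level`,
#'   or two numeric vectors via `concentration=`/`level=`.
#' @param concentration,level Alternative vector interface.
#' @return List with `slope` (level per uM), `intercept`, `r_squared`,
#'   `p_value` (two-sided, slope), `n_points` and the underlying `fit`.
#' @export
fit_dose_response <- function(points = NULL, concentration = NULL,
                              level = NULL) {
  if (!is.null(points)) {
    concentration <- points$concentration
    level <- points$level
  }
  stopifnot(length(concentration) == length(level),
            !any(is.na(concentration)), !any(is.na(level)))
  if (length(unique(concentration)) < 3L)
    stop("dose-response fit requires >= 3 distinct concentrations")
  fit <- lm(level ~ concentration)
  # summary() warns on an exactly collinear fit; the r^2/p are still valid
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(level) == 0) 0 else sm$r.squared
  pv <- if (nrow(sm$coefficients) >= 2L && ncol(sm$coefficients) >= 4L)
    sm$coefficients["concentration", 4L] else NA_real_
  list(slope = unname(stats::coef(fit)["concentration"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = r2,
       p_value = pv,
       n_points = length(level),
       fit = fit)
}

#' Differential-expression filter with pseudocounted fold changes
#'
#' To avoid infinite fold changes, a pseudocount (0.1 by default) is added
#' to every FPKM value before computing
#' `log2fc = log2((fpkm_treated + 0.1) / (fpkm_control + 0.1))`. A gene is
#' `up` iff `q < q_max` and `log2fc > lfc_min`, `down` iff `q < q_max` and
#' `log2fc < -lfc_min`; both inequalities are strict, so a log2 fold change
#' of exactly 2.0 is not differentially expressed at the defaults.
#'
#' @param expr Expression table (`gene_id`, `fpkm_control`, `fpkm_treated`,
#'   `q_value`).
#' @param pseudocount Added to every FPKM value.
#' @param q_max Strict upper bound on the q-value.
#' @param lfc_min Strict lower bound on `|log2fc|`.
#' @return `data.table` with `gene_id`, `log2fc`, `q_value` and `status`
#'   (`up`/`down`/`unchanged`).
#' @export
de_filter <- function(expr, pseudocount = 0.1, q_max = 0.05, lfc_min = 2.0) {
  expr <- data.table::as.data.table(expr)
  if (any(expr$fpkm_control < 0) || any(expr$fpkm_treated < 0))
    stop("negative FPKM values")
  out <- expr[, .(gene_id, q_value,
                  log2fc = log2((fpkm_treated + pseudocount) /
                                  (fpkm_control + pseudocount)))]
  out[, status := data.table::fcase(
    q_value < q_max & log2fc > lfc_min, "up",
    q_value < q_max & log2fc < -lfc_min, "down",
    default = "unchanged")]
  out[]
}

#' Fisher's exact enrichment of a gene category among upregulated genes
#'
#' Builds the 2x2 table of category membership versus upregulation status
#' over the stated background (category members vs the remaining background
#' genes, upregulated vs not) and applies a two-sided Fisher's exact test.
#' Methylation classes are tested against all classified protein-coding
#' genes; TE families are tested against all TE genes. The unconditional
#' sample odds ratio `(a*d)/(b*c)` is reported alongside the p-value.
#'
#' @param category_ids Gene ids of the category; must be a subset of
#'   `background_ids`.
#' @param background_ids Gene ids of the background universe.
#' @param up_ids Gene ids flagged upregulated.
#' @param label Optional category label carried into the result.
#' @param background_label Optional background description.
#' @return List with `label`, `table` (2x2 matrix), `odds_ratio`,
#'   `p_value`, `background_label`.
#' @export
fisher_enrichment <- function(category_ids, background_ids, up_ids,
                              label = NA_character_,
                              background_label = NA_character_) {
  category_ids <- unique(category_ids)
  background_ids <- unique(background_ids)
  if (length(category_ids) == 0L || length(background_ids) == 0L)
    stop("empty category or background")
  if (!all(category_ids %in% background_ids))
    stop("category must be a subset of the background")
  up <- unique(up_ids)
  rest <- setdiff(background_ids, category_ids)
  a <- sum(category_ids %in% up)
  b <- length(category_ids) - a
  c <- sum(rest %in% up)
  d <- length(rest) - c
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("category", "rest"), c("up", "not_up")))
  pv <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- (a * d) / (b * c)
  list(label = label, table = tab, odds_ratio = or, p_value = pv,
       background_label = background_label)
}

#' Composition of upregulated genes by kind, methylation class and TE family
#'
#' Tallies upregulated genes (per [de_filter()]) by gene kind
#' (protein-coding vs TE), by methylation class among protein-coding genes,
#' and by TE family among TE genes, with the percentage of each group that
#' is upregulated (`100 * n_up / n_total`). Protein-coding genes without a
#' class label fall into an explicit `other/unclassified` bucket. DE gene
#' ids that cannot be resolved in the annotation are excluded with a
#' message.
#'
#' @param de DE results from [de_filter()].
#' @param annotation Gene annotation (`id`, `kind`, `te_family`).
#' @param classes Optional gene class table (`id`, `class`), e.g. from
#'   [classify_genes()] or the generator's planted truth.
#' @return `data.table` with `group_type` (`gene_kind`, `meth_class`,
#'   `te_family`), `group`, `n_total`, `n_up`, `pct_up`.
#' @export
upregulation_summary <- function(de, annotation, classes = NULL) {
  ann <- data.table::as.data.table(annotation)
  de <- data.table::as.data.table(de)
  unresolved <- setdiff(de$gene_id, ann$id)
  if (length(unresolved))
    message(sprintf("upregulation_summary: %d DE gene id(s) not in annotation; excluded",
                    length(unresolved)))
  up_ids <- de[status == "up" & !(gene_id %in% unresolved), gene_id]
  ann[, up := id %in% up_ids]

  tally <- function(x, type, grp) {
    x[, .(group_type = type, n_total = .N, n_up = sum(up)), by = .(group = get(grp))][
      , pct_up := 100 * n_up / n_total][]
  }
  ann[, kind_group := kind]
  out <- list(tally(ann, "gene_kind", "kind_group"))

  pc <- ann[kind == "protein_coding_gene"]
  if (nrow(pc) > 0L) {
    if (!is.null(classes)) {
      cls <- data.table::as.data.table(classes)[, .(id, cls = class)]
      pc <- cls[pc, on = "id"]
    } else pc[, cls := NA_character_]
    pc[is.na(cls) | cls == "", cls := "other/unclassified"]
    out <- c(out, list(tally(pc, "meth_class", "cls")))
  }
  te <- ann[kind == "TE_gene"]
  if (nrow(te) > 0L) {
    te[is.na(te_family) | te_family == "", te_family := "other"]
    out <- c(out, list(tally(te, "te_family", "te_family")))
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setcolorder(res, c("group_type", "group", "n_total", "n_up",
                                 "pct_up"))
  res[]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment of a p-value vector (running-minimum tie
#' handling), as used for the per-context gene enrichment tests.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")
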