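# Synthetic methylome / expression generator with planted ground truth.
# All functions are deterministic given their seed: the same inputs yield
# byte-identical output files.

.GENE_BASELINES <- data.table::data.table(
  meth_class = c("gbM", "mCHG", "mCHH", "unmethylated", "TE"),
  pCG  = c(0.85, 0.80, 0.80, 0.05, 0.90),
  pCHG = c(0.02, 0.50, 0.50, 0.02, 0.70),
  pCHH = c(0.02, 0.02, 0.30, 0.02, 0.25)
)

#' Planted per-class baseline methylation probabilities
#'
#' Per-read methylation probabilities used by the generator for each gene
#' class: gbM genes carry high CG but background CHG/CHH; mCHG genes carry
#' mCG alongside mCHG; mCHH genes are methylated in all three contexts;
#' TE genes resemble pericentromeric heterochromatin.
#'
#' @return `data.table` with `meth_class`, `pCG`, `pCHG`, `pCHH`.
#' @export
gene_class_baselines <- function() data.table::copy(.GENE_BASELINES)

#' Specify a synthetic genome
#'
#' Geometry and site-density parameters of the simulated genome:
#' chromosome lengths, optional pericentromere intervals (heterochromatic,
#' TE-dense, methylated in all contexts), cytosine densities per context,
#' the intergenic baseline methylation probabilities of chromosome arms and
#' pericentromere, and the seed that makes site placement deterministic.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp (> 0).
#' @param pericentromere `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open, within the chromosome), or `NULL`.
#' @param site_density Cytosines per kb per context,
#'   `c(CG = , CHG = , CHH = )`.
#' @param arm_baseline,peri_baseline Intergenic per-read methylation
#'   probabilities per context for arms and pericentromere.
#' @param seed Integer seed governing site placement.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths,
                        pericentromere = NULL,
                        site_density = c(CG = 30, CHG = 25, CHH = 120),
                        arm_baseline = c(CG = 0.05, CHG = 0.02, CHH = 0.02),
                        peri_baseline = c(CG = 0.90, CHG = 0.70, CHH = 0.25),
                        seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0),
            all(.CONTEXTS %in% names(site_density)),
            all(site_density > 0),
            all(arm_baseline >= 0 & arm_baseline <= 1),
            all(peri_baseline >= 0 & peri_baseline <= 1))
  if (!is.null(pericentromere)) {
    pericentromere <- data.table::as.data.table(pericentromere)
    stopifnot(all(c("chrom", "start", "end") %in% names(pericentromere)))
    for (i in seq_len(nrow(pericentromere))) {
      cn <- pericentromere$chrom[i]
      if (!cn %in% names(chrom_lengths))
        stop(sprintf("pericentromere on unknown chromosome %s", cn))
      if (pericentromere$start[i] < 0 ||
          pericentromere$end[i] > chrom_lengths[[cn]] ||
          pericentromere$start[i] >= pericentromere$end[i])
        stop(sprintf("pericentromere interval outside chromosome %s", cn))
    }
  }
  structure(list(chrom_lengths = setNames(as.integer(chrom_lengths),
                                          names(chrom_lengths)),
                 pericentromere = pericentromere,
                 site_density = site_density[.CONTEXTS],
                 arm_baseline = arm_baseline[.CONTEXTS],
                 peri_baseline = peri_baseline[.CONTEXTS],
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Specify a treatment condition
#'
#' One sample's treatment: the demethylating agent, its concentration, the
#' per-context demethylation fraction `d` it induces (the expected
#' proportional loss of methylation: a site with baseline per-read
#' probability `p` is sequenced at `p * (1 - d)`), and the mean sequencing
#' coverage. At concentration 0 all `d` must be 0, and `d` must be
#' non-decreasing in concentration across a series.
#'
#' @param agent `"control"`, `"AZA"` (5-azacytidine) or `"ZEB"`
#'   (zebularine).
#' @param concentration Concentration in uM (the study design uses 0, 25,
#'   50, 100).
#' @param d Per-context demethylation fractions in \[0, 1\],
#'   `c(CG = , CHG = , CHH = )`.
#' @param coverage_mean Mean reads per cytosine (Poisson).
#' @return Object of class `treatment_model`.
#' @export
treatment_model <- function(agent = c("control", "AZA", "ZEB"),
                            concentration = 0,
                            d = c(CG = 0, CHG = 0, CHH = 0),
                            coverage_mean = 25) {
  agent <- match.arg(agent)
  stopifnot(all(.CONTEXTS %in% names(d)), concentration >= 0,
            coverage_mean > 0)
  d <- d[.CONTEXTS]
  if (any(d < 0 | d > 1))
    stop("demethylation fractions must lie in [0, 1]")
  if (concentration == 0 && any(d > 0))
    stop("at concentration 0 the demethylation fraction must be 0")
  structure(list(agent = agent, concentration = concentration, d = d,
                 coverage_mean = coverage_mean),
            class = "treatment_model")
}

.arm_segments <- function(spec) {
  segs <- list()
  for (cn in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[cn]]
    peri <- spec$pericentromere
    if (!is.null(peri) && cn %in% peri$chrom) {
      p <- peri[peri$chrom == cn, ]
      cuts <- sort(unique(c(0L, as.integer(p$start), as.integer(p$end), len)))
      for (i in seq_len(length(cuts) - 1L)) {
        s <- cuts[i]; e <- cuts[i + 1L]
        inside <- any(s >= p$start & e <= p$end)
        if (!inside && e > s)
          segs[[length(segs) + 1L]] <- list(chrom = cn, start = s, end = e)
      }
    } else {
      segs[[length(segs) + 1L]] <- list(chrom = cn, start = 0L, end = len)
    }
  }
  segs
}

#' Plant genes with known methylation classes on a synthetic genome
#'
#' Places non-overlapping genes sequentially with a fixed gap: protein-coding
#' classes (shuffled) along chromosome arms, TE genes inside the
#' pericentromere (falling back to arms if no pericentromere is defined or
#' it fills up). TE genes are assigned families by the given proportions.
#'
#' @param spec A [genome_spec()].
#' @param n_per_class Named counts per class
#'   (`gbM`, `mCHG`, `mCHH`, `unmethylated`, `TE`; missing classes = 0).
#' @param gene_bp Gene length in bp.
#' @param gap_bp Intergenic gap between consecutive genes.
#' @param te_family_props Named proportions over TE families.
#' @return Annotation `data.table`: `chrom`, `start`, `end`, `strand`,
#'   `id`, `kind`, `te_family`, `meth_class`.
#' @export
plant_genes <- function(spec,
                        n_per_class = c(gbM = 50, mCHG = 50, mCHH = 50,
                                        unmethylated = 50, TE = 0),
                        gene_bp = 2000, gap_bp = 1000,
                        te_family_props = c(CACTA = 0.2, Copia = 0.3,
                                            Gypsy = 0.3, LINE = 0.1,
                                            other = 0.1)) {
  stopifnot(inherits(spec, "genome_spec"), gene_bp > 0, gap_bp >= 0)
  known <- c("gbM", "mCHG", "mCHH", "unmethylated", "TE")
  stopifnot(all(names(n_per_class) %in% known))
  n_te <- if ("TE" %in% names(n_per_class)) n_per_class[["TE"]] else 0L
  pc_classes <- rep(setdiff(names(n_per_class), "TE"),
                    n_per_class[setdiff(names(n_per_class), "TE")])

  withr::with_seed(spec$seed, {
    pc_classes <- sample(pc_classes)
    # fill arm segments with protein-coding genes
    place <- function(segments, n) {
      rows <- list()
      i <- 0L
      for (seg in segments) {
        cursor <- seg$start + gap_bp
        while (i < n && cursor + gene_bp <= seg$end) {
          i <- i + 1L
          rows[[i]] <- data.table::data.table(chrom = seg$chrom,
                                              start = as.integer(cursor),
                                              end = as.integer(cursor + gene_bp))
          cursor <- cursor + gene_bp + gap_bp
        }
        if (i >= n) break
      }
      if (i < n)
        stop(sprintf("genome too small: placed %d of %d genes", i, n))
      data.table::rbindlist(rows)
    }
    pc <- NULL
    if (length(pc_classes) > 0L) {
      pc <- place(.arm_segments(spec), length(pc_classes))
      pc[, `:=`(strand = rep_len(c("+", "-"), .N),
                id = sprintf("gene%05d", seq_len(.N)),
                kind = "protein_coding_gene", te_family = "",
                meth_class = pc_classes)]
    }
    te <- NULL
    if (n_te > 0L) {
      peri_segs <- list()
      if (!is.null(spec$pericentromere)) {
        for (i in seq_len(nrow(spec$pericentromere)))
          peri_segs[[i]] <- as.list(spec$pericentromere[i,
                                                        c("chrom", "start", "end")])
      } else {
        peri_segs <- .arm_segments(spec)
      }
      te <- place(peri_segs, n_te)
      fams <- sample(names(te_family_props), n_te, replace = TRUE,
                     prob = te_family_props)
      te[, `:=`(strand = rep_len(c("+", "-"), .N),
                id = sprintf("te%05d", seq_len(.N)),
                kind = "TE_gene", te_family = fams, meth_class = "TE")]
    }
  })
  genes <- data.table::rbindlist(list(pc, te), use.names = TRUE)
  data.table::setorder(genes, chrom, start)
  genes[]
}

.validate_genes <- function(genes, spec) {
  genes <- data.table::as.data.table(genes)
  for (i in seq_len(nrow(genes))) {
    cn <- genes$chrom[i]
    if (!cn %in% names(spec$chrom_lengths))
      stop(sprintf("gene %s on unknown chromosome", genes$id[i]))
    if (genes$start[i] < 0 || genes$end[i] > spec$chrom_lengths[[cn]])
      stop(sprintf("gene %s extends outside its chromosome", genes$id[i]))
  }
  by_strand <- split(genes, list(genes$chrom, genes$strand), drop = TRUE)
  for (g in by_strand) {
    g <- g[order(g$start)]
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
      stop("overlapping gene intervals on the same strand")
  }
  invisible(genes)
}

#' Generate the fixed cytosine sites of a synthetic genome
#'
#' Draws cytosine positions per chromosome at the spec's per-context
#' densities (unique positions, uniform along the chromosome, random
#' strand, consistent trinucleotide) and assigns each site its baseline
#' per-read methylation probability: the planted class baseline inside a
#' gene, otherwise the pericentromere or arm intergenic baseline. The site
#' set is a property of the genome — every sample generated from it shares
#' positions and baselines, so treated/control contrasts are paired.
#'
#' @param spec A [genome_spec()] (its `seed` fixes the site set).
#' @param genes Annotation from [plant_genes()] (may be empty
#'   `data.table`).
#' @return `data.table`: `chrom`, `pos` (1-based), `strand`, `context3`,
#'   `context_class`, `p_base`, sorted by chromosome then position.
#' @export
simulate_sites <- function(spec, genes = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (is.null(genes))
    genes <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    id = character(), kind = character(),
                                    te_family = character(),
                                    meth_class = character())
  .validate_genes(genes, spec)
  h <- c("A", "C", "T")
  withr::with_seed(spec$seed, {
    per_chrom <- lapply(names(spec$chrom_lengths), function(cn) {
      len <- spec$chrom_lengths[[cn]]
      n_ctx <- pmax(0L, as.integer(round(len / 1000 * spec$site_density)))
      n_tot <- sum(n_ctx)
      if (n_tot == 0L) return(NULL)
      pos <- sort(sample.int(len, n_tot))
      ctx <- sample(rep(.CONTEXTS, n_ctx))
      tri <- character(n_tot)
      is_cg <- ctx == "CG"; is_chg <- ctx == "CHG"; is_chh <- ctx == "CHH"
      tri[is_cg] <- paste0("CG", sample(c("A", "C", "G", "T"), sum(is_cg),
                                        replace = TRUE))
      tri[is_chg] <- paste0("C", sample(h, sum(is_chg), replace = TRUE), "G")
      tri[is_chh] <- paste0("C", sample(h, sum(is_chh), replace = TRUE),
                            sample(h, sum(is_chh), replace = TRUE))
      data.table::data.table(chrom = cn, pos = pos,
                             strand = sample(c("+", "-"), n_tot,
                                             replace = TRUE),
                             context3 = tri, context_class = ctx)
    })
  })
  sites <- data.table::rbindlist(per_chrom)

  # baseline probability: gene class if inside a gene, else compartment
  base_mat <- as.matrix(.GENE_BASELINES[, .(pCG, pCHG, pCHH)])
  rownames(base_mat) <- .GENE_BASELINES$meth_class
  ctx_col <- match(sites$context_class, .CONTEXTS)
  peri <- spec$pericentromere
  in_peri <- rep(FALSE, nrow(sites))
  if (!is.null(peri)) {
    for (i in seq_len(nrow(peri)))
      in_peri <- in_peri | (sites$chrom == peri$chrom[i] &
                              (sites$pos - 1L) >= peri$start[i] &
                              (sites$pos - 1L) < peri$end[i])
  }
  arm_p <- spec$arm_baseline[ctx_col]
  peri_p <- spec$peri_baseline[ctx_col]
  sites[, p_base := data.table::fifelse(in_peri, peri_p, arm_p)]
  if (nrow(genes) > 0L) {
    f <- data.table::as.data.table(genes)[, .(chrom, fstart = start + 1L,
                                              fend = end, meth_class)]
    data.table::setkey(f, chrom, fstart, fend)
    pts <- sites[, .(chrom, pos, pstart = pos, pend = pos)]
    ov <- data.table::foverlaps(pts, f, by.x = c("chrom", "pstart", "pend"),
                                nomatch = NULL, which = TRUE)
    cls <- f$meth_class[ov$yid]
    sites[ov$xid, p_base := base_mat[cbind(match(cls, rownames(base_mat)),
                                           ctx_col[ov$xid])]]
  }
  data.table::setorder(sites, chrom, pos)
  sites[]
}

#' Sample a methylome from a site set under a treatment
#'
#' Per site, coverage is `Poisson(coverage_mean)` and the methylated read
#' count is `Binomial(total, p_base * (1 - d_ctx))` for the treatment's
#' per-context demethylation fraction. Covered sites get a binomial
#' methylated-site call ([call_sites()]); uncovered sites are written with
#' zero counts and call 0 (consumers exclude them). With `d = 0` and the
#' same seed, a treated sample is byte-identical to the control.
#'
#' @param sites Site table from [simulate_sites()].
#' @param model A [treatment_model()].
#' @param seed Integer seed for the coverage and read draws.
#' @param error_rate,alpha Site-call parameters (see [call_sites()]).
#' @return Methylome `data.table` sorted by chromosome then position.
#' @export
simulate_methylome <- function(sites, model, seed, error_rate = 0.005,
                               alpha = 0.01) {
  stopifnot(inherits(model, "treatment_model"))
  n <- nrow(sites)
  d <- model$d[match(sites$context_class, .CONTEXTS)]
  p <- sites$p_base * (1 - d)
  withr::with_seed(as.integer(seed), {
    total <- rpois(n, model$coverage_mean)
    mc <- rbinom(n, total, p)
  })
  out <- sites[, .(chrom, pos, strand, context3, context_class)]
  out[, `:=`(mc_count = as.integer(mc), total_count = as.integer(total))]
  out[, site_call := {
    sc <- call_sites(mc_count, total_count, error_rate, alpha)
    data.table::fifelse(is.na(sc), 0L, sc)
  }]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Simulate a full concentration series for one agent
#'
#' One sample per concentration, sharing the site set (paired design, one
#' deeply sequenced replicate per condition). Per-sample seeds are derived
#' as `seed * 100 + index`.
#'
#' @param sites Site table from [simulate_sites()].
#' @param agent `"AZA"` or `"ZEB"`.
#' @param d_table `data.frame` with `concentration` and per-context
#'   demethylation fractions `dCG`, `dCHG`, `dCHH` (fraction 0 required at
#'   concentration 0; fractions must be non-decreasing in concentration).
#' @param coverage_mean Mean reads per site.
#' @param seed Base seed.
#' @return Named list of methylomes, one per concentration (names are the
#'   concentrations).
#' @export
simulate_dose_series <- function(sites, agent, d_table, coverage_mean = 25,
                                 seed = 1L) {
  d_table <- data.table::as.data.table(d_table)
  data.table::setorder(d_table, concentration)
  for (col in c("dCG", "dCHG", "dCHH"))
    if (is.unsorted(d_table[[col]]))
      stop("demethylation fractions must be non-decreasing in concentration")
  out <- vector("list", nrow(d_table))
  for (i in seq_len(nrow(d_table))) {
    conc <- d_table$concentration[i]
    m <- treatment_model(
      agent = if (conc == 0) "control" else agent,
      concentration = conc,
      d = c(CG = d_table$dCG[i], CHG = d_table$dCHG[i],
            CHH = d_table$dCHH[i]),
      coverage_mean = coverage_mean)
    out[[i]] <- simulate_methylome(sites, m, seed = seed * 100L + i)
  }
  names(out) <- as.character(d_table$concentration)
  out
}

#' Generate a Cuffdiff-style expression table with planted upregulation
#'
#' Each gene's upregulation status is drawn Bernoulli with the fraction
#' for its label — the TE family for TE genes, the methylation class
#' otherwise (labels absent from `up_fraction` get 0). Planted upregulated
#' genes receive a treated FPKM whose pseudocounted log2 fold change is
#' uniform in (2.2, 5) — at least ~4.5-fold — with q < 0.05; other genes
#' get |log2fc| <= 1.5 with a uniform q-value, so the strict DE filter
#' recovers exactly the planted set. This table is a synthetic stand-in
#' for a differential-expression caller's output, not a model of one.
#'
#' @param genes Annotation from [plant_genes()] (needs `id`, `kind`,
#'   `te_family`, `meth_class`).
#' @param up_fraction Named fractions in \[0, 1\] per label.
#' @param seed Integer seed.
#' @param fpkm_meanlog,fpkm_sdlog Lognormal parameters of control FPKM.
#' @return `data.table`: `gene_id`, `fpkm_control`, `fpkm_treated`,
#'   `q_value`, and the ground-truth `planted_up` flag (dropped by
#'   [write_expression()]).
#' @export
simulate_expression <- function(genes, up_fraction, seed,
                                fpkm_meanlog = 1, fpkm_sdlog = 1) {
  genes <- data.table::as.data.table(genes)
  if (nrow(genes) == 0L) stop("empty gene set")
  if (any(up_fraction < 0 | up_fraction > 1))
    stop("upregulated fractions must lie in [0, 1]")
  lab <- ifelse(genes$kind == "TE_gene", genes$te_family, genes$meth_class)
  frac <- up_fraction[lab]
  frac[is.na(frac)] <- 0
  n <- nrow(genes)
  withr::with_seed(as.integer(seed), {
    up <- runif(n) < frac
    fpkm_c <- rlnorm(n, fpkm_meanlog, fpkm_sdlog)
    lfc <- ifelse(up, runif(n, 2.2, 5), runif(n, -1.5, 1.5))
    fpkm_t <- pmax((fpkm_c + 0.1) * 2^lfc - 0.1, 0)
    qv <- ifelse(up, runif(n, 1e-8, 0.049), runif(n, 0, 1))
  })
  data.table::data.table(gene_id = genes$id, fpkm_control = fpkm_c,
                         fpkm_treated = fpkm_t, q_value = qv,
                         planted_up = up)
}
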