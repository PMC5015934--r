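#' Classify a trinucleotide context as CG, CHG or CHH
#'
#' The sequence context of a cytosine is determined by the two bases 3' of it
#' (read on the strand carrying the cytosine): `CG` if the next base is G,
#' `CHG` if the base after next is G, otherwise `CHH` (H = A, C or T).
#' Contexts containing `N` or unexpected letters cannot be resolved and
#' return `NA`.
#'
#' @param context3 Character vector of trinucleotides starting with the
#'   cytosine itself, e.g. `"CGG"`, `"CAG"`, `"CTT"`.
#' @return Character vector with values `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @export
#' @examples
#' context_class(c("CGA", "CAG", "CTA"))
context_class <- function(context3) {
  c2 <- substr(context3, 2L, 2L)
  c3 <- substr(context3, 3L, 3L)
  h <- c("A", "C", "T")
  out <- rep(NA_character_, length(context3))
  out[c2 == "G"] <- "CG"
  out[c2 %in% h & c3 == "G"] <- "CHG"
  out[c2 %in% h & c3 %in% h] <- "CHH"
  out
}

.validate_methylome <- function(dt, source = "methylome") {
  need <- c("chrom", "pos", "strand", "context3", "mc_count", "total_count",
            "site_call")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", source,
                 paste(miss, collapse = ", ")))
  if (any(dt$pos < 1L))
    stop(sprintf("%s: positions must be 1-based (>= 1)", source))
  if (!all(dt$strand %in% c("+", "-")))
    stop(sprintf("%s: strand must be '+' or '-'", source))
  bad <- which(dt$mc_count > dt$total_count)
  if (length(bad))
    stop(sprintf("%s: mc_count > total_count at line %d", source, bad[1L]))
  if (any(dt$mc_count < 0L) || any(dt$total_count < 0L))
    stop(sprintf("%s: negative read counts", source))
  invisible(dt)
}

#' Build a per-cytosine methylome table
#'
#' Validates the invariants of a per-cytosine call table (counts, strand,
#' 1-based positions) and derives the `context_class` column from the
#' trinucleotide context. Records whose context cannot be resolved (e.g.
#' containing `N`) are dropped with a message.
#'
#' @param dt A data.frame/data.table with columns `chrom`, `pos` (1-based),
#'   `strand`, `context3`, `mc_count`, `total_count`, `site_call`.
#' @return A `data.table` with an added `context_class` column.
#' @export
methylome <- function(dt) {
  dt <- data.table::as.data.table(dt)
  .validate_methylome(dt)
  cls <- context_class(dt$context3)
  n_bad <- sum(is.na(cls))
  if (n_bad > 0L)
    message(sprintf("methylome: skipped %d record(s) with unresolvable trinucleotide context",
                    n_bad))
  dt[, context_class := cls]
  dt <- dt[!is.na(context_class)]
  dt[]
}

#' Read an allc-style per-cytosine methylation table
#'
#' The allc dialect is a headerless 7-column TSV: chromosome, 1-based
#' position, strand, trinucleotide context, methylated read count, total read
#' count, binary methylated-site call. Each cytosine appears once per strand.
#' Input order is preserved.
#'
#' @param path Path to the TSV file.
#' @return A `data.table` of cytosine records with derived `context_class`.
#' @export
read_allc <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1L, 3L, 4L),
                                            integer = c(2L, 5L, 6L, 7L)))
  if (ncol(dt) != 7L)
    stop(sprintf("allc file %s has %d columns, expected 7", path, ncol(dt)))
  data.table::setnames(dt, c("chrom", "pos", "strand", "context3",
                             "mc_count", "total_count", "site_call"))
  .validate_methylome(dt, source = basename(path))
  methylome(dt)
}

#' Write an allc-style per-cytosine methylation table
#'
#' @param meth A methylome table (see [methylome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allc <- function(meth, path) {
  keep <- c("chrom", "pos", "strand", "context3", "mc_count", "total_count",
            "site_call")
  data.table::fwrite(meth[, ..keep], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a feature annotation (GFF3 or BED)
#'
#' Coordinates are normalized to the package-wide internal convention of
#' 0-based half-open intervals: a GFF3 feature `start=101 end=200` becomes
#' `(100, 200)`; a BED line `chr1 100 200` stays `(100, 200)`; a 1 bp GFF3
#' feature with `start = end = k` becomes `(k-1, k)`.
#'
#' For GFF3, features of type `transposable_element_gene` become kind
#' `TE_gene` and `gene` becomes `protein_coding_gene`; a `te_family`
#' attribute is carried through (as is a `meth_class` attribute when
#' present). BED features are imported as kind `region`.
#'
#' @param path Path to the annotation file.
#' @param dialect Either `"gff3"` or `"bed"`.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `id`, `kind`, `te_family` (and `meth_class` for GFF3 inputs carrying it).
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = dialect)
  md <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  ann <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(strand == "*", "+", strand)
  )
  if (dialect == "gff3") {
    type <- as.character(md$type)
    ann[, id := if ("ID" %in% names(md)) as.character(md$ID)
        else sprintf("feature_%06d", .I)]
    ann[, kind := data.table::fcase(
      type == "transposable_element_gene", "TE_gene",
      type == "gene", "protein_coding_gene",
      type == "window", "window",
      default = "region")]
    ann[, te_family := if ("te_family" %in% names(md))
      data.table::fifelse(is.na(md$te_family), "", as.character(md$te_family))
      else ""]
    if ("meth_class" %in% names(md))
      ann[, meth_class := as.character(md$meth_class)]
  } else {
    ann[, id := if ("name" %in% names(md) && !all(is.na(md$name)))
      as.character(md$name) else sprintf("region_%06d", .I)]
    ann[, kind := "region"]
    ann[, te_family := ""]
  }
  if (any(ann$end <= ann$start))
    stop(sprintf("annotation %s: feature with end <= start after normalization",
                 basename(path)))
  ann[]
}

#' Write a gene/TE annotation as GFF3
#'
#' Protein-coding genes are written as type `gene`, TE genes as
#' `transposable_element_gene`; `te_family` (and `meth_class`, if present)
#' are written as attributes. Internal 0-based half-open coordinates are
#' converted to GFF3 1-based inclusive.
#'
#' @param ann Annotation table as returned by [read_annotation()] or
#'   [plant_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  ann <- data.table::as.data.table(ann)
  type <- data.table::fcase(
    ann$kind == "TE_gene", "transposable_element_gene",
    ann$kind == "protein_coding_gene", "gene",
    ann$kind == "window", "window",
    default = "region")
  attrs <- sprintf("ID=%s", ann$id)
  has_fam <- !is.na(ann$te_family) & ann$te_family != ""
  attrs[has_fam] <- paste0(attrs[has_fam], ";te_family=", ann$te_family[has_fam])
  if ("meth_class" %in% names(ann)) {
    has_cls <- !is.na(ann$meth_class) & ann$meth_class != ""
    attrs[has_cls] <- paste0(attrs[has_cls], ";meth_class=", ann$meth_class[has_cls])
  }
  lines <- sprintf("%s\tmethylDose\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   ann$chrom, type, ann$start + 1L, ann$end, ann$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read / write a chromosome-lengths table
#'
#' Two-column headerless TSV: chromosome name, length in bp.
#'
#' @param path File path.
#' @return `read_chrom_lengths`: a named integer vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  if (any(dt$length <= 0)) stop("chromosome lengths must be > 0")
  setNames(as.integer(dt$length), dt$chrom)
}

#' @rdname read_chrom_lengths
#' @param lengths Named vector of chromosome lengths.
#' @export
write_chrom_lengths <- function(lengths, path) {
  data.table::fwrite(data.table::data.table(chrom = names(lengths),
                                            length = as.integer(lengths)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a Cuffdiff-style expression table
#'
#' TSV with header columns `gene_id`, `fpkm_control`, `fpkm_treated`,
#' `q_value`. FPKM values must be non-negative and q-values in \[0, 1\].
#'
#' @param path File path.
#' @return `read_expression`: a `data.table` of expression records.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("gene_id", "fpkm_control", "fpkm_treated", "q_value")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("expression table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(dt$fpkm_control < 0) || any(dt$fpkm_treated < 0))
    stop("negative FPKM values")
  if (any(is.na(dt$q_value)) || any(dt$q_value < 0 | dt$q_value > 1))
    stop("q_value must be present and in [0, 1] for every gene")
  dt[]
}

#' @rdname read_expression
#' @param expr Expression table.
#' @export
write_expression <- function(expr, path) {
  keep <- c("gene_id", "fpkm_control", "fpkm_treated", "q_value")
  data.table::fwrite(data.table::as.data.table(expr)[, ..keep], path,
                     sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Write / read per-window methylation statistics
#'
#' BED-compatible TSV with header: `chrom`, `start`, `end`, then for every
#' context present the site count, summed methylated reads, summed total
#' reads and the weighted level (written `NA` where the window has no
#' covered sites). On reading, weighted levels are recomputed from the
#' integer counts so a round trip reproduces the statistics exactly.
#'
#' @param stats Long-format window statistics as produced by
#'   [chromosome_profile()] or [region_profile()].
#' @param path Output path.
#' @return `write_windows`: `path`, invisibly. `read_windows`: the
#'   long-format statistics table.
#' @export
write_windows <- function(stats, path) {
  stats <- data.table::as.data.table(stats)
  if (nrow(stats) == 0L) stop("empty window statistics")
  wide <- data.table::dcast(stats, chrom + start + end ~ context,
                            value.var = c("n_sites", "sum_mc", "sum_total",
                                          "level"))
  data.table::setorder(wide, chrom, start)
  data.table::fwrite(wide, path, sep = "\t", col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  wide <- data.table::fread(path, header = TRUE, sep = "\t")
  long <- data.table::melt(wide, id.vars = c("chrom", "start", "end"),
                           measure.vars = patterns(n_sites = "^n_sites_",
                                                   sum_mc = "^sum_mc_",
                                                   sum_total = "^sum_total_"),
                           variable.name = "context")
  ctxs <- sub("^n_sites_", "",
              grep("^n_sites_", names(wide), value = TRUE))
  long[, context := ctxs[as.integer(context)]]
  long[, level := data.table::fifelse(sum_total > 0, sum_mc / sum_total,
                                      NA_real_)]
  data.table::setorder(long, chrom, start, context)
  long[]
}
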