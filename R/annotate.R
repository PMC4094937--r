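#' Assign CpGs to gene-centric regions
#'
#' Regions relative to the transcription start site (TSS), measured along
#' each gene's strand (upstream negative): intergenic (no gene window within
#' 10 kb), distal promoter (-10 kb to -1.5 kb), proximal promoter (-1.5 kb
#' to +500 bp), gene body (+500 bp to the 3' end) and downstream (3' end to
#' +5 kb past it). When a CpG satisfies several genes' windows, precedence
#' is proximal promoter > distal promoter > gene body > downstream; residual
#' ties break by smallest absolute TSS distance, then lexicographic gene id.
#'
#' @param position,chrom CpG coordinates (1-based position of the C).
#' @param genes gene model table: gene_id, chrom, strand ("+"/"-"), tss,
#'   end3 (1-based).
#' @return character vector of region labels.
#' @export
assign_gene_region <- function(position, chrom, genes) {
  g <- data.table::as.data.table(genes)
  n <- length(position)
  best_code <- rep(5L, n)       # 1 prox, 2 distal, 3 body, 4 downstream, 5 none
  best_dist <- rep(Inf, n)
  best_gene <- rep(NA_character_, n)
  off_chrom <- !(chrom %in% unique(g$chrom))
  if (any(off_chrom) && nrow(g))
    warning(sum(off_chrom), " CpG(s) on chromosomes absent from the gene models; assigned intergenic")
  for (i in seq_len(nrow(g))) {
    on <- chrom == g$chrom[i]
    if (!any(on)) next
    sgn <- if (g$strand[i] == "+") 1 else -1
    d <- (position - g$tss[i]) * sgn
    len <- abs(g$end3[i] - g$tss[i])
    code <- rep(5L, n)
    code[on & d >= -1500 & d <= 500] <- 1L
    code[on & d >= -10000 & d < -1500] <- 2L
    code[on & d > 500 & d <= len] <- 3L
    code[on & d > len & d <= len + 5000] <- 4L
    ad <- abs(d)
    upd <- code < best_code |
      (code == best_code & (ad < best_dist |
         (ad == best_dist & !is.na(best_gene) & g$gene_id[i] < best_gene)))
    upd <- upd & code < 5L
    best_dist[upd] <- ad[upd]
    best_code[upd] <- code[upd]
    best_gene[upd] <- g$gene_id[i]
  }
  c("proximal_promoter", "distal_promoter", "gene_body", "downstream",
    "intergenic")[best_code]
}

#' Assign CpGs to CpG-island context classes
#'
#' Inside a (merged) island: CGI; within 2 kb of an island edge: shore;
#' within 2-4 kb: shelf; otherwise non-CGI. The nearest island governs where
#' the flanks of two islands overlap, so CGI beats shore beats shelf.
#'
#' @param position,chrom CpG coordinates (1-based).
#' @param cgi island intervals (chrom, start, end; 1-based inclusive).
#' @return character vector of "CGI" / "shore" / "shelf" / "nonCGI".
#' @export
assign_cgi_class <- function(position, chrom, cgi) {
  x <- data.table::as.data.table(cgi)
  if (nrow(x) && any(x$end < x$start)) stop("malformed interval: end < start")
  out <- rep("nonCGI", length(position))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    isl <- x[x$chrom == ch]
    if (!nrow(isl)) next
    ir_isl <- IRanges::reduce(IRanges::IRanges(isl$start, isl$end))
    ir_pts <- IRanges::IRanges(position[sel], position[sel])
    inside <- IRanges::overlapsAny(ir_pts, ir_isl)
    dtn <- IRanges::distanceToNearest(ir_pts, ir_isl)
    gap <- rep(Inf, length(sel))
    gap[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
    bp <- gap + 1          # IRanges reports positions strictly between
    cls <- rep("nonCGI", length(sel))
    cls[bp <= 4000] <- "shelf"
    cls[bp <= 2000] <- "shore"
    cls[inside] <- "CGI"
    out[sel] <- cls
  }
  out
}

#' Regulatory and imprinted-region overlap flags
#'
#' Point-in-interval membership against DNase-hypersensitivity,
#' transcription-factor-binding and imprinted-DMR tracks; the imprinted
#' overlap returns the DMR's gene id.
#'
#' @param position,chrom CpG coordinates (1-based).
#' @param dhs,tfbs interval tables (chrom, start, end; 1-based inclusive).
#' @param imprinted interval table with a `name` column carrying gene ids.
#' @return data.table: dhs, tfbs (logical), imprinted_gene (character, NA
#'   when no overlap).
#' @export
overlap_flags <- function(position, chrom, dhs = NULL, tfbs = NULL,
                          imprinted = NULL) {
  hit <- function(track) {
    out <- rep(FALSE, length(position))
    if (is.null(track) || !nrow(track)) return(out)
    tr <- data.table::as.data.table(track)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      iv <- tr[tr$chrom == ch]
      if (!nrow(iv)) next
      out[sel] <- IRanges::overlapsAny(
        IRanges::IRanges(position[sel], position[sel]),
        IRanges::IRanges(iv$start, iv$end))
    }
    out
  }
  gene_hit <- function(track) {
    out <- rep(NA_character_, length(position))
    if (is.null(track) || !nrow(track)) return(out)
    tr <- data.table::as.data.table(track)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      iv <- tr[tr$chrom == ch]
      if (!nrow(iv)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(position[sel], position[sel]),
        IRanges::IRanges(iv$start, iv$end), select = "first")
      out[sel] <- ifelse(is.na(ov), NA_character_, iv$name[ov])
    }
    out
  }
  data.table::data.table(dhs = hit(dhs), tfbs = hit(tfbs),
                         imprinted_gene = gene_hit(imprinted))
}

#' Full per-CpG annotation
#'
#' @param manifest probe manifest (probe_id, chrom, position).
#' @param genes gene model table.
#' @param tracks list with elements cgi, dhs, tfbs, imprinted (interval
#'   tables, 1-based inclusive).
#' @return data.table: probe_id, gene_region, cgi_class, dhs, tfbs,
#'   imprinted_gene.
#' @export
annotate_cpgs <- function(manifest, genes, tracks) {
  man <- data.table::as.data.table(manifest)
  flags <- overlap_flags(man$position, man$chrom,
                         tracks$dhs, tracks$tfbs, tracks$imprinted)
  data.table::data.table(
    probe_id = man$probe_id,
    gene_region = assign_gene_region(man$position, man$chrom, genes),
    cgi_class = assign_cgi_class(man$position, man$chrom, tracks$cgi),
    flags)
}

#' Class counts and proportions of an annotation
#'
#' @param annotation output of [annotate_cpgs()].
#' @return list of data.tables, one per classification axis (gene_region,
#'   cgi_class, dhs, tfbs, imprinted), each with n and proportion columns;
#'   proportions sum to 1 per axis.
#' @export
annotation_composition <- function(annotation) {
  ann <- data.table::as.data.table(annotation)
  if (!nrow(ann)) stop("empty annotation")
  one <- function(values, levels_) {
    f <- factor(values, levels = levels_)
    tab <- table(f)
    data.table::data.table(class = names(tab), n = as.integer(tab),
                           proportion = as.numeric(tab) / length(values))
  }
  list(
    gene_region = one(ann$gene_region, gene_region_levels()),
    cgi_class = one(ann$cgi_class, cgi_class_levels()),
    dhs = one(ifelse(ann$dhs, "dhs", "non_dhs"), c("dhs", "non_dhs")),
    tfbs = one(ifelse(ann$tfbs, "tfbs", "non_tfbs"), c("tfbs", "non_tfbs")),
    imprinted = one(ifelse(is.na(ann$imprinted_gene), "not_imprinted", "imprinted"),
                    c("imprinted", "not_imprinted"))
  )
}
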