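#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Emits the tab-separated signal table (CpG and negative-control rows
#' together), the probe manifest, the sample sheet (CSV), the gene model
#' table, BED tracks (0-based half-open) for CpG islands, DHS, TFBS and
#' imprinted DMRs, the ground-truth tables, and a README describing every
#' column. Re-reading with [read_fixture_bundle()] reproduces the dataset
#' bit-exactly.
#'
#' @param dataset a `twin_sim` from [simulate_dataset()].
#' @param directory output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(dataset, directory) {
  stopifnot(inherits(dataset, "twin_sim"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  p <- function(f) file.path(directory, f)
  tsv <- function(x, f) { data.table::fwrite(x, p(f), sep = "\t"); p(f) }

  paths <- c(
    signal = tsv(rbind(dataset$signal, dataset$negcontrols), "signal.tsv"),
    manifest = tsv(dataset$manifest, "manifest.tsv"),
    genes = tsv(dataset$genes, "genes.tsv"))
  data.table::fwrite(dataset$samples, p("samples.csv"))
  paths["samples"] <- p("samples.csv")

  for (tr in names(dataset$tracks)) {
    f <- p(paste0(tr, ".bed"))
    write_bed(dataset$tracks[[tr]], f)
    paths[paste0("track_", tr)] <- f
  }

  tsvp <- function(x, f) { data.table::fwrite(precise_doubles(x), p(f), sep = "\t"); p(f) }
  tr <- dataset$truth
  paths["truth_cpg"] <- tsvp(tr$cpg, "truth_cpg.tsv")
  paths["truth_strata"] <- tsvp(tr$strata, "truth_strata.tsv")
  paths["truth_latent"] <- tsvp(mat_to_dt(tr$latent), "truth_latent.tsv")
  paths["truth_pair_effects"] <- tsvp(mat_to_dt(tr$pair_effects), "truth_pair_effects.tsv")
  paths["truth_fail_cells"] <- tsv(tr$fail_cells, "truth_fail_cells.tsv")
  paths["truth_zero_cells"] <- tsv(tr$zero_cells, "truth_zero_cells.tsv")
  saveRDS_free_config(dataset$config, p("config.json"))
  paths["config"] <- p("config.json")

  writeLines(fixture_readme(), p("README.txt"))
  paths["readme"] <- p("README.txt")
  invisible(paths)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param directory bundle directory.
#' @return a `twin_sim` list (true beta matrix reconstructed from the
#'   stored latent values).
#' @export
read_fixture_bundle <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("signal.tsv", "manifest.tsv", "samples.csv"))
    if (!file.exists(p(f))) stop("fixture bundle is missing ", f)
  manifest <- data.table::fread(p("manifest.tsv"))
  all_signal <- data.table::fread(p("signal.tsv"))
  is_neg <- startsWith(all_signal$probe_id, "negctl_")
  cfg <- config_from_json(p("config.json"))
  latent <- dt_to_mat(data.table::fread(p("truth_latent.tsv")))
  truth <- list(
    cpg = data.table::fread(p("truth_cpg.tsv")),
    strata = data.table::fread(p("truth_strata.tsv")),
    latent = latent,
    beta = plogis_(latent),
    pair_effects = dt_to_mat(data.table::fread(p("truth_pair_effects.tsv"))),
    fail_cells = data.table::fread(p("truth_fail_cells.tsv"),
                                   colClasses = c("character", "character")),
    zero_cells = data.table::fread(p("truth_zero_cells.tsv"),
                                   colClasses = c("character", "character")))
  structure(list(
    signal = all_signal[!is_neg],
    negcontrols = all_signal[is_neg],
    manifest = manifest,
    samples = data.table::fread(p("samples.csv")),
    genes = data.table::fread(p("genes.tsv"),
                              colClasses = list(character = "gene_id")),
    tracks = list(
      cgi = read_bed(p("cgi.bed")),
      dhs = read_bed(p("dhs.bed")),
      tfbs = read_bed(p("tfbs.bed")),
      imprinted = read_bed(p("imprinted.bed"), named = TRUE)),
    truth = truth,
    config = cfg
  ), class = "twin_sim")
}

# --- BED (0-based half-open on disk; 1-based inclusive in memory) ---------

#' Write / read genomic intervals as BED
#'
#' In-memory interval tables are 1-based inclusive (`start`, `end`); on disk
#' BED is 0-based half-open, so a feature covering 1-based positions
#' 101..200 is written as `start = 100`, `end = 200`.
#'
#' @param intervals data.frame with columns chrom, start, end (and
#'   optionally name).
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  x <- data.table::as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$end < x$start)) stop("malformed interval: end < start")
  out <- data.table::data.table(chrom = x$chrom, start = x$start - 1L, end = x$end)
  if ("name" %in% names(x)) out$name <- x$name
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param named expect a 4th name column.
#' @export
read_bed <- function(path, named = FALSE) {
  cols <- if (named) c("chrom", "start", "end", "name") else c("chrom", "start", "end")
  if (!file.exists(path) || file.size(path) == 0)
    return(data.table::as.data.table(
      stats::setNames(c(list(character(), integer(), integer()),
                        if (named) list(character())), cols)))
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(x, cols[seq_len(ncol(x))])
  x$start <- x$start + 1L
  if (nrow(x) && any(x$end < x$start)) stop("malformed interval: end < start")
  x[]
}

# --- helpers --------------------------------------------------------------

mat_to_dt <- function(m) {
  dt <- data.table::as.data.table(m, keep.rownames = "probe_id")
  dt
}

# Render double columns with 17 significant digits so that writing and
# re-parsing reproduces them bit-exactly.
precise_doubles <- function(x) {
  dt <- data.table::as.data.table(x)
  for (col in names(dt))
    if (is.double(dt[[col]]))
      data.table::set(dt, j = col, value = sprintf("%.17g", dt[[col]]))
  dt
}

dt_to_mat <- function(dt) {
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

saveRDS_free_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$strata <- lapply(x$strata, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
}

config_from_json <- function(path) {
  if (!file.exists(path)) return(NULL)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  strata <- lapply(x$strata, function(s)
    stratum_spec(s$name, s$gene_region, s$cgi_class, s$n_cpgs,
                 unlist(s$meth_class_weights), s$target_spearman,
                 s$logit_noise_sd, s$probe_type_fraction_II,
                 s$dhs, s$tfbs,
                 if (is.null(s$imprinted_gene)) NA_character_ else s$imprinted_gene))
  sim_config(x$n_pairs, x$n_control_replicates, unname(strata),
             x$background_mean, x$background_sd,
             x$total_intensity_log_mean, x$total_intensity_log_sd,
             x$bead_count_mean, x$fail_fraction, x$zero_fraction,
             x$n_negative_controls, x$ambiguous_fraction, x$snp_fraction,
             x$type2_logit_scale, x$finite_pair_correction, x$seed)
}

fixture_readme <- function() c(
  "Synthetic twin-methylation fixture bundle",
  "",
  "signal.tsv        probe_id, sample_id, meth, unmeth, beads; CpG probes plus",
  "                  negative-control rows (probe_id prefix 'negctl_').",
  "manifest.tsv      probe_id, chrom, position (1-based C position), probe_type",
  "                  (I/II), ambiguous (mapping flag), snp_at_cpg.",
  "samples.csv       sample_id, pair_id, twin_index, role (twin /",
  "                  control_replicate), sex, age_group.",
  "genes.tsv         gene_id, chrom, strand, tss, end3 (1-based).",
  "cgi.bed/dhs.bed/tfbs.bed/imprinted.bed  0-based half-open BED;",
  "                  imprinted.bed carries the gene id in column 4.",
  "truth_cpg.tsv     probe_id, stratum, position, meth_class_true, baseline_logit.",
  "truth_strata.tsv  per-stratum generating parameters and realized latent",
  "                  co-twin Spearman correlation.",
  "truth_latent.tsv  latent log-odds methylation, CpG x sample.",
  "truth_pair_effects.tsv  familial effects, CpG x pair.",
  "truth_fail_cells.tsv / truth_zero_cells.tsv  planted detection failures /",
  "                  zero-intensity cells.",
  "config.json       full generator configuration.")

# Long signal table -> list of probe x sample matrices (meth, unmeth, beads).
signal_matrices <- function(signal) {
  s <- data.table::as.data.table(signal)
  probes <- unique(s$probe_id)
  samples <- unique(s$sample_id)
  cast1 <- function(col) {
    w <- data.table::dcast(s, probe_id ~ sample_id, value.var = col)
    m <- as.matrix(w[, -1])
    rownames(m) <- w$probe_id
    m[probes, samples, drop = FALSE]
  }
  list(meth = cast1("meth"), unmeth = cast1("unmeth"), beads = cast1("beads"),
       probes = probes, samples = samples)
}
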