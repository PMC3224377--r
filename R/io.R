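#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#' @param genome named character vector or DNAStringSet.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(as_genome_strings(genome)))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' GFF 1-based closed coordinates map directly onto GRanges. Only rows whose
#' type is `gene` are kept.
#'
#' @param path GFF3 file.
#' @return GRanges of genes with strand.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr[gr$type == "gene"]
}

#' Write gene ranges as GFF3
#' @param genes GRanges with optional `gene_id` column.
#' @param path output file.
#' @export
write_gff_genes <- function(genes, path) {
  g <- genes
  g$type <- "gene"
  g$source <- "nucleoflex"
  if (is.null(g$gene_id)) g$gene_id <- sprintf("gene%03d", seq_along(g))
  g$ID <- g$gene_id
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED6
#'
#' 1-based closed GRanges are converted to BED's 0-based half-open
#' convention. `score` defaults to 0; for classified nucleosome calls use
#' `score = 1000 * height_score` and `name = class`.
#'
#' @param gr GRanges.
#' @param path output file.
#' @param name,score optional per-range vectors.
#' @export
write_bed <- function(gr, path, name = NULL, score = NULL) {
  if (is.null(name)) name <- rep(".", length(gr))
  if (is.null(score)) score <- rep(0, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = round(score, 3), strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a track as bedGraph
#'
#' Runs of equal value are merged into single 0-based half-open lines; `NA`
#' stretches are omitted. A `track` header line records the kind and the
#' parameters echoed by the caller.
#'
#' @param track `coverage_track` or named list of numeric vectors.
#' @param path output file.
#' @param header optional extra `#` comment lines (parameter echo).
#' @export
write_bedgraph <- function(track, path, header = character(0)) {
  values <- if (inherits(track, "coverage_track")) track$values else track
  kind <- if (inherits(track, "coverage_track")) track$kind else "track"
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(sprintf("track type=bedGraph name=%s", kind), con)
  for (chrom in names(values)) {
    v <- values[[chrom]]
    r <- rle(ifelse(is.na(v), NA, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep] - 1L,
                       ends[keep], format(r$values[keep], trim = TRUE,
                                          scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read a generic TSV with header
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#")
}

default_pipeline_params <- function() {
  list(extend = 147, dyad_window = 20, cap_k = 5, lr_q = 0.05,
       lr_min_len = 50, lr_merge_gap = 20, clr_min_len = 50, alpha = 0.5,
       keep_fraction = 0.02, height_threshold_quantile = 0.25,
       nms_window = 74, rel_height = 0.4,
       overlap_max = 50, h_min = 0.4, depleted_quantile = 0.9,
       enriched_quantile = 0.25, predict_min_len = 50, flank = 1000,
       energy_stride = 1)
}

#' Run the full synthetic-digestion analysis pipeline
#'
#' Orchestrates simulate -> coverage -> cut-site enrichment -> LR/CLR ->
#' bias correction -> nucleosome calling/classification -> physical
#' descriptor profiles -> region prediction -> metagene aggregation, writing
#' every product plus a JSON manifest into `out_dir`. Reruns with the same
#' configuration are identical except for the manifest timestamp.
#'
#' @param config a [sim_config()], or path to a YAML file whose keys override
#'   `sim_config()` arguments and the pipeline parameters
#'   (extend, lr_q, alpha, keep_fraction, ...).
#' @param out_dir run directory (created).
#' @param params named list overriding individual pipeline parameters.
#' @return invisible list with the main in-memory objects.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, params = list()) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    pp <- default_pipeline_params()
    sim_args <- y[intersect(names(y), names(formals(sim_config)))]
    params <- utils::modifyList(y[intersect(names(y), names(pp))], params)
    config <- do.call(sim_config, sim_args)
  }
  pp <- utils::modifyList(default_pipeline_params(), params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- stage("simulate", {
    t0 <- generate_genome(config)
    place_nucleosomes(t0)
  })
  glen <- setNames(nchar(truth$genome[[1]]), names(truth$genome))
  write_fasta(truth$genome, pth("genome.fa"))
  write_gff_genes(truth$genes, pth("genes.gff3"))
  dig_nuc <- stage("simulate", simulate_digestion(truth, naked = FALSE))
  dig_nak <- stage("simulate", simulate_digestion(truth, naked = TRUE))
  write_bed(dig_nuc$reads, pth("reads_nucleosomal.bed"))
  write_bed(dig_nak$reads, pth("reads_naked.bed"))

  capped <- stage("coverage", lapply(
    list(nuc = dig_nuc$reads, naked = dig_nak$reads),
    cap_duplicates, k = pp$cap_k))
  cov <- stage("coverage", lapply(capped, function(r) {
    rpm_normalize(build_coverage(r, glen))
  }))
  hdr <- sprintf("cap_k=%g", pp$cap_k)
  write_bedgraph(cov$nuc, pth("coverage_nucleosomal.bedgraph"), hdr)
  write_bedgraph(cov$naked, pth("coverage_naked.bedgraph"), hdr)

  enr <- stage("enrich", lapply(
    list(nuc = dig_nuc$reads, naked = dig_nak$reads), function(r) {
      ct <- extract_cut_tetramers(r, truth$genome)
      tetramer_enrichment(ct$counts, ct$n_sites,
                          genome_background(truth$genome))
    }))
  write.table(enr$naked, pth("cut_enrichment_naked.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(enr$nuc, pth("cut_enrichment_nucleosomal.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  lr <- stage("lr", list(
    naked = detect_lr(cov$naked, pp$lr_q, pp$lr_min_len, pp$lr_merge_gap,
                      kind = "LR_naked"),
    nuc = detect_lr(cov$nuc, pp$lr_q, pp$lr_min_len, pp$lr_merge_gap,
                    kind = "LR_nuc")))
  clr <- stage("clr", common_lr(lr$naked, lr$nuc, pp$clr_min_len))
  write_bed(lr$naked, pth("lr_naked.bed"),
            name = rep("LR_naked", length(lr$naked)))
  write_bed(lr$nuc, pth("lr_nucleosomal.bed"),
            name = rep("LR_nuc", length(lr$nuc)))
  write_bed(clr, pth("clr.bed"), name = rep("CLR", length(clr)))

  corrected <- stage("correct", correct_bias(cov$nuc, cov$naked, pp$alpha))
  write_bedgraph(corrected, pth("coverage_corrected.bedgraph"),
                 sprintf("alpha=%g", pp$alpha))
  dyad_cov <- stage("nuccall", lapply(capped, function(r) {
    rpm_normalize(build_coverage(
      dyad_intervals(r, pp$extend, pp$dyad_window), glen))
  }))
  smoothed <- stage("nuccall", fft_smooth(dyad_cov$nuc, pp$keep_fraction))
  calls <- stage("nuccall", classify_calls(
    call_nucleosomes(smoothed, dyad_cov$nuc,
                     pp$height_threshold_quantile,
                     pp$nms_window, pp$rel_height),
    pp$overlap_max, pp$h_min))
  write_bed(calls, pth("nucleosome_calls.bed"), name = calls$class,
            score = 1000 * calls$height_score)

  table <- default_stiffness_table()
  shape <- nucleosome_shape()
  ktr <- stage("physprof", {
    kt <- ktotal_profile(truth$genome[[1]], table)
    setNames(list(c(kt, NA)), names(truth$genome)) # pad to genome length
  })
  etr <- stage("energy", energy_profile(truth$genome, table, shape,
                                        stride = pp$energy_stride))
  write_bedgraph(ktr, pth("ktotal.bedgraph"))
  write_bedgraph(etr, pth("energy.bedgraph"))
  pred <- stage("predict", predict_regions(etr, pp$depleted_quantile,
                                           pp$enriched_quantile,
                                           pp$predict_min_len))
  write_bed(pred, pth("predicted_regions.bed"), name = pred$kind)

  prof <- stage("metagene", {
    tss <- gene_anchors(truth$genes, "TSS")
    tts <- gene_anchors(truth$genes, "TTS")
    list(tss_nuc = anchor_profile(cov$nuc, tss, pp$flank),
         tss_naked = anchor_profile(cov$naked, tss, pp$flank),
         tts_nuc = anchor_profile(cov$nuc, tts, pp$flank),
         tss_ktotal = anchor_profile(ktr, tss, pp$flank),
         lr_naked_mid = if (length(lr$naked) > 0) {
           region_midpoint_profile(cov$naked, lr$naked, pp$flank)
         } else NULL)
  })
  for (nm in names(prof)) {
    if (!is.null(prof[[nm]])) {
      write.table(prof[[nm]], pth(paste0("profile_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  report <- stage("report", truth_report(
    truth, calls, c(lr$naked, lr$nuc), enr$naked))
  write.table(report, pth("truth_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "nucleoflex",
    version = as.character(utils::packageVersion("nucleoflex")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    sim_config = config[setdiff(names(config), c("cut_weights",
                                                 "deg_weights"))],
    pipeline_params = pp,
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(truth = truth, coverage = cov, enrichment = enr, lr = lr,
                 clr = clr, corrected = corrected, calls = calls,
                 energy = etr, ktotal = ktr, predicted = pred,
                 profiles = prof, report = report))
}
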