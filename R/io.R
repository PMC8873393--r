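fmt_num <- function(x) sprintf("%.17g", x) # lossless double round trip

#' Write a simulated experiment to plain-text fixtures
#'
#' Emits the annotation as GTF (transcript + exon features with `gene_id`,
#' `transcript_id`, `gene_biotype` and a `cds_length` attribute; unknown
#' strand serialises as `"."`), the counts, design and ground truth as
#' tab-separated files. Reading the files back with [read_annotation()],
#' [read_counts()], [read_design()] and [read_truth()] reproduces the
#' in-memory objects.
#'
#' @param models Gene models tibble.
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param design Design tibble.
#' @param truth Optional truth tibble.
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(models, counts, design, truth = NULL, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir), class = "uvtx_io_error")
  }
  stopifnot(identical(sort(models$gene_id), sort(counts$gene_id)))
  stopifnot(all(sample_columns(counts) %in% design$sample_id))
  paths <- c(
    annotation = file.path(dir, "annotation.gtf"),
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv")
  )
  write_gtf(models, paths[["annotation"]])
  readr::write_tsv(counts, paths[["counts"]])
  readr::write_tsv(design, paths[["design"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    readr::write_tsv(flatten_truth(truth), paths[["truth"]])
  }
  invisible(paths)
}

write_gtf <- function(models, path) {
  check_gene_models(models)
  tx <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(models$tx_start, models$tx_end),
    strand = models$strand,
    type = "transcript",
    gene_id = models$gene_id,
    transcript_id = paste0(models$gene_id, ".t1"),
    gene_biotype = models$biotype,
    cds_length = as.character(models$cds_length)
  )
  ex_tbl <- tidyr::unnest(
    models[, c("gene_id", "biotype", "chrom", "strand", "cds_length", "exons")],
    "exons"
  )
  ex <- GenomicRanges::GRanges(
    seqnames = ex_tbl$chrom,
    ranges = IRanges::IRanges(ex_tbl$start, ex_tbl$end),
    strand = ex_tbl$strand,
    type = "exon",
    gene_id = ex_tbl$gene_id,
    transcript_id = paste0(ex_tbl$gene_id, ".t1"),
    gene_biotype = ex_tbl$biotype,
    cds_length = as.character(ex_tbl$cds_length)
  )
  rtracklayer::export(c(tx, ex), path, format = "gtf")
  invisible(path)
}

#' Read a GTF annotation into a gene-model tibble
#'
#' Accepts the GTF written by [write_fixtures()] (or any GTF carrying
#' `gene_id`, exon features, and optionally `gene_biotype` and
#' `cds_length` attributes) and rebuilds the gene-model tibble: exons are
#' collected per gene, sorted, and the derived lengths recomputed.
#'
#' @param path Path to a GTF file.
#' @return A gene-model tibble (see [generate_gene_models()]).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  tbl <- tibble(
    gene_id = ex$gene_id,
    biotype = if (!is.null(ex$gene_biotype)) ex$gene_biotype else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    cds_length = if (!is.null(ex$cds_length)) {
      as.integer(ex$cds_length)
    } else {
      0L
    }
  )
  out <- tbl |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      biotype = dplyr::first(.data$biotype),
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      exons = list(tibble(
        start = as.integer(start),
        end = as.integer(end)
      )),
      tx_length = as.integer(sum(.data$end - .data$start + 1)),
      exon_count = dplyr::n(),
      cds_length = dplyr::first(.data$cds_length),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      template_span = as.integer(.data$tx_end - .data$tx_start + 1),
      exon_count = as.integer(.data$exon_count),
      intron_count = as.integer(.data$exon_count - 1L),
      tx_start = as.integer(.data$tx_start),
      tx_end = as.integer(.data$tx_end)
    )
  out[, c(
    "gene_id", "biotype", "chrom", "strand", "tx_start", "tx_end", "exons",
    "template_span", "tx_length", "exon_count", "intron_count", "cds_length"
  )]
}

#' Read counts / design / truth fixtures
#'
#' @param path Path to the TSV written by [write_fixtures()].
#' @return `read_counts()`: a tibble `gene_id` + integer sample columns;
#'   `read_design()`: the design tibble; `read_truth()`: the truth tibble
#'   with `lesion_positions` and `kinetics` list columns rebuilt.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (cn in sample_columns(out)) out[[cn]] <- as.integer(out[[cn]])
  out
}

#' @rdname read_counts
#' @export
read_design <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      fraction = readr::col_character(),
      timepoint = readr::col_double(),
      replicate = readr::col_integer()
    ), progress = FALSE
  )
}

# one row per gene; per-timepoint kinetics widened, doubles printed at full
# precision so the round trip is exact
flatten_truth <- function(truth) {
  tps <- truth$kinetics[[1]]$timepoint
  out <- truth[, c(
    "gene_id", "biotype", "induced", "label_chromatin", "label_cytoplasm"
  )]
  out$baseline <- fmt_num(truth$baseline)
  out$n_lesions <- truth$n_lesions
  out$recovery_time <- ifelse(is.na(truth$recovery_time), "",
    fmt_num(truth$recovery_time)
  )
  out$lesion_positions <- vapply(
    truth$lesion_positions,
    function(x) paste(fmt_num(x), collapse = ","), character(1)
  )
  for (j in seq_along(tps)) {
    out[[sprintf("unrepaired_t%g", tps[j])]] <-
      vapply(truth$kinetics, function(k) k$unrepaired[j], integer(1))
    out[[sprintf("activity_t%g", tps[j])]] <-
      vapply(truth$kinetics, function(k) fmt_num(k$activity[j]), character(1))
    out[[sprintf("induction_t%g", tps[j])]] <-
      vapply(truth$kinetics, function(k) fmt_num(k$induction[j]), character(1))
  }
  out
}

#' @rdname read_counts
#' @export
read_truth <- function(path) {
  flat <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  tp_cols <- grep("^activity_t", names(flat), value = TRUE)
  tps <- as.numeric(sub("^activity_t", "", tp_cols))
  n <- nrow(flat)
  kinetics <- vector("list", n)
  for (i in seq_len(n)) {
    kinetics[[i]] <- tibble(
      timepoint = tps,
      unrepaired = as.integer(unlist(flat[i, sprintf("unrepaired_t%g", tps)])),
      activity = as.numeric(unlist(flat[i, sprintf("activity_t%g", tps)])),
      induction = as.numeric(unlist(flat[i, sprintf("induction_t%g", tps)]))
    )
  }
  tibble(
    gene_id = flat$gene_id,
    biotype = flat$biotype,
    baseline = as.numeric(flat$baseline),
    lesion_positions = lapply(flat$lesion_positions, function(s) {
      if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ",")[[1]])
    }),
    n_lesions = as.integer(flat$n_lesions),
    induced = as.logical(flat$induced),
    kinetics = kinetics,
    label_chromatin = flat$label_chromatin,
    recovery_time = ifelse(is.na(flat$recovery_time) | flat$recovery_time == "",
      NA_real_, suppressWarnings(as.numeric(flat$recovery_time))
    ),
    label_cytoplasm = flat$label_cytoplasm
  )
}
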