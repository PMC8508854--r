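# Plain-text readers/writers for the package's table dialects:
# manifest and matrices as TSV, sample sheets as CSV, reports as JSON.

#' Read / write a probe manifest (TSV)
#'
#' Columns: `probe_id`, `chrom`, `pos`, `gene`, `design_type`, `snp_flag`.
#'
#' @param path File path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    gene = readr::col_character(),
    design_type = readr::col_character(),
    snp_flag = readr::col_logical()
  )) |>
    dplyr::mutate(gene = dplyr::coalesce(.data$gene, ""))
}

#' @param manifest Manifest tibble.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' Read / write a probes-by-samples matrix (TSV)
#'
#' First column `probe_id`, remaining columns one per sample. Used for beta
#' values, M-values and detection p-values alike.
#'
#' @param path File path.
#' @return `read_matrix_tsv()` returns the matrix tibble.
#' @export
read_matrix_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    .default = readr::col_double()
  ))
  stopifnot(names(x)[1] == "probe_id")
  x
}

#' @param x Matrix tibble (first column `probe_id`).
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write a sample sheet (CSV)
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns the sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    subject_id = readr::col_character(),
    timepoint = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character(),
    on_treatment = readr::col_logical(),
    .default = readr::col_double()
  ))
}

#' @param sheet Sample sheet tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path)
  invisible(path)
}

#' Write every artifact of a pipeline run to a directory
#'
#' Lays out one file per stage: filter reports (JSON), the selection result
#' (JSON plus a per-probe contribution TSV), validated sites, gene
#' summaries and descriptives (TSV), the biomarker model (JSON) and, when
#' present, recovery metrics (JSON). Content is deterministic for a fixed
#' configuration and seed (no timestamps).
#'
#' @param report A `meth_report` from [run_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_report_bundle <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jw <- function(x, file) {
    jsonlite::write_json(x, file.path(outdir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jw(report$filter_baseline, "filter_baseline.json")
  jw(report$filter_followup, "filter_followup.json")
  sel <- report$selection
  jw(list(stage1_ids = sel$stage1_ids, stage2_ids = sel$stage2_ids,
          thresholds_used = as.list(sel$thresholds_used),
          params = unclass(sel$params)), "selection.json")
  readr::write_tsv(sel$stage2_contrib,
                   file.path(outdir, "stage2_contributions.tsv"))
  readr::write_tsv(report$sites, file.path(outdir, "validated_sites.tsv"))
  readr::write_tsv(report$genes, file.path(outdir, "gene_summary.tsv"))
  readr::write_tsv(report$descriptives,
                   file.path(outdir, "descriptives.tsv"))
  if (!is.null(report$model)) {
    jw(list(model = report$model$model, trace = report$model$trace,
            n_initial = report$model$n_initial,
            n_final = report$model$n_final,
            criterion = report$model$criterion,
            penalty = report$model$penalty), "biomarker_model.json")
  }
  if (!is.null(report$recovery)) {
    jw(as.list(report$recovery), "recovery.json")
  }
  invisible(outdir)
}
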