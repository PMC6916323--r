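#' Run the full pipeline over a directory of cases
#'
#' For every matched (series, RTSTRUCT) pairing and every selected ROI:
#' rasterize the contours, run the configured preprocessing, extract the
#' feature panel, and add the results to one merged provenance graph and one
#' merged CSV. A failing case is logged with its reason and does not stop the
#' batch. Outputs are written once per batch (merged across cases), plus a
#' JSON run manifest.
#'
#' @param root directory containing the case tree
#' @param cfg an [extraction_config()]
#' @param out_dir output directory (created if needed)
#' @param include,exclude ROI name glob filters, see [select_rois()]
#' @param format one of `"rdf"`, `"csv"`, `"both"`
#' @param rdf_format serialization for the graph file
#' @return the run manifest, invisibly: a list with `attempted`, `succeeded`,
#'   `failed`, `cases`, `outputs`, `config`, `started`, `finished`
#' @export
run_batch <- function(root, cfg = extraction_config(), out_dir = ".",
                      include = character(0), exclude = character(0),
                      format = c("both", "rdf", "csv"),
                      rdf_format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  rdf_format <- match.arg(rdf_format)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  pairings <- match_cases(root)
  if (length(pairings) == 0L) stop("no matched cases under ", root)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  all_feats <- list(); all_pat <- character(0); all_voi <- character(0)
  graphs <- list()
  cases <- list()
  for (pr in pairings) {
    case_id <- basename(dirname(pr$rtstruct_path))
    rec <- list(series_dir = pr$series_dir, rtstruct = pr$rtstruct_path,
                matched_by = pr$matched_by, rois = character(0),
                status = "succeeded", reason = NA_character_)
    res <- tryCatch({
      vol <- read_series(pr$series_dir)
      ss <- select_rois(read_structset(pr$rtstruct_path), include, exclude)
      if (length(ss$rois) == 0L) stop("no ROI matches the include/exclude filters")
      for (roi in ss$rois) {
        rs_log("info", "extracting", case = case_id, stage = roi$name)
        m <- rasterize(roi, vol)
        if (sum(m$bits) == 0L) {
          rs_log("warning", "empty mask, skipping", case = case_id,
                 stage = roi$name)
          next
        }
        feats <- extract_all(vol, m, cfg)
        all_feats[[length(all_feats) + 1L]] <- feats
        all_pat <- c(all_pat, rep(vol$patient_id, nrow(feats)))
        all_voi <- c(all_voi, rep(roi$name, nrow(feats)))
        graphs[[length(graphs) + 1L]] <-
          build_graph(feats, vol$patient_id, roi$name, cfg)
        rec$rois <- c(rec$rois, roi$name)
      }
      if (length(rec$rois) == 0L) stop("no non-empty masks in case")
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$status <- "failed"
      rec$reason <- conditionMessage(res)
      rs_log("error", "case failed: ", rec$reason, case = case_id)
    }
    cases[[case_id]] <- rec
  }

  statuses <- vapply(cases, `[[`, character(1), "status")
  outputs <- character(0)
  if (sum(statuses == "succeeded") > 0L) {
    feats <- do.call(rbind, all_feats)
    if (format %in% c("csv", "both")) {
      csv_path <- file.path(out_dir, "features.csv")
      features_to_csv(feats, all_pat, all_voi, csv_path)
      outputs <- c(outputs, csv_path)
    }
    if (format %in% c("rdf", "both")) {
      g <- do.call(graph_union, graphs)
      ext <- if (rdf_format == "turtle") ".ttl" else ".nt"
      rdf_path <- file.path(out_dir, paste0("features", ext))
      serialize_graph(g, rdf_path, rdf_format)
      outputs <- c(outputs, rdf_path)
    }
  }
  manifest <- list(
    attempted = length(cases),
    succeeded = sum(statuses == "succeeded"),
    failed = sum(statuses == "failed"),
    cases = cases,
    outputs = outputs,
    config = unclass(cfg),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  rs_log("info", sprintf("batch done: %d attempted, %d succeeded, %d failed",
                         manifest$attempted, manifest$succeeded,
                         manifest$failed))
  invisible(manifest)
}
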