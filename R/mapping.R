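#' Feature-name to ontology-code mapping
#'
#' Radiomic features are published under stable identifiers rather than
#' software-specific human-readable names, so that the same quantity computed
#' by different tools can be recognized as the same thing. The built-in table
#' covers the full 105-feature panel: the two features with well-known IBSI
#' identifiers carry them (Intensity Histogram Entropy = TLU2, GLCM Joint
#' Entropy = TU9B); every other feature is assigned a deterministic
#' Radiomics-Ontology-style local code derived from its normalized name and
#' flagged `local`. Users may override or extend the mapping with a
#' two-column CSV (`native_name`, `ontology_code`).
#'
#' @param path optional CSV with columns `native_name`, `ontology_code`
#' @return data.frame with columns `native_name`, `code`, `source`
#' @export
mapping_table <- function(path = NULL) {
  known <- c("firstorder Entropy" = "TLU2",
             "glcm Joint Entropy" = "TU9B")
  roster <- .feature_roster()
  code <- unname(known[roster])
  is_local <- is.na(code)
  code[is_local] <- vapply(roster[is_local], .local_code, character(1))
  tbl <- data.frame(native_name = roster, code = code,
                    source = ifelse(is_local, "local", "ibsi"),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    usr <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("native_name", "ontology_code") %in% names(usr)))
      stop("mapping CSV needs columns native_name, ontology_code")
    if (anyDuplicated(usr$native_name))
      stop("duplicate native_name entries in mapping CSV")
    hit <- match(usr$native_name, tbl$native_name)
    new <- is.na(hit)
    tbl$code[hit[!new]] <- usr$ontology_code[!new]
    tbl$source[hit[!new]] <- "user"
    if (any(new))
      tbl <- rbind(tbl, data.frame(native_name = usr$native_name[new],
                                   code = usr$ontology_code[new],
                                   source = "user"))
  }
  tbl
}

.feature_roster <- function() {
  c(paste("firstorder", c("Energy", "Total Energy", "Entropy", "Minimum",
                          "10th Percentile", "90th Percentile", "Maximum",
                          "Mean", "Median", "Interquartile Range", "Range",
                          "Mean Absolute Deviation",
                          "Robust Mean Absolute Deviation",
                          "Root Mean Squared", "Skewness", "Kurtosis",
                          "Variance", "Uniformity")),
    paste("shape", c("Mesh Volume", "Voxel Volume", "Surface Area",
                     "Surface Volume Ratio", "Sphericity",
                     "Maximum 3D Diameter", "Maximum 2D Diameter Slice",
                     "Maximum 2D Diameter Column", "Maximum 2D Diameter Row",
                     "Major Axis Length", "Minor Axis Length",
                     "Least Axis Length", "Elongation", "Flatness")),
    paste("glcm", .glcm_names),
    paste("glrlm", .glrlm_names),
    paste("glszm", .glszm_names),
    paste("gldm", .gldm_names),
    paste("ngtdm", .ngtdm_names))
}

.local_code <- function(name) {
  paste0("local_", gsub("[^a-z0-9]+", "_", tolower(name)))
}

#' Map feature names to ontology codes
#'
#' Known names map to their table code; unknown names map to a deterministic
#' local code derived from the normalized name, with a warning.
#'
#' @param names character vector of `"family Name"` feature identifiers
#' @param table a [mapping_table()]
#' @return data.frame with columns `native_name`, `code`, `source`
#' @export
map_features <- function(names, table = mapping_table()) {
  hit <- match(names, table$native_name)
  out <- data.frame(native_name = names,
                    code = table$code[hit],
                    source = table$source[hit],
                    stringsAsFactors = FALSE)
  miss <- is.na(hit)
  if (any(miss)) {
    rs_log("warning", "no ontology mapping for: ",
           paste(names[miss], collapse = ", "), "; using local codes")
    out$code[miss] <- vapply(names[miss], .local_code, character(1))
    out$source[miss] <- "local"
  }
  out
}
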